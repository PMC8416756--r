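# V2 + 32 nouns, 3 verbs
[nouns]
bébé
livre
doudou
main
tête
eau
voiture
pied
micro
nez
maison
lapin
train
lait
fleur
poisson
trou
oiseau
lit
cheval
gâteau
oreille
chat
éléphant
jeu
place
bouche
chien
morceau
chambre
pomme
doigt
poussin
canard
poule
carte
verre
montre
matin
monsieur
yeux
vache
boîte
camion
porte
oeuf
biberon
sac
rose
caméra
page
chausson
image
ballon
animal
assiette
mouchoir
cuillère
chanson
bras
fille
table
feuille
banane
[verbs]
aller
faire
garder
mettre
dire
tenir
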