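# V3 + 64 nouns, 6 verbs
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
mouton
balle
chaussure
bout
souris
bouton
bateau
téléphone
musique
carotte
ferme
nounours
puzzle
enfant
arbre
ours
chaise
mamie
soleil
cheveu
papillon
tour
souffle
tasse
fil
panier
café
bonhomme
chapeau
lettre
lumière
soeur
terre
pelle
dent
cochon
pantalon
vélo
sapin
jouet
fenêtre
école
forme
fruit
avion
garçon
crocodile
miette
argent
crèche
chaussette
château
photo
dessin
ventre
colle
clown
renard
pot
cuisine
lune
tétine
neige
tapis
[verbs]
aller
faire
garder
mettre
dire
tenir
prendre
venir
manger
jouer
appeler
trouver
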