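# V1 + 16 nouns, 1 verb
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
[verbs]
aller
faire
garder
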