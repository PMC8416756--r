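# V0 + 8 nouns, 1 verb
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
[verbs]
aller
faire
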