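# smallest seed: 8 object words, 1 action word
[nouns]
bébé
livre
doudou
main
tête
eau
voiture
pied
[verbs]
aller
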