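herb	ingredient
He Shou Wu	Emodin
He Shou Wu	Chrysophanol
He Shou Wu	Chrysarobin
He Shou Wu	Rhein
He Shou Wu	Danthron
He Shou Wu	Polygonumnolide C2
He Shou Wu	Emodin dianthrone
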