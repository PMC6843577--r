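name,source
Emodin,literature
Chrysophanol,literature
Rhein,literature
Aloe emodin,literature
Luteolin,literature
Physcion,literature
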