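id,name,smiles,label
pmt_01,Emodin,,unknown
pmt_02,Chrysophanol,,unknown
pmt_03,Rhein,,unknown
pmt_04,Danthron,,unknown
pmt_05,Aloe emodin,,unknown
pmt_06,Luteolin,,unknown
pmt_07,Physcion,,unknown
pmt_08,Apigenin,,unknown
pmt_09,Emodin-8-methyl ether,,unknown
pmt_10,Citreorosein,,unknown
pmt_11,Emodin-3-methyl ether,,unknown
pmt_12,Fallacinol,,unknown
pmt_13,2-Acetylemodin,,unknown
pmt_14,Hexadecanoic acid methyl ester,,unknown
pmt_15,Octadecanoic acid methyl ester,,unknown
pmt_16,Docosanoic acid methyl ester,,unknown
pmt_17,4-Hydroxybenzaldehyde,,unknown
pmt_18,"2,5-dimethyl-7-hydroxychromone",,unknown
pmt_19,Hydroxymaltol,,unknown
pmt_20,Butanedioic acid,,unknown
pmt_21,"Emodin-6,8-dimethylether",,unknown
pmt_22,Hexanoic acid,,unknown
pmt_23,Resveratrol,,unknown
pmt_24,Kaempferol,,unknown
pmt_25,Quercetin,,unknown
pmt_26,Gallic acid,,unknown
pmt_27,Emodin 8-glucoside,,unknown
pmt_28,Physcion-8-O-D-glucopyranoside,,unknown
pmt_29,"2,3,5,4'-tetrahydroxystilbene-2-O-beta-D-glucopyranoside",,unknown
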