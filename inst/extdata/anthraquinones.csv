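id,name,smiles,label
aq_1,Emodin,CC1=CC2=C(C(=C1)O)C(=O)C3=C(C2=O)C=C(C=C3O)O,hepatotoxic
aq_2,Chrysophanol,CC1=CC2=C(C(=C1)O)C(=O)C3=CC=CC(=C3C2=O)O,hepatotoxic
aq_3,Rhein,C1=CC2=C(C(=C1)O)C(=O)C3=C(C2=O)C=C(C=C3O)C(=O)O,hepatotoxic
aq_4,Danthron,C1=CC2=C(C(=C1)O)C(=O)C3=C(C2=O)C=CC=C3O,hepatotoxic
aq_5,Aloe emodin,C1=CC2=C(C(=C1)O)C(=O)C3=C(C2=O)C=C(C=C3O)CO,hepatotoxic
aq_6,Physcion,CC1=CC2=C(C(=C1)O)C(=O)C3=C(C2=O)C=C(C=C3O)OC,hepatotoxic
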