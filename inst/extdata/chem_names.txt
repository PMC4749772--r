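# Curated starter list of known chemical names for the window-merge and
# plurality rules (case-insensitive lookup). Replace or extend with a full
# chemical-name resource (compounds, elements, amino acids) for production.
NaCL
NaCl
H2O
Acid
salicylate
clonidine
cisplatin
glucose
insulin
rifampin
docetaxel
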