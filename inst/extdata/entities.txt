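# Curated starter list of known entity surface forms for the step-2 gate
# (tokens matching an entry verbatim are exempt from delimiter splitting).
# In production this list is built from the entity annotations of the
# training corpus. Case-sensitive by default.
d-alpha-tocopheryl-co-poly
3-(4,5-dimethylthiazol-2-yl)-2,5-diphenyl
tetrazolium
bromide
cisplatin
TPGS
MTT
HER2
Glucose
salicylate
clonidine
insulin
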