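# Curated starter list of domain-specific affixes used to split conjoined
# tokens (e.g. "hyperinsulinaemia" -> "hyper" + "insulinaemia").
# One entry per line; matching is case-insensitive and prefix-only.
# Replace or extend with a full affix resource for production corpora.
Hyper
Anti
Amino
Hydroxy
Methoxy
Carboxy
Phospho
Sulfo
Nitro
Chloro
Fluoro
Bromo
Iodo
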