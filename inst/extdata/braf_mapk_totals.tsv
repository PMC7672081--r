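drug	tested_lines	anchor_mutated	anchor_related_mm	mm_total
dabrafenib	861	66	28	28
refametinib	933	72	37	42
trametinib	882	70	28	35
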