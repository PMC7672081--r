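MAP2K1
MAP2K2
MAPK1
MAPK3
PTEN
RAC1
CDK4
AKT1
NF1
NRAS
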