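category	count
total	990
melanoma	55
colorectal_carcinoma	50
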