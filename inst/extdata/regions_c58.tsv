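name	kind	definition	exclude
ori1_ori2	rectangle	122:163,363:402
ch1_ch2_alignment	polygon_union	13,285;63,285;220,492;270,492|13,492;63,492;220,285;270,285	ori1_ori2
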