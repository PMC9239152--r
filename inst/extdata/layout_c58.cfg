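bin_size: 10000
ch1_start_offset: 1400000

name: Ch1
length: 2841000
topology: circular
origin: 2825000

name: Ch2
length: 2076000
topology: linear
origin: 975000

name: pAt
length: 542000
topology: circular
origin: 275000

name: pTi
length: 216000
topology: circular
origin: 105000
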