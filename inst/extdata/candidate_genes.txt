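SLC4A2
SLC6A1
SLC6A14
SLC9A7
SLC13A3
SLC13A4
SLC35D2
SLCO1A2
SLC39A10
SLC9B1
SLC22A25
SLC38A6
SPNS2
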