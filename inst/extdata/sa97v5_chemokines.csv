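chemokine,pct
CCL2,28.7
CCL3,14.3
CCL4,27.2
CCL5,13.4
CCL7,38.0
CCL11,36.9
CCL20,30.6
CX3CL1,32.9
CXCL14,-3.3
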