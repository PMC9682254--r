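category	n
PD	11
PR	17
SD	33
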