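source,double_zero,total
surgery,5877,54073
telemonitored,761,44150
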