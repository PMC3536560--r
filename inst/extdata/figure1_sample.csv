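a,c,b1,d1,cohort_controls,cohort_size
30,10,10,30,400,440
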