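stage,tsc,vacancy,axon,n_endplates
P0,31,17,52,10
P3,57,18,25,8
P7,55,5,40,5
P16,41,6,53,2
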