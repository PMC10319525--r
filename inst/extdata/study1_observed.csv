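group,outcome,count
exposed,1,360
unexposed,1,160
exposed,0,240
unexposed,0,240
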