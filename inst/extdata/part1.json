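{"prior_m1":[{"w":1,"mu":0,"var":1}],"prior_m2":[{"w":0.5,"mu":-2.5,"var":0.25},{"w":0.5,"mu":2.5,"var":0.25}],"p_m1":0.5,"d_max":8,"probe_widths":[3,5,8]}
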