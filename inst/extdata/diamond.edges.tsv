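parent	child
t1	t2
t1	t3
t1	t4
t2	t4
t3	t4
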