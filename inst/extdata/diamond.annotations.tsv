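gene_id	term_id
a	t4
b	t4
c	t2
d	t3
e	t3
f	t1
g	t1
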