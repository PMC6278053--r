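# five-node example network: source	target	probability
# (synthetic probabilities; the topology is the documented toy example)
a	d	0.1
b	c	0.8
b	d	0.7
a	c	0.9
c	e	0.6
b	e	0.4
e	d	0.7
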