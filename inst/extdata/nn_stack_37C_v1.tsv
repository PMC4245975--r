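key	value
version	nn37-v1
stack:AA	-0.93
stack:AC	-2.24
stack:AG	-2.08
stack:AU	-1.10
stack:CA	-2.11
stack:CC	-3.26
stack:CG	-2.36
stack:CU	-2.08
stack:GA	-2.35
stack:GC	-3.42
stack:GG	-3.26
stack:GU	-2.24
stack:UA	-1.33
stack:UC	-2.35
stack:UG	-2.11
stack:UU	-0.93
gu_stack	-1.00
terminal_au	0.45
duplex_init	0.00
mismatch_penalty	1.00
asym_penalty	0.50
hairpin_base	5.40
hairpin_slope	1.60
bulge_base	3.80
bulge_per	0.50
intloop_base	1.70
intloop_per	0.50
intloop_asym	0.60
ml_init	3.40
ml_branch	0.40
ml_unpaired	0.00
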