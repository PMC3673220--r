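# riboSD RNA:RNA duplex nearest-neighbor parameters, v1.0
# Free-energy increments at 37 C, kcal/mol.
# Watson-Crick and G:U wobble stack increments and loop initiation penalties
# from the Turner 2004 RNA parameter set (as distributed with ViennaRNA 2.x);
# `init` is the intermolecular duplex initiation penalty.
# stack: `key1` = 5' pair, `key2` = pair stacked directly 3' of it on the
# probe strand; a pair "XY" is probe base X (5'->3') paired to target base Y.
# bulge/iloop: `key1` = total unpaired length of the bulge / internal loop.
param	key1	key2	value
init	.	.	4.10
stack	CG	CG	-3.30
stack	CG	GC	-2.40
stack	CG	GU	-1.40
stack	CG	UG	-2.10
stack	CG	AU	-2.10
stack	CG	UA	-2.10
stack	GC	CG	-3.40
stack	GC	GC	-3.30
stack	GC	GU	-1.50
stack	GC	UG	-2.50
stack	GC	AU	-2.40
stack	GC	UA	-2.20
stack	GU	CG	-2.50
stack	GU	GC	-2.10
stack	GU	GU	-0.50
stack	GU	UG	1.30
stack	GU	AU	-1.30
stack	GU	UA	-1.40
stack	UG	CG	-1.50
stack	UG	GC	-1.40
stack	UG	GU	0.30
stack	UG	UG	-0.50
stack	UG	AU	-1.00
stack	UG	UA	-0.60
stack	AU	CG	-2.20
stack	AU	GC	-2.10
stack	AU	GU	-0.60
stack	AU	UG	-1.40
stack	AU	AU	-0.90
stack	AU	UA	-1.10
stack	UA	CG	-2.40
stack	UA	GC	-2.10
stack	UA	GU	-1.00
stack	UA	UG	-1.30
stack	UA	AU	-1.30
stack	UA	UA	-0.90
bulge	1	.	3.80
bulge	2	.	2.80
bulge	3	.	3.20
bulge	4	.	3.60
iloop	2	.	1.00
iloop	3	.	1.00
iloop	4	.	1.10
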