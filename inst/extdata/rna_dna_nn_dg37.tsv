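# Nearest-neighbor free energy parameters (dG37, kcal/mol) for RNA/DNA hybrid
# duplexes, Sugimoto et al. 1995 (Biochemistry 34:11211-11216).
# 'pair' is the RNA dinucleotide read 5'->3'; the DNA strand is its perfect
# Watson-Crick complement. 'init' is the duplex initiation penalty.
pair	dg37
AA	-1.0
AC	-2.1
AG	-1.8
AU	-0.9
CA	-0.9
CC	-2.1
CG	-1.7
CU	-0.9
GA	-1.3
GC	-2.7
GG	-2.9
GU	-1.1
UA	-0.6
UC	-1.5
UG	-1.6
UU	-0.2
init	3.1
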