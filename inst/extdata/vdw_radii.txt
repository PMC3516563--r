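# van der Waals contact radii (Angstrom), one "key value" pair per line.
# Keys are element symbols (replacing the built-in default) or PDB atom
# names (per-atom overrides).  This file mirrors the package default table;
# copy and edit it, then load with read_radius_table().
H  1.20
C  1.70
N  1.55
O  1.52
F  1.47
P  1.80
S  1.80
CL 1.75
BR 1.85
I  1.98
SE 1.90
B  1.92
FE 2.00
CU 1.40
ZN 1.39
MG 1.73
MN 2.00
MO 2.10
CO 2.00
NI 1.63
NA 2.27
K  2.75
CA 2.31
W  2.10
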