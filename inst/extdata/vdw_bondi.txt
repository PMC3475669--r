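# Van der Waals radii (Angstrom), Bondi (1964) set with common extensions.
# Format: element whitespace radius.  Used as the default radii table; the
# table name is recorded in every run manifest because results depend on it.
H  1.20
C  1.70
N  1.55
O  1.52
S  1.80
P  1.80
F  1.47
CL 1.75
BR 1.85
I  1.98
SE 1.90
B  1.92
SI 2.10
NA 2.27
K  2.75
MG 1.73
CA 2.31
MN 2.05
FE 2.05
CO 2.00
NI 1.97
CU 1.96
ZN 2.01
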