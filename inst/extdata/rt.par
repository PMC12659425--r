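# van der Waals radii (Angstrom), Rowland-Taylor tabulation.
# Applied radii are tabulated * scale; the conventional scale is 1.18 (+18%).
H   1.10
C   1.77
N   1.64
O   1.58
F   1.46
P   1.80
S   1.81
Cl  1.76
Br  1.87
I   2.03
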