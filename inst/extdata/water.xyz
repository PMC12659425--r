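3
water, gas-phase-like geometry (Angstrom)
O    0.000000    0.000000    0.117300
H    0.000000    0.757200   -0.469200
H    0.000000   -0.757200   -0.469200
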