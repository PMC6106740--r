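# Linear RGB dichromacy simulation matrices.
# Rows give (R', G', B') as weights over (R, G, B). These are the
# Vienot/Brettel-derived approximations popularised by web colour-blindness
# simulators (e.g. colorjack/Coblis). Each row sums to ~1, so the
# achromatic axis (grays, white) is a fixed point of the simulation.
matrices:
  protanopia:
    - [0.567, 0.433, 0.000]
    - [0.558, 0.442, 0.000]
    - [0.000, 0.242, 0.758]
  deuteranopia:
    - [0.625, 0.375, 0.000]
    - [0.700, 0.300, 0.000]
    - [0.000, 0.300, 0.700]
  tritanopia:
    - [0.950, 0.050, 0.000]
    - [0.000, 0.433, 0.567]
    - [0.000, 0.475, 0.525]
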