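# Lipid-mimetic medium at 298.15 K.
# Viscosity of pentyl ethanoate (pentyl acetate) at 298.15 K from standard
# solvent tables. Stokes radii are package defaults: ~4 A for a ~390 g/mol
# fused-ring ester solute, ~2 A for the HO radical; reaction distance
# defaults to their sum.
temperature_K: 298.15
medium: pentyl ethanoate
viscosity_Pa_s: 8.62e-4
solute_radius_m: 4.0e-10
radical_radius_m: 2.0e-10
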