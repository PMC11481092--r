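# Frozen calibration of the shipped "paper" kinetic preset, as produced by
# calibrate_rig() with its default targets (step-1 max 0.65, step-2 max on the
# intermediate mixture 0.97, telescoped overall max 0.85).  Stored as plain
# constants so loading the package never re-runs the calibration.
CAL <- list(
  A1 = 87880.1557139335,      # min^-1 g^-1, hydrogenation pre-exponential
  k_h = 36.1865452846468,     # L mol^-1 min^-1, anhydride hydrolysis constant
  C3_stock = 0.245727736956859  # mol/L, acetic anhydride stock concentration
)
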