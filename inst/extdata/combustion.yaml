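# Per-PFT combustion (emission) and fire-mortality fractions by carbon pool.
#
# SYNTHETIC PLACEHOLDER VALUES.  The source model's calibrated tables are
# not reproduced here; these values only preserve the qualitative ordering
# of combustion completeness (litter > leaf > soil > stem ~ root) and keep
# emission + mortality <= 1 for every live pool.  Override via
# apply_fire(params = ...) or a custom file read with read_combustion().
#
# emission_frac: fraction of the pool's carbon in the burned area emitted
#   as CO2 (soil value is a bulk profile-average combustibility).
# mortality_frac: fraction of the live pool killed and transferred to
#   litter (live pools only).
needleleaf_evergreen:
  leaf:   {emission_frac: 0.35, mortality_frac: 0.50}
  stem:   {emission_frac: 0.06, mortality_frac: 0.40}
  root:   {emission_frac: 0.05, mortality_frac: 0.35}
  litter: {emission_frac: 0.50}
  soil:   {emission_frac: 0.02}
needleleaf_continental:
  leaf:   {emission_frac: 0.35, mortality_frac: 0.50}
  stem:   {emission_frac: 0.06, mortality_frac: 0.40}
  root:   {emission_frac: 0.05, mortality_frac: 0.35}
  litter: {emission_frac: 0.50}
  soil:   {emission_frac: 0.02}
broadleaf_deciduous:
  leaf:   {emission_frac: 0.30, mortality_frac: 0.45}
  stem:   {emission_frac: 0.05, mortality_frac: 0.35}
  root:   {emission_frac: 0.04, mortality_frac: 0.30}
  litter: {emission_frac: 0.45}
  soil:   {emission_frac: 0.02}
grass:
  leaf:   {emission_frac: 0.70, mortality_frac: 0.25}
  stem:   {emission_frac: 0.40, mortality_frac: 0.30}
  root:   {emission_frac: 0.02, mortality_frac: 0.20}
  litter: {emission_frac: 0.65}
  soil:   {emission_frac: 0.01}
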