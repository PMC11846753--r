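# Material parameter sets (kPa) for the modified Mooney-Rivlin models.
# Assumptions recorded with the values:
#  - c2 is taken as 0 for lipid and calcification (isotropic tissues,
#    K1 = 0; the fiber term is absent).
#  - The vessel c1 is negative; the exponential isotropic term (D1, D2)
#    dominates, giving a monotone stiffening stress-stretch response.
vessel:
  c1: -515.6
  c2: 45.05
  D1: 247.3
  D2: 2.0
  K1: 14.1
  K2: 23.5
lipid:
  c1: 0.5
  c2: 0.0
  D1: 0.5
  D2: 1.5
calcification:
  c1: 920.0
  c2: 0.0
  D1: 360.0
  D2: 2.0
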