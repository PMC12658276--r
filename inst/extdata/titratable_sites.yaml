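# Titratable-site definitions: reference pKa in water and the localized
# functional-group charge sets. The protonated and deprotonated sets must
# differ by exactly +1 e in total; charges are in elementary charge units.
# This is a simplified charge model shipped as data so that alternative
# (e.g. force-field derived) models can be dropped in without code changes.
ASP:
  reference_pka: 3.90
  is_base: false
  charge_sets:
    protonated:   {CG: 0.60, OD1: -0.30, OD2: -0.30}
    deprotonated: {CG: 0.60, OD1: -0.80, OD2: -0.80}
GLU:
  reference_pka: 4.07
  is_base: false
  charge_sets:
    protonated:   {CD: 0.60, OE1: -0.30, OE2: -0.30}
    deprotonated: {CD: 0.60, OE1: -0.80, OE2: -0.80}
HIS:
  # default (deprotonated) form is the neutral epsilon tautomer
  reference_pka: 6.04
  is_base: true
  charge_sets:
    protonated:   {CE1: 0.30, ND1: 0.50, NE2: 0.20}
    deprotonated: {CE1: 0.30, ND1: 0.00, NE2: -0.30}
LYS:
  reference_pka: 10.54
  is_base: true
  charge_sets:
    protonated:   {CE: 0.30, NZ: 0.70}
    deprotonated: {CE: 0.10, NZ: -0.10}
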