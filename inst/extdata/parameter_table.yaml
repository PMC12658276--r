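# Charges and radii assigned to PDB input, which carries neither.
# radii: per-element, in Angstrom. charges: per (residue, atom), in e;
# atoms not listed default to 0. Titratable residues are listed in their
# default protonation form; the titration machinery replaces these by the
# site charge sets as needed.
radii:
  H: 1.10
  C: 1.70
  N: 1.55
  O: 1.52
  S: 1.80
  P: 1.80
  NA: 1.20
  CL: 1.80
  K: 1.50
  MG: 1.20
  CA: 1.40
  ZN: 1.10
charges:
  ASP: {CG: 0.60, OD1: -0.80, OD2: -0.80}
  GLU: {CD: 0.60, OE1: -0.80, OE2: -0.80}
  HIS: {CE1: 0.30, ND1: 0.00, NE2: -0.30}
  LYS: {CE: 0.30, NZ: 0.70}
  NA:  {NA: 1.00}
  CL:  {CL: -1.00}
  CA:  {CA: 2.00}
  MG:  {MG: 2.00}
  K:   {K: 1.00}
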