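# Two-state diabatic NaI model (Faist--Levine-type ionic + covalent diabats
# with a Gaussian coupling localized at the curve crossing), parameter values
# from the classic NaI quantum-dynamics literature. Every entry carries its
# unit explicitly; distances in the raw parameters are in angstrom, energies
# in eV. The constant diabatic transition dipole magnitude is a model choice
# (selection probabilities are normalized and insensitive to its scale); the
# default keeps a 0.001 au field well inside the weak-field regime.
format_version: 1
label: NaI
reduced_mass: {value: 19.463753, unit: amu}
ionic:
  A2:            {value: 2760.0,    unit: eV}
  B2:            {value: 2.398,     unit: "eV^(1/8) angstrom"}
  rho:           {value: 0.3489,    unit: angstrom}
  C2:            {value: 11.3,      unit: "eV angstrom^6"}
  lambda_plus:   {value: 0.408,     unit: "angstrom^3"}
  lambda_minus:  {value: 6.431,     unit: "angstrom^3"}
  delta_E0:      {value: 2.075,     unit: eV}
  e2:            {value: 14.399645, unit: "eV angstrom"}
covalent:
  A1:            {value: 0.813,     unit: eV}
  beta1:         {value: 4.08,      unit: "1/angstrom"}
  R0:            {value: 2.67,      unit: angstrom}
coupling:
  A12:           {value: 0.055,     unit: eV}
  beta12:        {value: 0.6931,    unit: "1/angstrom^2"}
  Rx:            {value: 6.93,      unit: angstrom}
transition_dipole:
  mu12:          {value: 0.1,       unit: au}
domain: {min: 2.0, max: 120.0, unit: bohr}
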