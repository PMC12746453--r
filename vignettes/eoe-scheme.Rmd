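---
title: "The electron-only explicit excitation scheme: model, assumptions, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The electron-only explicit excitation scheme}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Trajectory surface hopping (TSH) simulations of photochemistry need initial
conditions: nuclear phase-space points, an initial electronic state per
trajectory, and — if the exciting laser pulse is to be represented at all — a
start time. The common "vertical" scheme picks initial states from an energy
window with probabilities proportional to `f_osc / dE^2`, which ignores the
temporal and spectral structure of the pulse entirely. Including the laser
explicitly in every TSH trajectory is wasteful in the weak-field regime, where
almost no trajectory ever leaves the ground state.

The electron-only explicit (EOE) scheme implemented here is a two-step
compromise. First, for each sampled geometry the electronic time-dependent
Schroedinger equation is solved under the explicit pulse with *frozen nuclei*,
which requires only the vertical excitation energies and transition dipole
moments of a single-point calculation per geometry. Second, the resulting
time-dependent populations are renormalized and fed to a stochastic
surface-hopping-style selection that assigns each geometry an initial
electronic state and a start time, or rejects it. The subsequent TSH
trajectories are field-free; the laser enters only through the selection and
through time-shifting the trajectories by their start times during analysis.

## Electron-only dynamics

With nuclei frozen, the electronic Hamiltonian per geometry `k` is

```
H_k(t) = diag(E_k) + H_coupling - mu_k . E(t)
```

with constant energies, optional constant Hermitian couplings (e.g.
spin--orbit), and the electric-dipole interaction with the sampled field. The
propagator is a time-ordered product of short-time exponentials with the field
evaluated at each step midpoint (second-order accurate; field tables are
spline-interpolated at the midpoints because the carrier oscillates on the
scale of the step). The study step is 0.0625 fs with every eighth step stored,
so stored populations live on the 0.5 fs lattice of the downstream TSH step.
Static dipole moments are excluded by default (the dynamic Stark effect is
negligible for weak fields) and can be switched on; excited--excited
transition dipoles can likewise be excluded for response-method data.

For the bundled two-state models the ensemble propagation is vectorized across
all geometries with the closed-form exponential of a 2x2 Hermitian matrix —
identical mathematics to the per-geometry path (tested to 1e-12), which makes
the 10,000-geometry study ensemble a matter of seconds.

## Renormalized selection

Weak fields transfer a tiny fraction of population, so raw hopping
probabilities would accept almost nothing. The scheme computes, per geometry,
the per-step probability to leave the initial state
`P(t) = max(0, 1 - p_beta(t+dt)/p_beta(t))`, the total leave probability
`P_tot = 1 - prod_t min(1, ratio)`, and the global maximum `P_max` over the
ensemble. All excited populations are divided by `P_max`, and the
initial-state population is rescaled to keep the total at one. Two exact
consequences are used as invariant tests: per-step population differences
scale exactly by `1/P_max`, and `1 - P_max <= p_beta(t)` everywhere, so the
renormalized leave factor never changes sign.

Selection then sweeps every stored step of every renormalized trace, drawing
one uniform number per step from a stream keyed by `(seed, geometry)` —
geometries are therefore statistically independent and reproducible
regardless of ensemble composition. Hop probabilities out of the initial
state use the renormalized leave factor; after a hop the probabilities are
recomputed for the new active state with the plain global-flux expression
(the renormalization factors cancel there). Multiple hops are allowed: the
state of the *last* hop is the selected initial state, and a last hop back to
the initial state rejects the geometry. This matters physically: transitions
detuned from the carrier are populated transiently in the first half of the
pulse and depopulated in the second half; the second hop removes them. The
accepted `(energy, start time)` pairs consequently form the teardrop-shaped
distribution predicted by the closed-form coherently driven two-level model
(first-order perturbation theory + rotating-wave approximation), with the
on-resonance ridge peaking slightly after the pulse center and a triangular
late-time tail.

Because `P_max` rescales everything, the selection probabilities — and hence
the selected counts — are insensitive to the overall magnitude of the
transition dipole and of `E0` in the weak-field regime; we verified the count
ratios are unchanged across a factor of ten in the dipole scale. The bundled
default (0.1 au constant diabatic transition dipole, `E0 = 0.001` au) keeps
the strongest resonant transfer below about half a percent.

## Bundled models and the generator

The NaI model is the classic two-state diabatic picture: a Rittner-type ionic
diabat (Born--Mayer repulsion, Coulomb and induction/dispersion attraction,
offset by the Na ionization potential minus the I electron affinity), an
exponentially decaying covalent diabat, and a Gaussian diabatic coupling
centred at the crossing near 13.2 bohr where the adiabatic gap is twice the
coupling (0.11 eV). Parameters are read from a YAML file with explicit units;
the shipped values are the canonical set from the NaI quantum-dynamics
literature (equilibrium at 5.06 bohr, vertical gap 3.87 eV, absorption band
3.5--4.4 eV, upper-adiabat quasibound oscillation with a ~1 ps period and a
few-percent diabatic leak per crossing passage). The constant diabatic
transition dipole is a model choice whose magnitude cancels in all selection
probabilities; only the weak-field bookkeeping depends on it.

The harmonic fixture (two harmonic diabats, constant dipole, optional
displacement, zero coupling) exists because every downstream module has a
closed form against it: ground-state energy `omega/2`, width
`sqrt(1/(2 m omega))`, a Gaussian Wigner function with `sigma_R sigma_P =
1/2`, and the driven two-level dynamics of the oracle.

What the generator does *not* emulate: more than one nuclear dimension,
geometry-dependent transition dipoles away from the crossing, finite
temperature (sampling is from the 0 K ground-state Wigner function), and
incoherent/dephasing effects during excitation. Passing tests therefore
validate the scheme's mechanics and its agreement with exact quantum dynamics
for this model class, not its accuracy for fast Franck--Condon motion in
polyatomics, where the frozen-nuclei and fully coherent treatment are the
known limitations, stressed harder by longer pulses.

## Reference quantum dynamics and sampling

The grid reference uses 1024 points on 3--40 bohr. The ground state comes
from imaginary-time split-operator propagation of the coupled two-state
problem (default imaginary step 2 au, converged when the energy change per
step drops below 1e-12 hartree); real-time propagation is Strang-split with
the kinetic step spectral and the dipole--field coupling inside the potential
half-steps, the field evaluated at each half-step midpoint. There is no
absorbing boundary; edge density is monitored instead and warned about above
1e-6. Convergence of the S1-projected position mean
and width between (1024 points, 0.1 fs) and (4096 points, 0.01 fs) is at the
4e-5 angstrom level over a 500 fs window, two orders below the 0.01 angstrom
requirement; the test uses a 500 fs horizon to keep the run in minutes.

The Wigner transform is computed by FFT of the position-shifted
autocorrelation on the same grid. The discrete transform of the (numerically)
Gaussian ground state is positive to below 1e-10 provided the grid extends
far enough that the truncated tails are at machine level — with narrow
domains the truncation produces small negative ringing, which is why the
transform clips negatives before rejection-free inverse-CDF sampling and
records the clipped mass (essentially zero for all bundled states). Sampling
jitters uniformly within grid cells, which adds `dR^2/12` and `dP^2/12` to
the sampled variances; this is included in the test expectations and is
negligible at production grids.

## Surface hopping

Nuclear motion is velocity Verlet on the active adiabatic surface with
Hellmann--Feynman gradients; the default step is 0.5 fs with 25 electronic
substeps (0.02 fs). Electronic coefficients are propagated in the diabatic
frame along the linearly interpolated path — the exact limit of local
diabatization, since the overlap between consecutive adiabatic bases is the
product of the adiabatic-diabatic transformation matrices at both ends, and
the model's diabatic basis is globally defined. Coefficients were checked
against an independent adaptive ODE integration of the same path to 1e-6.

Hop decisions use the global-flux probabilities once per nuclear step with
the cumulative-interval rule. This is a deliberate, documented choice: the
selection step is defined through global-flux probabilities, and using the
same prescription inside TSH keeps the package self-consistent, even though
production surface-hopping drivers often use other fewest-switches
expressions. Accepted hops rescale the scalar 1D
velocity to conserve total energy (the general prescription of rescaling the
full velocity vector along its direction reduces to this in 1D); frustrated
hops leave the velocity unchanged and are counted, with no velocity reversal
— the simplest defensible convention, logged per trajectory. Energy-based
decoherence damps non-active amplitudes with time constant
`(1/|dE|)(1 + C/E_kin)`, `C = 0.1` hartree, renormalizing the active state;
it is applied after the hop decision by default, switchable to before, since
the bookkeeping order is a genuinely open convention. Eigenvector signs are
fixed (largest component positive, ties toward the first diabat) so
transformations are reproducible; all hop bookkeeping uses populations and is
sign-invariant.

Ensemble analysis shifts each trajectory by its start time and averages
position mean and width over trajectories currently in the upper adiabatic
state. With the low-energy 20 fs pulse, ~120-trajectory swarms reproduce the
expected ordering: the vertical-scheme width (~0.33 bohr time-averaged) is
far too narrow against the quantum-dynamics reference (~0.68 bohr), while the
EOE ensemble (~0.62 bohr) recovers most of the missing width because the
start-time spread dephases the swarm the way the finite pulse dephases the
wavepacket.

## Numerical choices worth knowing

- **Units.** Atomic units internally everywhere; fs and eV only at the user
  surface. `1 hartree = 27.2114 eV`, `1 au time = 0.02418884 fs`.
- **FWHM bookkeeping.** Pulses store the *field-envelope* FWHM; study widths
  (20/100/500 fs) are intensity FWHMs, converted by `sqrt(2)` on input. The
  two-level oracle uses `tau = FWHM_field / (2 sqrt(2 ln 2))`.
- **Envelope cutoff.** Field tables span where the envelope exceeds `1e-8 E0`
  ("effectively zero" made concrete), padded so the pulse center sits on the
  grid and each side is a multiple of the storage stride.
- **Complex error function.** The oracle evaluates
  `exp(-v^2)(1 + erf(u - iv))` through the Faddeeva function on the upper
  half-plane (Weideman's rational approximation, ~1e-13), with branch
  symmetry chosen so every exponential is bounded — stable out to reduced
  detunings of hundreds where naive `erf` overflows.
- **Time step bias.** The midpoint short-time exponential has O(dt^2) error:
  ~1.3% in transferred population at 0.0625 fs for a 4 eV gap, 0.08% at
  0.0156 fs. Renormalized selection cancels this common-mode bias; oracle
  comparisons are run at the converged step.
- **Random streams.** Every stochastic element (sampling, per-geometry
  selection sweeps, per-trajectory hopping) draws from its own stream keyed
  by a named seed, without touching the global RNG state. Selection draws are
  taken at every stored step, including steps with zero hop probability, so
  the stream stays aligned across variations.

## Known limitations

One nuclear dimension and two electronic states in the bundled models (the
selection and propagation code is N-state, exercised with three-state
fixtures in the tests); no chirped pulses, no magnetic-dipole or quadrupole
light--matter terms; no finite-temperature sampling; no decoherence
correction inside the electron-only step, so the selection inherits the fully
coherent teardrop rather than the pulse's Wigner distribution. The vertical
counts of the bundled NaI parameterization sit a few percent below the values
the original parameter tabulation would give; the parameter file is the
single place to swap in an alternative set.
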