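---
title: "Methods: ensemble Poisson–Boltzmann pKa calculations and pH-sensor analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble Poisson–Boltzmann pKa calculations and pH-sensor analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbpka)
```

## The physical model

A titratable side chain in a protein has its water pKa shifted by the
electrostatic work of charging it in the protein environment instead of
bulk water. `pbpka` estimates that shift from continuum electrostatics:
the potential solves the linearized Poisson–Boltzmann equation

$$\nabla\cdot(\varepsilon(\mathbf r)\,\nabla\varphi(\mathbf r))
  - \bar\kappa^2(\mathbf r)\,\varphi(\mathbf r) = -4\pi C \rho(\mathbf r),$$

with $\varphi$ in kcal/(mol·e), distances in Å, charges in e and
$C = 332.06$ kcal·Å/(mol·e²). Linearization truncates the Boltzmann
factor $e^{-x}$ of the mobile-ion distribution at first order; this is
accurate for $|z\varphi| \ll k_BT/e$ (≈ 27 mV, 0.62 kcal/mol at 310 K)
and *underestimates* the magnitude of the potential whenever that bound
is violated — salt bridges are the canonical offender.
`linearization_error_report()` quantifies this: for a typical
monovalent salt-bridge energy of −0.85 kcal/mol the first-order
approximation is 42% low, corresponding to ≈ 0.24 pKa units, falling to
18% and 6% at second and third order. The report is the package's own
error model for interpreting its results; the solver itself always uses
the linear form.

### Dielectric and screening maps

Five regions, with relative permittivities 1 (reference environment,
used for vacuum legs of Born-type checks), 4 (membrane hydrophobic
core), 8 (headgroup shells), 8 (protein interior) and 80 (solvent).
The protein region is the union of atom spheres at their input radii —
no solvent-probe reentrant surface and no Stern layer, since the
underlying protocol specifies neither; both could be added behind the
same map-building interface. The membrane is a slab whose geometry is
estimated *per frame*: midplane = mean z of the lipid terminal-methyl
carbons, total thickness = difference of the per-leaflet phosphorus
means, headgroup shells 2 Å thick immediately outside the core. Frames
without membrane markers legally produce a protein+solvent-only map,
so soluble proteins reuse the whole stack.

Mobile-ion screening ($\bar\kappa^2$, from a 1:1 electrolyte at 0.15 M
by default) acts in solvent voxels only; it vanishes inside protein and
membrane where mobile ions cannot penetrate. At 0.15 M the implied
Debye length is ≈ 7.9 Å. Ions *resolved in the frames* are different:
an implicit treatment misses their strong local fields, so ions within
3 Å of the protein (6 Å for divalents) are retained as explicit point
charges (`select_explicit_ions()`). The monovalent 3 Å default is kept
deliberately even though bound ions further away can still shift pKas;
the thresholds are plain arguments.

### Discretization and solver

7-point finite differences with harmonic-mean face permittivities;
charges spread trilinearly onto the 8 surrounding nodes; Dirichlet
boundary values are the summed Debye–Hückel monopole potentials of all
source charges. The interior system is symmetric positive definite and
is solved by Jacobi-preconditioned conjugate gradients (compiled code)
to a relative residual of 1e-6 within 10,000 iterations; failure to
converge is an error carrying the final residual. Focusing performs a
coarse solve over the whole system (1.5 Å default) and re-solves a box
around the site of interest (0.5 Å default) with boundary values
interpolated from the coarse potential; sources outside the focus box
enter only through those boundary values, which is exact for the
interior equation because their field is source-free there.

One numerical subtlety matters enough to name: **grid alignment**. The
energy of a trilinearly spread charge contains a large lattice
self-energy that depends on where the charge falls relative to the grid
nodes. All cycle legs are therefore *snapped* so that the site center
lies exactly on a lattice point of every grid involved; with identical
spacing and alignment the self-energy cancels exactly in the
protein-minus-water difference. A corollary: symmetry-equivalent
subunit copies of a site sit at different positions relative to the
*outer* box boundary, so their computed pKas agree only to within a
small discretization residue (≲ 0.05 units in the test systems) rather
than bit-exactly; identical frames of one site do reproduce exactly.

## The thermodynamic cycle

For site $s$ with protonated/deprotonated group charge sets (differing
by exactly +1 e, localized on the functional-group atoms and shipped as
replaceable YAML data):

$$\mathrm pK_a = \mathrm pK_{a,\mathrm{ref}} +
  \frac{(G_d - G_p)_{\mathrm{protein}} - (G_d - G_p)_{\mathrm{water}}}
       {\ln 10 \cdot k_BT}.$$

Each leg is decomposed as a reaction-field self term (solve with the
group charges only, in the full dielectric map) plus an interaction
term (group charges times the potential of every *other* charge,
computed once per site and shared between the two states). The water
leg is the excised residue keeping its own low-dielectric cavity,
surrounded by pure solvent on an identically spaced, identically
aligned grid. A literally homogeneous ε = 80 water leg was rejected:
without the cavity the lattice self-energy no longer cancels and the
pKa would diverge with grid refinement; the cavity form is the standard
model-compound construction and is the only one under which cycle
closure (isolated compound → pKa = reference) holds, which it does here
to machine precision.

During a single evaluation all *other* titratable sites carry the
charge set of the current protonation assignment — single-site
evaluation, not coupled multi-site statistical mechanics. The coupled
problem is retained only as the exhaustive microstate oracle
(`microstate_titration_oracle()`, ≤ 3 sites), the independent reference
against which the engine is validated: on a Glu–Lys pair 8 Å apart in
water the full pipeline and the oracle agree to < 0.05 pKa units.

Ensemble estimates average over frames and equivalent subunits
(5 frames × 3 subunits = n 15 for a trimer at the default frame labels
0, 2, 4, 6, 8), with failed samples dropped, warned about, and n
reduced.

## The iterative protocol

Round 1 uses the default assignment: Asp/Glu deprotonated, His in its
neutral ε-tautomer (the δ/ε choice only affects which charge set the
YAML names as the deprotonated form), Lys protonated. After each round,
every currently-deprotonated Asp/Glu/His with mean pKa above the
state's relevant pH (7.4 closed, 5.5 open and desensitized) is switched
to protonated, and every currently-protonated Lys below it to
deprotonated. Two readings of "the residues with the highest calculated
pKa" are possible; the default switches *all* qualifying residues per
round, and `switch_mode = "one"` provides the conservative
one-per-round alternative. Adjusted sites are frozen — not re-evaluated
— and the value reported for them is the table of the round immediately
preceding their adjustment; never-adjusted sites report the final
round. Freezing makes oscillation impossible by construction, but the
`max_rounds` guard (default 10) still returns `converged = FALSE`
rather than erroring if the provider itself is unstable.

The MD engine is replaced by a provider seam: any function mapping an
assignment to a `frame_ensemble` (a directory loader over PQR files and
the synthetic jitter generator ship with the package).

## Sensor analysis choices

The published ranking combines two criteria without printing a formula;
this package defines it explicitly: criterion 1 is a flag (both state
pKas inside [5, 8], or straddling it), criterion 2 is |ΔpKa| min–max
scaled across the analyzed residues, and the score is their weighted
sum with unit weights by default. The definition is validated against
the single available anchor (the known top-ranked residue wins on a
table containing its values among in-range distractors) and is
configurable; it is an interpretation, not a transcription.

Protonation fractions are evaluated at five (structure, pH) conditions:
closed/7.4, closed/6.0, open/6.0, closed/6.8, desensitized/6.8. A
residue is a candidate *driver* of a transition if |Δf| ≥ 0.15 between
rest and the acidified closed state, a *stabilizer* if |Δf| ≥ 0.15
between rest and the end-state condition; deprotonation counts through
the absolute value, and both labels can hold at once. The 0.15
threshold is the published arbitrary limit and is an argument.

## Functional analysis choices

Activation curves fit
$I = I_{max}/[1 + (10^{-\mathrm{pH}_{50}}/10^{-\mathrm{pH}})^{n_H}]$;
steady-state desensitization uses the same form mirrored so that the
response *falls* as the conditioning pH falls (an availability curve),
with the midpoint reported as pHD50 — the concrete reading of "an
analogous equation". Fits use Levenberg–Marquardt with the half-max
crossing as the pH50 start, $n_H = 1$, $I_{max} = \max$ response, and
box constraints $n_H \in (0.05, 10]$; a flat curve is an error, and
< 5 points are refused. Effect bins on |ΔpH50| are [0.08, 0.2), [0.2,
0.3) and ≥ 0.3 with closed lower edges exactly as printed;
"functionally important" means |ΔpH50| ≥ 0.2 or |ΔpHD50| ≥ 0.15.
Mutant-cycle coupling is Δ(AB) − [Δ(A) + Δ(B)] with quadrature SE and a
z = 1.96 additivity verdict. Property regressions are OLS of pH50 (or
pHD50) on one of 12 side-chain scales, raw two-sided slope p-values (a
Holm flag exists but is off, matching the published reporting), minimum
panel size 4 — the published text says "more than four" but its own
result tables include 4-variant panels, so ≥ 4 is the operative default
and it is configurable. The numeric scale values are transcribed from
the standard published scales named in the data file header
(Kyte–Doolittle, Zimmerman, Chou–Fasman, Deléage–Roux,
Bhaskaran–Ponnuswamy, Zamyatnin, Chothia, IMGT-style H-bond counts) and
are deliberately data, not code.

## What the synthetic generator does and does not emulate

`make_toy_membrane_system()` builds side-chain fragments with the
package's charge sets, uncharged zero-radius membrane marker atoms (so
slab geometry is testable independently of electrostatics), fixed
background charges and explicit ions; `jitter_frames()` emulates
snapshot ensembles by zero-mean Gaussian coordinate noise (default
amplitude 0.1 Å, roughly the sub-Å heavy-atom fluctuation of a short
restrained relaxation; frame 0 unperturbed). Everything is
bit-reproducible from (spec, seed).

What passing tests on these systems shows: the solver reproduces
closed-form electrostatics (Coulomb within 0.8%, screened Coulomb
within 1.1%, Born solvation within 5% at 0.5 Å), the cycle closes, the
engine matches exhaustive statistical mechanics on coupled pairs, and
the iteration bookkeeping is exact. What it does not show: accuracy of
real force-field charge sets, conformational reorganization on
protonation (frames are rigid inputs here), lipid chemistry beyond a
slab, or agreement with experimental pKas of real proteins — those
require real ensembles upstream.

## Numerical parameters and test problem sizes

Defaults: region permittivities 1/4/8/8/80; focusing 1.5 → 0.5 Å;
coarse padding 10 Å; fine box 12 Å; CG tolerance 1e-6, max 10,000
iterations; ionic strength 0.15 M; T = 310 K with
$k_BT = 0.0019872\,T$ kcal/mol. One deliberate inconsistency is
surfaced rather than hidden: the protocol's stated temperature is
310 K, but its printed worked-example numbers (4.207, −0.852 kcal/mol)
are only consistent with $k_BT = 0.593$ kcal/mol (≈ 298 K) and
$\varepsilon_r = 78$; both temperature and $k_BT$ are therefore
explicit configuration, and the worked-example reproduction passes
$k_BT = 0.593$ while the thermal-scale constants use 310 K.

The test and validation suites run on small boxes (single fragments to
two-site pairs, grids of 20–90 nodes per axis, single-pass 1.2 Å solves
where only bookkeeping is under test and 1.5 → 0.5 Å focusing where
accuracy is), chosen so the full suite completes in well under a minute
while still exercising every code path at the production spacings.

## Known limitations

* Linearized PB only; the package reports the induced error but cannot
  remove it. Nonlinear solves are out of scope.
* Sphere-union molecular surface; no reentrant surface, no Stern layer.
* Single-site titration with fixed partners; coupled titration exists
  only as the ≤ 3-site oracle.
* The slab membrane has no curvature, deformation or lipid-specific
  dielectric profile.
* Symmetry-equivalent subunits agree only to the grid-placement residue
  described above; report SDs accordingly.
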