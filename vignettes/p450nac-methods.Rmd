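---
title: "Models and methods in p450nac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in p450nac}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p450nac)
```

This vignette is the package's own account of what it computes, which
choices were genuinely open, and what the synthetic-data tests do and do not
establish about real data.

## Near-attack conformations

P450 hydroxylation begins with abstraction of a substrate hydrogen by the
electrophilic ferryl oxygen of the compound I intermediate. Whether a given
carbon position can react is therefore largely a geometric question, and a
standard way to quantify it over a trajectory is to count *near-attack
conformations*: frames in which a hydrogen sits within van der Waals contact
of the ferryl oxygen with the reacting atoms near their transition-state
arrangement. In this package a site — one or more chemically equivalent
hydrogens plus their bonded carbon, e.g. the three C21 methyl hydrogens —
is NAC in a frame iff **any** equivalent hydrogen has

$$ d(\mathrm{H\cdots O}) < d_\max
   \quad\text{and}\quad
   |\theta(\mathrm{C{-}H\cdots O}) - \theta_{\mathrm{ref}}|
   \le \theta_{\mathrm{tol}}. $$

Tunable parameters, defaults, and why:

* `d_max = 2.72` Å. "Van der Waals contact" needs a radii convention; we use
  Bondi radii, r(O) 1.52 + r(H) 1.20 Å. Configurable because other radii
  tables shift this by ~0.1 Å.
* `theta_ref = 180`°. Hydrogen abstraction by oxo species is modelled as
  near-linear C–H···O transfer in QM studies of P450 chemistry; published
  transition-state geometries for a specific enzyme/substrate pair may
  prefer a slightly bent reference, so the value is explicit, not baked in.
* `theta_tol = 20`°, the customary tolerance for NAC counting.
* One angle is scored. NAC definitions sometimes add further angles (e.g.
  Fe–O–H); the criterion object scores the C–H···O angle of the three
  reacting atoms and additional constraints are treated as an extension
  point rather than a default, since multiple-angle conventions vary.

Equivalent hydrogens combine by any-satisfies for classification and by
minimum distance for traces, matching the convention that with several
identical hydrogens only the shortest distance is shown per time point.
Ties between equally close hydrogens break to the lowest roster index for
determinism. Geometry is evaluated on every frame supplied; no distinction
is made between an engine's on-the-fly recording rate and its snapshot
export rate — the trajectory you load is the data.

The per-site NAC percentage is $100 \cdot n_{\mathrm{NAC}}/n_{\mathrm{frames}}$.
It is invariant under rigid motion of frames and monotone non-decreasing in
both `d_max` and `theta_tol`; both properties are tested.

## Water intrusion and mobility

Uncoupling (loss of activated oxygen to water) correlates with solvent
reaching the ferryl oxygen. `nearest_water_trace()` reports, per frame, the
closest water oxygen and a hydrogen-bond flag. Criteria are the common
geometric ones — O···O distance ≤ 3.5 Å and, when the winning water's
hydrogens are in the roster, an O–H···O angle ≥ 120° — because studies often
assert H-bonding without printing thresholds; both are parameters and are
recorded as attributes on the output.

Substrate mobility is measured as RMSF about the trajectory-mean position,
optionally after Kabsch-fitting each frame to frame 1 over a reference atom
set (typically protein Cα). The mean-position reference and frame-1 fitting
reference are the standard choices; for isotropic Gaussian jitter of
standard deviation σ per axis the expected RMSF is σ√3, which the tests use
as a closed-form oracle (σ = 0.5 Å → 0.866 Å at 20 000 frames, 3 %
tolerance).

## Superposition and structure comparison

Rigid superposition solves the orthogonal Procrustes problem by SVD of the
cross-covariance with a determinant guard so reflections are never returned
(`kabsch()`), and is verified in tests against an independent Horn
quaternion-eigenvalue implementation and against `bio3d`'s fitter. Cα atoms
of two complexes are paired by (chain, residue number) — appropriate for
crystal forms of the same protein, where sequence alignment would be
overkill — with alternate locations other than blank/`A` dropped at parse
time, waters excluded, and the heme kept only as context (it has no Cα and
never enters the RMSD). Ligand correspondence distances are measured after
superposing one protein onto the other, so they inherit the mapping
convention.

## Tight-binding titration analysis

Substrate binding displaces the heme's axial water and shifts the Soret band
(type I shift); the titration signal is ΔA = A(386) − A(420) versus total
ligand. With 3 µM enzyme, dissociation constants of interest range from
below 1 nM to a few µM, so the free-ligand (Langmuir) approximation fails
and the fit uses the exact single-site quadratic ("Morrison") solution. The
Methods-style probe pair 386/420 nm is the default; a 390/420 pair is
available by argument since the high-spin maximum is often quoted as
"approximately 390 nm".

Numerical choices:

* Weighted least squares via constrained Levenberg–Marquardt
  (`minpack.lm::nlsLM`); replicates at a ligand concentration are averaged
  and their pooled variance feeds the weights (unit weights otherwise).
* K_D is bounded below by 10⁻⁶ µM (0.001 nM) rather than 0: at exactly
  K_D = 0 the model's discriminant kinks at L = E and the gradient matrix is
  singular; the bound is far below anything measurable.
* `no_shift` status when max|ΔA| stays under a noise floor, defaulting to 3×
  the replicate standard deviation at L = 0 (3 mAU when no replicates
  exist).
* `upper_bound_only` status when the profile-likelihood F-test cannot reject
  K_D = 0: the profile RSS over K_D (with ΔA_max solved analytically) is
  compared at the 95 % level, and the reported upper limit is where the
  profile crosses the threshold — the "K_D < x nM" reporting style. The
  residual variance is floored at (10⁻⁴ AU)², the scale of spectrophotometer
  resolution, so that noiseless synthetic series are still classified
  sensibly instead of the F-test becoming infinitely sensitive.
* Identifiability: with E = 3 µM, a 12-point grid to 150 µM and 1 %
  multiplicative noise, the median relative K_D error stays within 25 % for
  K_D between 50 and 5000 nM (tested over 100 seeds per value); K_D of
  order 1 nM is unidentifiable at these concentrations and is flagged, not
  estimated.

High-spin content is estimated by non-negative least-squares unmixing of a
low-spin and a high-spin basis spectrum; with only two components the NNLS
reduces to an unconstrained solve plus boundary comparison. How published
"roughly 50 %" figures were obtained is typically unstated; linear unmixing
is this package's choice and is exact on noiseless mixtures.

## Turnover and coupling calculators

TON is defined as µmol substrate consumed per µmol P450 per minute over the
window of highest consumption rate. Rather than two-point differences, every
contiguous sample window spanning at least `window_min` (default 120 min,
matching the usual "fastest within the first 2–3 h" observation) gets a
least-squares slope and the steepest negative slope wins; this is robust to
sampling noise while honouring the highest-observed-rate rule. Monotonically
rising "substrate" clamps TON to 0 with a `no_consumption` flag rather than
reporting a negative number.

Coupling efficiency is 100 · substrate converted / NADH consumed. The
underlying assay consumes a known NADH pool completely and measures
conversion afterwards, so the generator emulates the two measurements as
separate quantities: an A₃₄₀ trace that decays to zero and an endpoint
conversion consistent with the planted ratio. Values above 100 % are
reported but flagged as stoichiometrically implausible. Beer–Lambert
helpers use ε₃₄₀(NADH) = 6.22 mM⁻¹cm⁻¹, ε(cytochrome c) = 19.1 mM⁻¹cm⁻¹ at
the 550 nm readout (the literature pairing of that value with a "450"
subscript is internally inconsistent; the stated value is used at the stated
wavelength), and ε(CO difference) = 91 mM⁻¹cm⁻¹ (Omura–Sato), all
configurable.

## The synthetic-data generators

The generators define the study conditions under which the package is
verified; they are deterministic functions of their spec (seed included).

* `gen_reactive_trajectory()` plants, per site, an exact count
  `round(fraction × n_frames)` of NAC frames (sampled without replacement).
  A planted frame places one equivalent hydrogen with d uniform in
  [1.8 Å, d_max(1−margin)] and angle within θ_tol(1−margin) of θ_ref; every
  other hydrogen — and all hydrogens of unplanted frames — is
  rejection-sampled on a 1.09 Å sphere around the site carbon until both
  criteria are violated by at least the margin (default 10 %). The margin
  band means no generated geometry sits near a threshold, so planted labels
  are robust to floating-point noise, and the exact-count plant makes
  percentages equal the request exactly rather than binomially. Waters park
  at 7 Å (the distance at which a well-packed active site holds solvent
  away) unless scheduled to approach, and carry one hydrogen aimed at the
  acceptor so close approaches also hydrogen-bond.
* `gen_titration()` uses the titration design: 3 µM enzyme, 12
  concentrations from 0 to 150 µM, duplicates, 1 % multiplicative noise.
* `gen_timecourse()` plants a steep phase of slope −TON·[P450] inside a
  window (default 60–180 min of a 0–360 min course sampled every 15 min,
  2 mM substrate, 3 µM P450) and an NADH record consumed to completion with
  the planted coupling ratio.
* `gen_complex_pair()` perturbs a 3.8 Å-step random Cα scaffold and
  rescales the perturbation through a short calibration loop until the
  minimized RMSD matches the target within 2 %, then applies a random rigid
  motion; ligand atoms are placed at a requested post-alignment offset.

What passing these tests shows: the estimators recover planted truth under
controlled geometry, noise and sampling. What they do not show: anything
about force fields, sampling adequacy, spectral baselines, or chromatography
— the generators make no attempt at physical dynamics (no bonded structure
beyond the scored atoms, no solvent box, no autocorrelation between frames),
and real NAC percentages depend on the QM reference angle and radii
convention chosen. Published NAC tables from undeposited trajectories are
therefore treated as layout and behaviour templates, not as numeric oracles.

## Problem sizes and interfaces

The shipped test suite runs the full study-condition sizes: 10 000-frame
plants for percentage recovery, 20 000 frames for the RMSF closed form, 100
seeds per K_D for recovery medians, 50 seeded time courses, 200-water frames
against exhaustive nearest-neighbour oracles, and 100 random point-cloud
pairs against the quaternion oracle. Everything completes in well under a
minute on a single core.

This is an analysis package, not a shell tool: the exported functions are
the interface, `scripts/acceptance.R` reproduces the headline numbers from
the command line, and trajectories exchange via multi-model PDB (read) and
a lossless frame-table CSV dialect (read/write,
`frame,serial,name,element,resname,resnum,chain,x,y,z[,time_ps]`) for
fixtures and interchange. Plot helpers (`plot_distance_trace()`,
`plot_water_trace()`, `autoplot()` on fits, `plot_timecourse()`,
`plot_rmsf()`) return ggplot objects.

## Known limitations

* No binary trajectory formats (DCD/XTC/TRR) and no mmCIF; convert upstream.
* NAC scoring uses explicit site definitions; abstractable hydrogens are not
  detected from connectivity.
* Cα mapping assumes shared residue numbering; divergent constructs would
  need an alignment step the package deliberately omits.
* The tight-binding fit is single-site; cooperative (Hill) binding is out of
  scope.
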