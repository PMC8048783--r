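# p450nac

Analytics for cytochrome P450 steroid-hydroxylation studies: geometric
reactivity scoring of MD-style trajectories around the compound I
intermediate, plus the spectroscopic and kinetic assay calculations that
accompany such studies.

## Who this is for

Groups studying P450 regioselectivity (e.g. CYP154C5-type bacterial steroid
hydroxylases) typically combine four kinds of evidence: molecular-dynamics
snapshots of the enzyme–substrate complex in its reactive (ferryl,
compound I) state; type-I spin-shift titrations of substrate binding;
NADH-driven turnover and coupling measurements; and crystal-structure
comparisons of the complexes. This package implements the shared
computations behind all four, with tidyverse-style data-frame interfaces and
a seeded synthetic-data module so every stage is testable without large
trajectory or spectral files.

## What it computes

**Near-attack conformations (NACs).** The first chemical step of P450
hydroxylation is hydrogen abstraction by the ferryl oxygen of compound I. A
trajectory frame counts as a NAC for a site (a set of chemically equivalent
substrate hydrogens and their bonded carbon) when any equivalent hydrogen
satisfies

    d(H···O) < d_max        and       |θ(C–H···O) − θ_ref| ≤ θ_tol

with defaults d_max = 2.72 Å (Bondi van der Waals contact of O and H),
θ_ref = 180° (near-linear abstraction) and θ_tol = 20°. The per-site NAC
percentage over a trajectory is the headline reactivity statistic; the
package also produces shortest-distance traces (minimum over equivalent
hydrogens at each time point), nearest-water distance traces with
hydrogen-bond flags (uncoupling diagnostics), and substrate RMSF mobility
profiles.

**Tight-binding titrations.** Type-I difference signals
(ΔA = A(386 nm) − A(420 nm)) versus total ligand L are fitted with the
quadratic tight-binding (Morrison) equation

    ΔA(L) = ΔA_max · [ (E + L + K_D) − √((E + L + K_D)² − 4·E·L) ] / (2·E)

which is exact when K_D is comparable to the enzyme concentration E.
Fits flag `no_shift` series and report `upper_bound_only` ("K_D < x nM")
when the profile-likelihood lower limit of K_D reaches zero. High-spin
fractions are estimated by non-negative unmixing of low-spin/high-spin basis
spectra.

**Turnover and coupling.** Turnover numbers (TON, µmol substrate consumed
per µmol P450 per minute) are taken from the steepest least-squares window
of a substrate time course; coupling efficiency is
100 · substrate converted / NADH consumed, with Beer–Lambert helpers for
NADH (ε₃₄₀ = 6.22 mM⁻¹cm⁻¹), cytochrome c reduction activity
(ε = 19.1 mM⁻¹cm⁻¹) and P450 CO-difference quantification (ε = 91 mM⁻¹cm⁻¹).

**Structure comparison.** Cα atoms of two complexes are paired by
chain/residue number, superposed by the Kabsch SVD method (proper rotations
only), and reported as minimized RMSD; ligand-atom correspondence distances
(e.g. C15 of one steroid vs C16 of another) are measured after protein
superposition.

## Worked example

```r
library(p450nac)

# a seeded trajectory with planted NAC fractions: 22 % at 16a, 7 % at 21
gen <- gen_reactive_trajectory(reactive_trajectory_spec(
  n_frames = 10000,
  sites = list(list("16a", 1, 0.22), list("21", 3, 0.07)),
  seed = 102))
nac_percentages(gen$trajectory, gen$criterion)
#> # A tibble: 2 × 4
#>   site  nac_frames total_frames nac_percent
#>   <chr>      <int>        <int>       <dbl>
#> 1 16a         2200        10000          22
#> 2 21           700        10000           7

# titration at the wild-type/progesterone-like scale
fit <- fit_tight_binding(gen_titration(titration_spec(
  kd_nM = 209, noise_sigma = 0, replicates = 1, seed = 1))$series)
fit
#> <binding_fit> status: ok
#>   K_D = 209.0 +/- 0.0 nM, dA_max = 0.1 AU
```

The NAC table reads: of 10 000 frames, 2 200 put a 16a hydrogen inside the
geometric criterion (22 %), so abstraction at C16 is sterically favoured
over the C21 methyl (7 %). The fit recovers the planted dissociation
constant exactly on noiseless input.

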