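---
title: "Methods: redox potentials and hole delocalization in ds-DNA ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: redox potentials and hole delocalization in ds-DNA ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsredox)
```

## The problem

One-electron oxidation of double-stranded DNA creates a positive vacancy (a
hole) whose thermodynamics and spatial distribution control charge transfer
along the helix. Two ensemble-level quantities describe this: the
one-electron oxidation potential of the duplex, and the number of
nucleobases over which the hole spreads. Both are ensemble averages over a
conformational trajectory — a single optimized structure is not
representative — and both are expensive when each snapshot requires an
electronic-structure calculation. This package implements the ensemble
analysis stage: Marcus-theory redox statistics from vertical energy gaps,
hole-distribution and delocalization indices from per-base charge
differences, and RMSD-clustering diagnostics that quantify how few
representative conformations suffice.

The package analyzes 12-bp model duplexes `ds-poly(XY-X'Y')`: a
dinucleotide `XY` repeated six times with its exact Watson–Crick
complement. Charges and holes are analyzed over an 8-base region (the
central four bases of the 5'→3' strand plus their partners), mirroring the
QM region such calculations typically afford.

## Marcus linear-response redox statistics

Within linear response, the oxidation free energy is the mean of the two
vertical energy gaps, sampled on the neutral-state ensemble (the vertical
ionization energy, VIE) and on the cation-state ensemble (the vertical
attachment energy, VAE):

$$\Delta G_\mathrm{ox} = \tfrac{1}{2}\left(\langle \mathrm{VIE}\rangle +
\langle\mathrm{VAE}\rangle\right), \qquad
E_\mathrm{ox} = \Delta G_\mathrm{ox}/e - E_\mathrm{SHE},\qquad
\lambda = \tfrac{1}{2}\left(\langle \mathrm{VIE}\rangle -
\langle\mathrm{VAE}\rangle\right).$$

Conventions that matter:

* **Sign.** Both gaps are stored cation-minus-neutral, so mean VIE and VAE
  are positive and $\Delta G_\mathrm{ox}$ is their direct average. A
  negative mean VIE is rejected as a probable sign error rather than
  silently flipped.
* **Electrode.** `reference_electrode()` defaults to an absolute SHE
  potential of 4.28 V. That literature value already contains the gas-phase
  free energy of the electron, which is why no explicit electron term
  appears above; because several absolute SHE values circulate, the value
  is a parameter, not a constant.
* **Spread.** The SD of $E_\mathrm{ox}$ is propagated as
  $\sqrt{s_\mathrm{VIE}^2 + s_\mathrm{VAE}^2}/2$, treating the two
  trajectories as independent simulations — the defensible default given
  that they are separate runs. $\lambda \ge 0$ is a physical expectation,
  so a violation warns instead of failing.

## Hole distributions and delocalization numbers

For each snapshot, the hole fraction on base $i$ comes from the per-base
charge difference $\Delta q_i$ between the post- and pre-ionization
electronic state at the same geometry. Population analyses can yield
slightly negative $\Delta q_i$ on spectator bases, and part of the unit
charge leaks outside the 8-base region; the package therefore clamps
negative differences to zero (logging the discarded mass) and renormalizes
the remainder to 1 over the analysis region. Both choices are explicit
outputs (`clamped_mass`, `raw_sum`) rather than silent conventions.

Two indices summarize a distribution $q$:

* the **empirical delocalization number** $n$: the bases are ordered by
  increasing hole charge and the effective number of occupied bases
  $n = \exp(-\sum_i q_i \ln q_i)$ is evaluated — 1 when the hole sits on a
  single base, 8 when it is uniform;
* the **participation number** $n' = 1/\sum_i q_i^2$, a Pipek–Mezey-style
  index adapted to per-base charges, with the same endpoints.

$n' \le n$ holds for every distribution (monotonicity of Rényi effective
numbers in the order), so the participation index reading lower than the
empirical count is a structural property here, not an empirical accident.
Both indices are invariant to base order and to uniform rescaling of the
charge differences, and both are Schur-concave: concentrating hole mass
can only lower them. These invariances are enforced by property tests.

## Clustering and representative-structure estimation

Frames are compared by minimum RMSD after least-squares rigid-body
superposition (Kabsch algorithm with the reflection-excluding determinant
correction). Clustering is average-linkage hierarchical agglomeration on
the pairwise superposed-RMSD matrix, cut at $k$ clusters — deterministic
and seed-free, which keeps every downstream diagnostic exactly
reproducible. Each cluster is represented by its **medoid** (the member
minimizing summed RMSD to co-members): under superposition ambiguity a
coordinate average is not a valid conformation, so the medoid stands in
for "the configuration closest to the centroid". A property $A$ is then
estimated from representatives only,

$$\hat A_k = \sum_{i=1}^{k} P(i)\, A(\mathrm{rep}_i),$$

with $P(i)$ the fraction of frames in cluster $i$. At $k$ equal to the
frame count this identity collapses to the plain ensemble mean, which the
tests check to $10^{-12}$.

The convergence scan evaluates $\hat A_k$ for $k$ on a grid (default
2–10) for five properties — VIE, VAE, $E_\mathrm{ox}$, and the
delocalization numbers of both trajectories — and reports the relative
unsigned error against the full-ensemble reference,
$\mathrm{RUE}_k = |\hat A_k - A_\mathrm{ref}|/|A_\mathrm{ref}|\times 100$.
Definitions that had to be pinned down:

* **Converged k**: the smallest grid point whose estimate moved less than
  the per-property tolerance from the previous grid point (defaults:
  0.05 eV for VIE/VAE, 0.02 V for $E_\mathrm{ox}$, 0.05 for $n$). The
  first grid point has no predecessor, so convergence can be declared at
  the second point at the earliest. Without explicit tolerances
  "converged" would be ill-defined, so they are parameters.
* **MRUE**: the mean RUE over the converged window
  $[k_\mathrm{conv}, k_\mathrm{max}]$ is the headline; the RUE at the
  converged k is reported alongside, since either reading is a reasonable
  construction of a convergence figure. A property whose reference is
  exactly zero has no relative error; it is reported missing with a
  warning rather than as an infinity.

## The synthetic ensemble generator

No deposited trajectories exist for this analysis, so the package ships a
seeded generator whose output has the same statistical structure as MD +
QM/MM snapshot ensembles, with closed-form ground truth
(`ground_truth()`) for every downstream estimate. It emulates four
features of the real data:

1. **Multi-basin conformational heterogeneity.** Each frame draws a latent
   basin (default three, weights 0.5/0.3/0.2) shifting the vertical
   energies by −0.2/0/+0.3 eV. Because superposed RMSD is exactly
   invariant to rigid motions, basins are realized as *internal*
   deformations — per-basin offsets of the helical rise (axial stretch,
   spacing 0.6 length units) on an ideal-helix pseudo-atom template
   (3 pseudo-atoms per base, rise 3.4, twist 36°), plus a continuous
   within-basin stretch mode and isotropic per-atom jitter (0.05). A
   rigid-body "displacement" would be invisible to the clustering it is
   meant to exercise.
2. **Base-type-dependent hole affinity.** Hole site energies order
   G < A < C ≈ T (0, 0.25, 0.55, 0.55 eV), smeared through a
   Boltzmann-like weight at `t_eff` = 0.12 eV. The same site energies
   shift the mean vertical gaps of a system by the free energy of the
   hole, $-t_\mathrm{eff}\ln\sum_i e^{-\epsilon_i/t_\mathrm{eff}}$, so
   guanine-rich duplexes are easier to oxidize — the composition effect
   the analysis is supposed to resolve.
3. **Stacking enhancement of delocalization.** Bases in same-strand
   adjacent purine–purine pairs get a small site-energy bonus (0.05 eV)
   and, crucially, a doubly stochastic hole-sharing step (`stack_mixing`
   = 0.15) that symmetrically mixes population within each stacked pair.
   Doubly stochastic mixing can only raise both delocalization indices
   (Schur concavity), which makes "stacked > diagonal" a structural
   consequence rather than a tuned accident. A site-energy term alone
   cannot produce this ordering: for the homopurine presets the stacked
   and diagonal arrangements have four symmetry-equivalent purine sites
   either way, and a uniform energy shift cancels in the softmax.
4. **Basin-specific hole trapping.** Each basin carries a trapping
   potential — a focal base pair (non-degenerate positions 5.3/7.6/6.4)
   with slope 0.75 eV per base-pair step and a 0.22 eV penalty on the
   non-preferred strand — so the hole localizes on one or two purines per
   basin, giving ensemble delocalization numbers in the 1.4–2.3 range
   typical of ds-DNA instead of the unphysical 3–4 that symmetric site
   energies alone would produce.

Energies couple to geometry: a fraction `geom_coupling` = 0.98 of the
within-basin energy variance (total SD 0.15 eV) rides on the same
collective stretch coordinate that deforms the geometry, and only the
remainder is environment noise invisible to RMSD. This mirrors the real
pipeline, where the vertical gap is a deterministic function of the
snapshot geometry up to solvent/MM-environment effects — it is exactly
this coupling that makes representative-structure estimation work at all.
The per-base charge noise (`charge_noise` = 0.12 in units of `t_eff`)
plays the analogous residual role for the hole distribution. These
defaults were fixed once, by checking the generator's qualitative
structure (delocalization band, stacked-diagonal gaps, guanine ordering of
$E_\mathrm{ox}$, few-percent cluster-representative errors) against what
ds-DNA ensembles are known to look like, and are not adjusted per run.

Cation-state charges are emitted as neutral-state charges plus the hole
fraction scaled by `1 - leakage` (default 0.05), so the downstream
renormalization path is genuinely exercised instead of receiving
pre-normalized input.

What the generator does **not** emulate: real electronic-structure charges
(no orbitals, no polarization), solvent dynamics, sequence-context
chemistry beyond the site-energy/stacking/trap terms, base-pair
mismatches, or anharmonic basin shapes. Tests passing on synthetic data
therefore validate the *analysis machinery* — estimators, invariances,
clustering, error propagation — not the quantum chemistry of any specific
duplex.

## Numerical choices

* Ties in the oxidation-potential ranking keep input order (stable sort).
* RMSD uses the SVD closed form with clamping of the (numerically)
  slightly negative mean-square deviations that exact superposition can
  produce; identical frames give exactly 0.
* Hole fractions below machine negativity (−10⁻¹²) fail validation;
  clamping applies only to genuinely negative charge differences.
* Snapshot tables are tab-separated UTF-8 with '.' decimals and six
  decimal places (1 µeV / 1 µe round-trip precision); PDB coordinates
  carry the standard three decimals, XYZ six. Frame alignment between
  table and coordinate file is positional with an explicit count check.
* All randomness derives from one integer seed; per-(system, state)
  sub-seeds keep trajectories independent yet bit-reproducible, and the
  RNG state of the caller is restored after every draw.

## Problem sizes used by the test suite

The suite exercises 200-frame ensembles for the six presets (the study
condition), 5000-frame ensembles for parameter-recovery checks of the
$1/\sqrt{n}$ error scaling, 9–12-frame toys for exhaustive-enumeration
clustering oracles, and 4-point toys for the brute-force rotational-search
RMSD oracle. These sizes were chosen so the full suite exercises every
claim at comfortably verifiable scale.

## Known limitations

* The delocalization indices are intermolecular only; within-base
  (atomic-level) delocalization is out of scope.
* The Marcus treatment is linear-response: no free-energy perturbation,
  no temperature dependence, one-electron processes only.
* Average-linkage clustering is one defensible choice among several; the
  exhaustive-enumeration oracle guarantees optimal-dispersion partitions
  only on well-separated small sets, which is the regime the diagnostics
  target.
* The generator's ground-truth delocalization values are exact only for
  the zero-noise configuration; with noise switched on, ensemble means of
  the nonlinear indices differ from the zero-noise values by design.
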