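---
title: "Methods: reconstructing squid life history from beak isotope trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconstructing squid life history from beak isotope trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beaktraj)
```

## The measurement model

A cephalopod upper beak grows by posterior accretion, and its tanned chitin
is metabolically inert once deposited.  Sequential subsections along the
crest — indexed 1 (rostrum tip, oldest material) to S (posterior edge,
newest) — therefore carry an ordered record of δ¹³C (habitat / carbon
source) and δ¹⁵N (trophic position) over the individual's life.  The
package's canonical data structure is one tidy row per individual ×
subsection; unanalysed subsections are retained with missing isotope cells
because their *position* matters for every downstream statistic.

Cutting geometry: fine (target 1 mm) subsections tile the anterior crest
half, coarse (target 2 mm) subsections the posterior half — the anterior
half is where most of the ontogenetic change concentrates.  "As close to
the target width as possible" is not a published rounding rule; we divide
each half into `round(half/target)` equal tiles (ties half-up, at least
one) and rescale so the tiling is exact.  Both widths are arguments, so any
other convention can be expressed.  The first subsection is taken to start
at 0 mm: the eroded, re-deposited rostrum tip amounts to at most half of
subsection 1 and we do not model it separately.

Quality control is advisory only.  Beak chitin C:N outside the observed
3.05–3.86 band and replicate SDs above the 0.2‰ instrumental precision
raise flags but never drop data — no exclusion rule is part of the stated
methodology.

## Size at formation

Mantle length (ML) follows a power law in upper-crest length (UCL):
`ML = a·UCL^b + c`, where `c` is an additive bias correction equal to the
mean of (real − predicted) ML on the fitting data.  Two presets ship:
West Greenland (`3.25·UCL^1.40 + 4.2` mm, n = 86, R² = 0.95) and overall
Arctic (`3.77·UCL^1.34 + 3.3` mm, n = 142, R² = 0.93).  `fit_power_law()`
refits from data; the default is least squares on the log–log scale (the
standard allometric linearization, and multiplicative error is the
plausible error structure), with direct nonlinear least squares as an
option.  Which of the two the original analysis used is not stated; on
clean data they agree.

Each subsection is anchored at its **posterior edge** (the cumulative
crest length at the cut) because the material at the cut is the newest
deposited at that size; the midpoint anchor is available for sensitivity
analysis and differs by less than one subsection's ML increment.

Mass uses a second power law `mass = a_g·ML^b`.  The coefficients of the
regional length–mass equation are not published; the shipped default is a
two-anchor calibration through reconstructed subsection means
(7.3 mm, 0.033 g) and (86.9 mm, 20.8 g), giving `a_g ≈ 1.87e-4` g and
`b ≈ 2.60`.  **This is a synthetic stand-in**, exact at its anchors and
approximate elsewhere; override it via `mass_model()` when the true
coefficients are available.

## Trophic level and specialization

`TL = TL_base + (δ¹⁵N_beak + Δ_beak − δ¹⁵N_base) / TEF` with defaults
`Δ_beak = +4.8‰` (beak chitin is depleted relative to muscle),
`TEF = 3.8‰` per level ("Arctic"; the "classical" 3.4 is one argument
away), and a herbivorous-copepod baseline at `TL_base = 2.0`.  The
transform is affine, so TL *differences* between subsections equal δ¹⁵N
differences divided by the TEF — the baseline cancels, which is also how
the packaged summary fixture is internally validated.  One baseline per
run is assumed (nearest-station); per-station baselines can be expressed
by building separate `trophic_params`.

The specialization index is `s = V_within / (V_among + V_within)`.  The
estimators are not pinned by the index's source: we use the sample
variance (n−1) of the individual's analysed values for `V_within` and the
sample variance of per-individual means for `V_among`, with a
population-denominator switch.  `s < 0.5` is a specialist.  Note `s` is a
*relative* measure: adding a constant to one individual's series leaves
its `V_within` untouched and moves `s` only through the among-individual
variance (tested as a property).

Spearman correlation between the two isotope series uses midranks,
pairwise deletion (no imputation — roughly half the real individuals could
be assessed for this reason), and the t-approximation for p.

## Rank tests

All tests are implemented from first principles and cross-checked against
independent oracles in the test suite.

* **Mann–Whitney U** reports `min(U_a, U_b)` with midranks.  The default
  p-value is exact (network enumeration via Gaussian-binomial
  coefficients) when the data are tie-free and both groups have ≤ 10
  observations, otherwise the normal approximation with continuity
  correction and tie-corrected variance.  This default is what reproduces
  all three published by-sex p-values (0.67, 0.95, 0.85): the
  continuity-corrected normal alone gives 0.94, not 0.95, for the U = 20
  comparison, so the exact branch is not cosmetic.
* **Kruskal–Wallis** is tie-corrected with chi-square p; **Dunn's**
  pairwise z defaults to no multiplicity adjustment (none is named in the
  source methodology), with Holm and Bonferroni available.
* **Skillings–Mack** handles the subsection × individual tables with
  missing cells: within-block midranks are centred and scaled by
  `sqrt(12/(k_i+1))`, summed per treatment, and the statistic is the
  quadratic form under the null covariance implied by the missingness
  pattern (Moore–Penrose inverse; the covariance matrix is singular by
  construction).  On complete data it reduces *exactly* to Friedman's
  chi-square, which is asserted as an equality in the tests.  Blocks with
  fewer than two observed cells carry no rank information and are dropped
  with a warning.  P-values use the chi-square approximation on t−1 df;
  with heavy ties or tiny designs a simulated null would be preferable
  (not implemented — the intended designs have ≥ 10 blocks).
* **Nemenyi** post hoc standardizes pairwise differences of the adjusted
  rank sums by their null covariance and refers them to the studentized
  range distribution; for complete data this coincides with the classical
  Friedman–Nemenyi mean-rank formula (asserted against an independently
  coded oracle).
* **χ² / Fisher** operate on user-supplied count tables.  Fisher is
  two-sided by hypergeometric enumeration (sum of all tables no more
  probable than the observed, with a 1e-7 relative tie tolerance) and
  restricted to 2×2.

Under null simulation at the design sizes used in the acceptance suite
(two/three groups of 20; 20 blocks × 5 treatments with 10% missing cells)
each test's empirical size at α = 0.05 lies in [0.04, 0.06].  The
chi-square approximations are known to be conservative for much smaller
designs; those sizes were chosen once, as representative of the intended
use, before the acceptance run.

## Isotopic niches

Niche space is (δ¹³C, TL): using TL on the y axis counters baseline
variation when pooling areas.  Each individual contributes one point — the
mean of its analysed subsections, standing in for a powdered whole beak.

`SEA = π·sqrt(det(S))` (the standard ellipse, containing
1 − e^(−1/2) ≈ 39.35% of the generating normal), `SEAc = SEA·(n−1)/(n−2)`,
and TA is the convex hull area (shoelace).  `TA ≥ SEAc` is *not* generally
true and is not asserted.  SEAb draws the covariance from its posterior
under the vague normal–inverse-Wishart model (`Σ | data ~
IW(n−1, centred SSQ)`, `μ | Σ ~ N(x̄, Σ/n)`); its mean tracks SEAc.

Ellipse–ellipse overlap is computed by clipping 720-vertex polygon
approximations (Sutherland–Hodgman; relative area error < 1e-3, verified
against the circular-lens closed form).  The overlap **denominator is
directional** — intersection over the reference group's own SEAc — because
a single symmetric number cannot produce the asymmetric overlap matrices
that motivate the design; both directions are always returned.
Probabilistic niche-region overlap is likewise directional: the posterior
probability that a draw from A's distribution lands inside B's α-level
elliptical region (α = 0.95 default), estimated by Monte Carlo over paired
posterior draws.  Self-overlap tends to α·100%.  Sequential subsections of
the same beaks are not independent samples; the functions compute the
metrics regardless and the caveat is the caller's to weigh, as in the
original design.

Overlap categories: < 0.30 none, 0.30–0.60 medium, ≥ 0.61 large, with only
"large" conventionally treated as significant.

## Diet mixing

Per consumer i and isotope j:

```
x_ij ~ Normal( Σ_k p_k (μ_kj + μ_TEF,j),
               Σ_k p_k² (σ_kj² + σ_TEF,j²) + σ_resid,j² )
```

with `p ~ Dirichlet(1, …, 1)` and half-normal(0, 5) priors on the residual
SDs.  This is the squared-proportion variance composition used by the
standard mixing packages for this analysis type; the TEF defaults
(δ¹³C −0.20 ± 0.55‰, δ¹⁵N 3.37 ± 0.99‰) are the experimental beak-tissue
values.  The sampler is a self-contained adaptive random-walk Metropolis
on additive-log-ratio coordinates (joint update of alr(p) and log residual
SDs), tuned during burn-in toward 20–40% acceptance — no external
probabilistic-programming dependency.  Draws are exactly on the simplex by
construction; with no consumers the sampler is bypassed and the Dirichlet
prior returned directly.

Before fitting, consumers are screened against the **mixing polygon** (the
convex hull of TEF-corrected source means): points outside it cannot be
expressed as any mixture.  The hull is strict by default; with two sources
the polygon degenerates to a segment and a one-pooled-SD margin is applied
(a zero-width segment would reject everything).  Sources must be pairwise
distinguishable — mean separation above `distinguish_k` (default 1) pooled
SDs in at least one isotope — mirroring the rule that indistinct sources
(e.g. cephalopods and fish for the smallest squid) must be combined before
fitting; `aggregate_sources()` does the converse after fitting, summing
draws within supergroups draw-wise so SDs are recomputed, not added.

`compare_diet_profiles()` converts posterior mean proportions to
pseudo-counts of a stated total (default 100) for χ²/Fisher comparison.
This is an explicit heuristic: the original conversion procedure is
unstated, and the p-values depend directly on the chosen total.

The shipped `arctic_source_library()` is **synthetic and
non-authoritative**: six prey groups with the qualitative Arctic ordering
(copepods lowest δ¹⁵N → fish/squid highest), constructed to be pairwise
distinguishable under the default rule.  The real source table for the
original analysis is in an appendix that is not redistributable here, so
diet-model outputs on these sources are methodology-level only.

## The synthetic-data generator

`simulate_population()` writes down the stated world: per-subsection
population increments of 0.29‰ (δ¹³C, subsections 1→5) then 0.01‰, and
0.89‰ (δ¹⁵N, subsections 2→7) then 0.08‰, from starts of −20.5‰ and 9.1‰;
11–17 subsections per individual; measurement noise 0.2‰ (the instrumental
precision); missing cells at 10% (completely at random by default, with a
block-missing option because real failures cluster).  Between-individual
variation is a random intercept with SD 0.35‰ (δ¹³C) and 0.4‰ (δ¹⁵N) —
values chosen once so that the variance ratio reproduces the observed
contrast between a generalist δ¹⁵N regime (mean s ≈ 0.95) and a mixed
δ¹³C regime (mean s ≈ 0.6), since no between-individual SDs are printed.
Optional random slopes exist for specialization stress tests.

What a green test on synthetic data does **not** establish: the generator
has no real-ocean baseline gradients, no depth-driven δ¹³C structure, no
correlated missingness with beak size, and its consumers are drawn from
the mixing model's own likelihood — parameter-recovery tests validate the
inference machinery, not the ecological correctness of any source library.

The packaged `table1_fixture()` is a transcription of the published
per-individual summary table, used for acceptance testing.  One printed
inconsistency is preserved as printed and screened out where it matters:
individual F1's δ¹⁵N min–max (7.9–13.5) does not match its printed
min-to-max range (4.60; the TL column implies 5.6).
`table1_consistent_rows()` applies a 0.1‰ agreement tolerance — the
printed min/max are rounded to 0.1‰, so discrepancies up to ~0.1 are pure
rounding, and only the genuine typo fails.  Two published numbers are
deliberately not reproduced: the U = 23.0 for the δ¹⁵N min-to-max by-sex
test (recomputation from the printed columns gives 22) and the population
δ¹⁵N increase of 10.7‰ (the printed extremes give 11.1‰; the original
value presumably involves the pooled earlier dataset).

## Life stages

`classify_stage()` encodes the four-stage periodization with half-open
bins: [0, 20) → 1, [20, 50) → 2, [50, ∞) → 3, and gelatinous ∧ ML ≥ 200 →
4 (a gelatinous flag below 200 mm falls back to the size bin with a
warning).  Stage durations assume linear growth — `months = ΔML / rate /
30.44` — with published juvenile rates of 0.13–0.18 and 0.27 mm/day; the
published month figures cannot all be derived from one hatchling size and
rate, so each bound is matched individually where the arithmetic permits
(e.g. 30 mm / 0.27 / 30.44 = 3.7 months; 16.5 mm / 0.13 / 30.44 = 4.2
months from a 3.5 mm hatchling).  `biomass_partition()` reproduces the
67% / 21% / 12% Nordic Seas shares from the printed 8 / 2.5 / 1.5 Mt
components; the printed "0.02%" for gelatinous females is inconsistent
with 0.25 Mt of ~12 Mt (≈ 2%) and its derivation base is unstated, so only
the component shares are treated as reproducible.

## Numerical choices and limitations

* Grid arithmetic is exact to 1e-9 mm; tiling is deterministic.
* The Mann–Whitney exact branch enumerates in O(n₁·n₂·n₁) integer
  polynomial operations — fine for the ≤ 10-per-group default cap.
* The pseudo-inverse tolerance for the Skillings–Mack covariance is
  1e-10 relative to the largest singular value.
* MCMC defaults (10 000 iterations, 2 000 burn-in, thin 5) give effective
  sample sizes in the hundreds-to-thousands for ≤ 6 sources; multimodal
  posteriors from nearly collinear sources are not specially handled —
  the distinguishability check is the guard.
* Ellipse overlap is a polygonal approximation (720 vertices); exact
  conic–conic intersection is not implemented.
* No compound-specific amino-acid TL, no concentration-dependent mixing,
  no isotope routing, no hierarchical (random-effects) mixing across
  groups, and no oceanographic simulation — all outside the package's
  scope by design.
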