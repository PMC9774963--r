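# beaktraj

Life-history reconstruction from stable-isotope trajectories in cephalopod
beaks.

## The problem

Cephalopod beaks are chitinous archives: material at the rostrum tip was
deposited around hatching, material at the posterior edge of the crest just
before capture, and the tanned parts are metabolically inert afterwards.
Cutting a beak crest into sequential subsections and measuring δ¹³C and
δ¹⁵N in each yields an *individual ontogenetic trajectory* — habitat
(δ¹³C) and diet/trophic position (δ¹⁵N) over the animal's whole life —
instead of the single population snapshot that whole-beak analysis gives.
`beaktraj` implements the full analysis chain for such trajectories in
Arctic squid, from tidy CSV input to an ecological life-stage
classification, for trophic ecologists working with beak (or other
accretionary-structure) isotope series.

The core quantities:

- **Allometry.** Mantle length from beak crest length, `ML = a·UCL^b + c`
  (presets `ML = 3.25·UCL^1.40 + 4.2` mm for West Greenland and
  `ML = 3.77·UCL^1.34 + 3.3` mm for the overall Arctic), and mass from ML
  by a second power law — every subsection becomes a size-at-formation.
- **Trophic level.** `TL = TL_base + (δ¹⁵N_beak + 4.8 − δ¹⁵N_base) / TEF`
  with the beak-to-muscle correction (+4.8‰) and an "Arctic" TEF of 3.8‰
  per level against a copepod baseline at TL = 2.
- **Individual specialization.** `s = V_within / (V_among + V_within)`;
  s < 0.5 marks a specialist, s → 1 an extreme generalist.
- **Rank statistics.** Mann–Whitney U, Kruskal–Wallis + Dunn, and the
  Skillings–Mack test with Nemenyi post hoc for subsection-by-individual
  tables with missing cells (reduces exactly to Friedman when complete).
- **Isotopic niches.** Standard ellipse areas (SEA, SEAc = SEA·(n−1)/(n−2),
  posterior SEAb), convex hull area (TA), ML ellipse overlap, and
  directional probabilistic niche-region overlap under a
  normal–inverse-Wishart posterior.
- **Diet mixing.** A Bayesian mixing model with Dirichlet(1) prior,
  SIMMR-style variance composition
  `Var = Σ p_k²(σ_k² + σ_TEF²) + σ_resid²`, adaptive Metropolis on
  log-ratio coordinates, and mixing-polygon feasibility screening.
- **Life stages.** The four-stage periodization: (1) epipelagic, ML < 20 mm;
  (2) ML 20–50 mm; (3) meso-/bathypelagic, ML ≥ 50 mm; (4) gelatinous
  females, ML > 200 mm — plus stage durations and biomass partitioning.

## Worked example

```r
library(beaktraj)

# a synthetic population with the documented trajectory structure
pop <- simulate_population(trajectory_sim_params(), seed = 1)

# size-at-formation for one individual
wg <- allometry_preset("west_greenland")
sz <- size_at_subsections(pop$trajectories[[1]], wg)
round(head(sz, 3), 2)
#>   index anchor_mm ml_est_mm mass_est_g
#> 1     1      1.05      7.67       0.04
#> 2     2      2.10     13.35       0.16
#> 3     3      3.14     20.35       0.48

# trophic level and specialization
p <- trophic_params(baseline_d15n = 8.8)
sm <- summarize_trajectory(pop$trajectories[[1]], p)
round(c(tl_range = sm$tl$range_min_to_max, s_d15n =
        specialization_index(pop$trajectories[[1]], pop, "d15n")$s), 2)
#> tl_range   s_d15n
#>     1.56     0.95

# do subsections differ? (individuals x subsections, missing cells allowed)
m <- sapply(1:11, function(j) sapply(pop$trajectories, function(tr)
  tr$subsections$d15n[match(j, tr$subsections$index)]))
skillings_mack(m)
#> Skillings-Mack (chi-square approximation): SM = 111.9, df = 10, p = 2.237e-19

# diet mixing with known truth
src <- arctic_source_library()
truth <- mixture_truth(setNames(c(.2, .2, .15, .05, .25, .15), src$name), 30)
cons <- simulate_consumers(truth, src, seed = 2)
feasibility_check(cons, src)$report
#> [1] "17 of 30"
fit <- fit_mixing(cons, src, seed = 3)

# ecological stage of each subsection's reconstructed size
table(classify_stage(sz$ml_est_mm))
#>  1  2  3
#>  2  4  5
```

The first subsections sit below 20 mm ML (stage 1, copepod-dominated
epipelagic life), the trajectory crosses the 20–50 mm transition band, and
the later subsections are stage 3 — the sequence the trajectory analysis is
designed to resolve.  The TL range of ~1.5 levels within one individual and
the near-1 δ¹⁵N specialization index mirror the generalist regime reported
for adult Arctic squid.

## Command line

```sh
Rscript inst/cli/beaktraj simulate --n 14 --seed 42 --out synth.csv
Rscript inst/cli/beaktraj read --in synth.csv --validate
Rscript inst/cli/beaktraj summarize --in synth.csv --baseline 8.8 --out summary.csv
Rscript inst/cli/beaktraj size --in synth.csv --region west_greenland
```

## Documentation

The methods vignette (`vignettes/beak-trajectories.Rmd`) describes the
models, their assumptions, all tunable parameters with defaults, what the
synthetic-data generator does and does not emulate, and known limitations
(including transcription caveats in the packaged fixture).
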