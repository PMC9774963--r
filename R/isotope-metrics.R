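# Delta notation, trophic levels, per-trajectory summaries, individual
# specialization, rank correlation.

#' Delta notation for an isotope ratio
#'
#' `delta = (R_sample / R_standard - 1) * 1000` per mil, with R the heavy /
#' light isotope ratio (13C/12C against V-PDB, 15N/14N against AIR).
#'
#' @param r_sample,r_standard Isotope ratios; `r_standard` must be positive.
#' @return Delta value (per mil).
#' @export
delta_value <- function(r_sample, r_standard) {
  if (any(r_standard <= 0)) stop("r_standard must be positive")
  (r_sample / r_standard - 1) * 1000
}

#' Trophic-level estimation parameters
#'
#' Beak chitin is depleted in 15N relative to muscle by about 4.8 per mil,
#' so raw beak d15N is first shifted by `beak_d15n_correction`.  The
#' trophic level is then the baseline TL plus the corrected offset from the
#' baseline organism's d15N divided by the per-level trophic enrichment
#' factor (TEF).  Defaults: +4.8 per mil beak correction, "Arctic" TEF of
#' 3.8 per mil (the "classical" 3.4 is available by argument), baseline
#' TL = 2.0 (herbivorous copepod *Calanus finmarchicus*).
#'
#' @param baseline_d15n d15N (per mil, muscle scale) of the baseline
#'   organism at the nearest station.
#' @param baseline_tl Trophic level assigned to the baseline (default 2.0).
#' @param tef_per_level TEF per trophic level (per mil, default 3.8).
#' @param beak_d15n_correction Additive beak-to-muscle d15N correction
#'   (per mil, default +4.8).
#' @return Object of class `trophic_params`.
#' @export
trophic_params <- function(baseline_d15n, baseline_tl = 2.0,
                           tef_per_level = 3.8,
                           beak_d15n_correction = 4.8) {
  stopifnot(tef_per_level > 0, baseline_tl >= 1)
  structure(list(baseline_d15n = baseline_d15n, baseline_tl = baseline_tl,
                 tef_per_level = tef_per_level,
                 beak_d15n_correction = beak_d15n_correction),
            class = "trophic_params")
}

#' Estimate trophic level from beak d15N
#'
#' `TL = baseline_tl + (d15n_beak + correction - baseline_d15n) / TEF`.
#' Affine in `d15n_beak`, so TL differences between subsections equal
#' d15N differences divided by the TEF regardless of baseline.
#'
#' @param d15n_beak Raw beak d15N (per mil); vectorized, `NA` passed
#'   through.
#' @param params A [trophic_params()].
#' @return Estimated trophic level(s).
#' @export
estimate_tl <- function(d15n_beak, params) {
  stopifnot(inherits(params, "trophic_params"))
  params$baseline_tl +
    (d15n_beak + params$beak_d15n_correction - params$baseline_d15n) /
    params$tef_per_level
}

# summary of one numeric series along analysed subsections
.series_summary <- function(values, index) {
  ok <- !is.na(values)
  n_available <- length(values)
  if (sum(ok) < 2L)
    return(list(available = FALSE, n_analysed = sum(ok),
                n_available = n_available))
  v <- values[ok]; idx <- index[ok]
  i_min <- which.min(v); i_max <- which.max(v)
  list(available = TRUE,
       n_analysed = length(v), n_available = n_available,
       min = min(v), max = max(v),
       argmin_subsection = idx[i_min], argmax_subsection = idx[i_max],
       mean = mean(v), se = sd(v) / sqrt(length(v)),
       range_min_to_max = max(v) - min(v),
       range_first_to_last = abs(v[length(v)] - v[1L]))
}

#' Summarize one trajectory's isotope series
#'
#' For each isotope (and the derived TL series when `params` is supplied):
#' min / max over *analysed* subsections with their subsection numbers, the
#' min-to-max range, the newest-to-oldest range (absolute difference
#' between the last and first analysed values), mean +/- SE, and counts.
#' The two ranges coincide exactly when the extremes sit at the trajectory
#' ends; an interior extreme makes min-to-max strictly larger.
#'
#' @param traj A [beak_trajectory()].
#' @param params Optional [trophic_params()] to add a TL summary.
#' @return List with elements `d13c`, `d15n` and (optionally) `tl`, each a
#'   list as described above (`available = FALSE` when fewer than two
#'   analysed values).
#' @export
summarize_trajectory <- function(traj, params = NULL) {
  stopifnot(inherits(traj, "beak_trajectory"))
  s <- traj$subsections
  out <- list(individual_id = traj$individual_id,
              d13c = .series_summary(s$d13c, s$index),
              d15n = .series_summary(s$d15n, s$index))
  if (!is.null(params))
    out$tl <- .series_summary(estimate_tl(s$d15n, params), s$index)
  out
}

#' Individual specialization index
#'
#' `s = V_within / (V_among + V_within)`: the variance of the individual's
#' analysed subsection values divided by the sum of the among-individual
#' variance of the population and that within-individual variance.  `s` lies in `[0, 1]`: values near 0 mean
#' the individual spans a sliver of the population's isotopic spread
#' (specialist, conventionally `s < 0.5`), values near 1 mean it spans
#' essentially all of it (extreme generalist).
#'
#' Estimator choice (not pinned by the index's originators): `V_within` is
#' the sample variance (n-1 denominator) of the individual's analysed
#' values; `V_among` is the sample variance of per-individual means across
#' the population.  `denominator = "population"` switches both to the
#' n-denominator variance.
#'
#' @param traj A [beak_trajectory()] (must belong to `population`'s id set
#'   or simply provide the values).
#' @param population A [beak_population()] with at least 2 individuals.
#' @param isotope `"d13c"` or `"d15n"`.
#' @param denominator `"sample"` (default) or `"population"`.
#' @return List with `s`, `v_within`, `v_among`, `classification`
#'   (`"specialist"` if `s < 0.5`, else `"generalist"`).
#' @export
specialization_index <- function(traj, population,
                                 isotope = c("d13c", "d15n"),
                                 denominator = c("sample", "population")) {
  isotope <- match.arg(isotope)
  denominator <- match.arg(denominator)
  stopifnot(inherits(traj, "beak_trajectory"),
            inherits(population, "beak_population"))
  if (length(population$trajectories) < 2L)
    stop("population must contain at least 2 individuals")
  varfun <- if (denominator == "sample") var else
    function(x) mean((x - mean(x))^2)
  own <- traj$subsections[[isotope]]
  own <- own[!is.na(own)]
  if (length(own) < 2L)
    stop("need >= 2 analysed values for individual ", traj$individual_id)
  v_within <- varfun(own)
  means <- vapply(population$trajectories, function(tr) {
    v <- tr$subsections[[isotope]]
    mean(v, na.rm = TRUE)
  }, numeric(1))
  means <- means[!is.nan(means)]
  v_among <- varfun(means)
  if (v_among + v_within == 0)
    stop("zero total variance: specialization index undefined")
  s <- v_within / (v_among + v_within)
  list(s = s, v_within = v_within, v_among = v_among,
       classification = if (s < 0.5) "specialist" else "generalist")
}

#' Spearman rank correlation with midrank ties
#'
#' Pairs with either value missing are dropped (pairwise deletion, no
#' imputation).  rho is the Pearson correlation of midranks; the two-sided
#' p-value uses the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on
#' n-2 degrees of freedom (p = 0 at |rho| = 1).
#'
#' @param x,y Paired numeric vectors.
#' @return List with `rho`, `p_value`, `n` (complete pairs used).
#' @export
spearman_rho <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (var(x) == 0 || var(y) == 0)
    stop("all-tied input: rank correlation undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}
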