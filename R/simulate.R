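# Synthetic-data generator: populations of beak trajectories with the
# trajectory structure the analysis assumes, and known-truth diet
# mixtures for parameter-recovery tests.

#' Parameters for trajectory simulation
#'
#' The population curve follows the observed two-phase increment
#' structure: d13C starts near -20.5 per mil and climbs ~0.29 per mil per
#' subsection up to subsection 5, then ~0.01 per mil; d15N starts near
#' 9.1 per mil and climbs ~0.89 per mil per subsection from subsection 2
#' to 7, then ~0.08 per mil.  Individuals deviate by a random intercept
#' (between-individual SD per isotope; optionally a random slope for
#' stress tests) plus per-subsection measurement noise (default 0.2 per
#' mil, the instrumental precision).  Subsection counts are drawn
#' uniformly in `subsections_range` (default 11-17); cells go missing
#' completely at random at `missing_prob` (default 0.1), or in one
#' contiguous block per affected individual when
#' `missing_pattern = "block"`.
#'
#' @param n_individuals Number of individuals (>= 2).
#' @param subsections_range Integer range of subsection counts.
#' @param d13c_start,d13c_fast,d13c_slow,d13c_fast_until d13C curve:
#'   start mean, fast and slow per-subsection increments, last subsection
#'   of the fast phase.
#' @param d15n_start,d15n_fast,d15n_slow,d15n_fast_until Same for d15N.
#' @param between_sd_d13c,between_sd_d15n Between-individual intercept SDs.
#' @param slope_sd_d13c,slope_sd_d15n Optional random-slope SDs
#'   (multiplying the population increments; default 0).
#' @param measurement_sd Per-subsection noise SD (per mil).
#' @param missing_prob Probability a cell is missing.
#' @param missing_pattern `"mcar"` or `"block"`.
#' @param prop_female Sex ratio (probability of female).
#' @return List of class `trajectory_sim_params`.
#' @export
trajectory_sim_params <- function(n_individuals = 14L,
                                  subsections_range = c(11L, 17L),
                                  d13c_start = -20.5, d13c_fast = 0.29,
                                  d13c_slow = 0.01, d13c_fast_until = 5L,
                                  d15n_start = 9.1, d15n_fast = 0.89,
                                  d15n_slow = 0.08, d15n_fast_until = 7L,
                                  between_sd_d13c = 0.35,
                                  between_sd_d15n = 0.4,
                                  slope_sd_d13c = 0, slope_sd_d15n = 0,
                                  measurement_sd = 0.2,
                                  missing_prob = 0.1,
                                  missing_pattern = c("mcar", "block"),
                                  prop_female = 0.5) {
  missing_pattern <- match.arg(missing_pattern)
  stopifnot(n_individuals >= 2L,
            subsections_range[1] >= 2L,
            subsections_range[2] >= subsections_range[1],
            between_sd_d13c >= 0, between_sd_d15n >= 0,
            measurement_sd >= 0,
            missing_prob >= 0, missing_prob <= 1,
            prop_female >= 0, prop_female <= 1)
  structure(as.list(environment()), class = "trajectory_sim_params")
}

# population mean curve over subsections 1..n
.sim_curve <- function(n, start, fast, slow, fast_until) {
  inc <- ifelse(seq_len(n) <= fast_until, fast, slow)
  start + c(0, cumsum(inc[-1]))
}

#' Simulate a population of beak trajectories
#'
#' Each individual's series is population curve + individual intercept
#' (+ optional slope deviation) + iid measurement noise, then masked at
#' the configured missingness.  Crest coordinates come from
#' [build_subsection_grid()] with one fine subsection per index in the
#' anterior half (crest length `2 * max subsections / 1.5` is arbitrary
#' but fixed), and adult mantle length from the West Greenland allometry
#' preset at the last subsection's posterior edge -- so size
#' reconstruction on simulated data is exactly self-consistent.
#'
#' @param params A [trajectory_sim_params()].
#' @param seed Integer seed (all randomness is governed by it).
#' @return A [beak_population()].
#' @export
simulate_population <- function(params = trajectory_sim_params(),
                                seed = 1L) {
  stopifnot(inherits(params, "trajectory_sim_params"))
  set.seed(seed)
  n <- params$n_individuals
  n_sub <- sample(seq(params$subsections_range[1],
                      params$subsections_range[2]), n, replace = TRUE)
  sexes <- ifelse(runif(n) < params$prop_female, "female", "male")
  model <- allometry_preset("west_greenland")
  trajs <- vector("list", n)
  for (i in seq_len(n)) {
    s <- n_sub[i]
    mu13 <- .sim_curve(s, params$d13c_start, params$d13c_fast,
                       params$d13c_slow, params$d13c_fast_until)
    mu15 <- .sim_curve(s, params$d15n_start, params$d15n_fast,
                       params$d15n_slow, params$d15n_fast_until)
    slope13 <- if (params$slope_sd_d13c > 0)
      rnorm(1, 1, params$slope_sd_d13c) else 1
    slope15 <- if (params$slope_sd_d15n > 0)
      rnorm(1, 1, params$slope_sd_d15n) else 1
    d13 <- params$d13c_start + slope13 * (mu13 - params$d13c_start) +
      rnorm(1, 0, params$between_sd_d13c) +
      rnorm(s, 0, params$measurement_sd)
    d15 <- params$d15n_start + slope15 * (mu15 - params$d15n_start) +
      rnorm(1, 0, params$between_sd_d15n) +
      rnorm(s, 0, params$measurement_sd)
    miss13 <- .sim_missing(s, params$missing_prob, params$missing_pattern)
    miss15 <- .sim_missing(s, params$missing_prob, params$missing_pattern)
    d13[miss13] <- NA_real_
    d15[miss15] <- NA_real_
    # fine grid: first half 1-mm tiles; coarse 2-mm; crest sized so the
    # individual's subsections fill the grid exactly
    crest <- 4 / 3 * s            # s = crest/2 + crest/4 tiles
    grid <- build_subsection_grid(crest)
    grid <- grid[seq_len(s), , drop = FALSE]
    ml <- predict_ml(model, grid$crest_end_mm[s])
    trajs[[i]] <- beak_trajectory(
      individual_id = sprintf("S%02d", i),
      subsections = data.frame(index = seq_len(s), d13c = d13, d15n = d15,
                               crest_start_mm = grid$crest_start_mm,
                               crest_end_mm = grid$crest_end_mm),
      sex = sexes[i], mantle_length_mm = ml)
  }
  beak_population(trajs)
}

.sim_missing <- function(s, prob, pattern) {
  if (prob == 0) return(logical(s))
  if (prob >= 1) return(rep(TRUE, s))
  if (pattern == "mcar") return(runif(s) < prob)
  # block missingness: with probability 1 - (1-prob)^s the individual has
  # one contiguous missing run of expected length prob * s
  out <- logical(s)
  if (runif(1) < 1 - (1 - prob)^s) {
    len <- max(1L, rbinom(1L, s, prob))
    start <- sample.int(s - len + 1L, 1L)
    out[start:(start + len - 1L)] <- TRUE
  }
  out
}

#' Known-truth diet mixture specification
#'
#' @param proportions Named numeric vector on the simplex (names matching
#'   source names).
#' @param n_consumers Number of consumers to draw.
#' @return List of class `mixture_truth`.
#' @export
mixture_truth <- function(proportions, n_consumers = 30L) {
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("proportions must sum to 1")
  if (any(proportions < 0)) stop("proportions must be non-negative")
  structure(list(proportions = proportions, n_consumers = n_consumers),
            class = "mixture_truth")
}

#' Simulate consumers from the mixing model's own generative law
#'
#' Consumers are drawn from the exact likelihood used by [fit_mixing()]
#' at the true proportions: mean `sum p_k (mu_k + mu_TEF)`, variance
#' `sum p_k^2 (sd_k^2 + sd_TEF^2)` (+ optional residual variance), per
#' isotope independently.
#'
#' @param truth A [mixture_truth()].
#' @param sources data.frame of [source_spec()] rows (rows aligned with
#'   `truth$proportions` by name).
#' @param tef A [tef_spec()].
#' @param resid_sd Optional residual SD per isotope (length 2, default 0).
#' @param seed Integer seed.
#' @return data.frame with columns `d13c`, `d15n`.
#' @export
simulate_consumers <- function(truth, sources, tef = tef_spec(),
                               resid_sd = c(0, 0), seed = 1L) {
  stopifnot(inherits(truth, "mixture_truth"))
  p <- truth$proportions[sources$name]
  if (anyNA(p)) stop("truth proportions must name every source")
  set.seed(seed)
  mu <- unname(c(sum(p * (sources$mean_d13c + tef$mean["d13c"])),
                 sum(p * (sources$mean_d15n + tef$mean["d15n"]))))
  v <- unname(c(sum(p^2 * (sources$sd_d13c^2 + tef$sd["d13c"]^2)) +
                  resid_sd[1]^2,
                sum(p^2 * (sources$sd_d15n^2 + tef$sd["d15n"]^2)) +
                  resid_sd[2]^2))
  data.frame(d13c = rnorm(truth$n_consumers, mu[1], sqrt(v[1])),
             d15n = rnorm(truth$n_consumers, mu[2], sqrt(v[2])))
}
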