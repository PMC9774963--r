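# Power-law beak allometry: beak measure -> mantle length -> body mass.
# ML = a * L^b (+ additive bias correction); mass = a_g * ML^b.

#' Construct an allometric model
#'
#' @param coefficient_a Positive multiplier `a` of `ML = a * L^b`.
#' @param exponent_b Positive exponent `b`.
#' @param bias_correction_mm Additive correction (mm) applied after the
#'   power law; the mean of (real - predicted) ML on the training pairs.
#' @param predictor Beak measure the model maps from: `"UCL"` (upper beak
#'   crest length) or `"URL"` (upper beak rostrum length).
#' @param region_tag Free-form provenance label.
#' @param n_fit,r_squared Fit diagnostics (optional).
#' @return Object of class `allometric_model`.
#' @export
allometric_model <- function(coefficient_a, exponent_b,
                             bias_correction_mm = 0,
                             predictor = c("UCL", "URL"),
                             region_tag = "unspecified",
                             n_fit = NA_integer_, r_squared = NA_real_) {
  predictor <- match.arg(predictor)
  stopifnot(coefficient_a > 0, exponent_b > 0)
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1))
    stop("r_squared must be in [0, 1]")
  structure(list(coefficient_a = coefficient_a, exponent_b = exponent_b,
                 bias_correction_mm = bias_correction_mm,
                 predictor = predictor, region_tag = region_tag,
                 n_fit = n_fit, r_squared = r_squared),
            class = "allometric_model")
}

#' @export
print.allometric_model <- function(x, ...) {
  cat(sprintf("<allometric_model [%s, %s]: ML = %.4g * %s^%.4g + %.3g mm>\n",
              x$region_tag, x$predictor, x$coefficient_a, x$predictor,
              x$exponent_b, x$bias_correction_mm))
  invisible(x)
}

#' Built-in crest-length allometry presets
#'
#' Two published UCL -> ML power laws ship as presets, with their additive
#' bias corrections (mean real-minus-predicted ML on the fitting data):
#' `"west_greenland"` (`ML = 3.25 * UCL^1.40`, +4.2 mm, n = 86, R^2 = 0.95)
#' and `"arctic"` (`ML = 3.77 * UCL^1.34`, +3.3 mm, n = 142, R^2 = 0.93).
#' Use the regional model when beak provenance is known, the overall Arctic
#' model otherwise.
#'
#' @param region `"west_greenland"` or `"arctic"`.
#' @return An [allometric_model()].
#' @export
allometry_preset <- function(region = c("west_greenland", "arctic")) {
  region <- match.arg(region)
  switch(region,
    west_greenland = allometric_model(3.25, 1.40, bias_correction_mm = 4.2,
                                      predictor = "UCL",
                                      region_tag = "West Greenland",
                                      n_fit = 86L, r_squared = 0.95),
    arctic = allometric_model(3.77, 1.34, bias_correction_mm = 3.3,
                              predictor = "UCL", region_tag = "Arctic",
                              n_fit = 142L, r_squared = 0.93))
}

#' Fit a power law y = a * x^b
#'
#' Default fitting is ordinary least squares on log-transformed data (the
#' conventional allometric linearization); `method = "nls"` minimizes
#' squared error on the original scale starting from the log-log solution.
#' R^2 is reported on the model's fitted scale (log-log for `"loglog"`,
#' raw for `"nls"`).  The additive bias correction is computed as
#' `mean(y - a * x^b)` on the training pairs.
#'
#' @param x Beak lengths (mm), positive.
#' @param y Mantle lengths (mm), positive.
#' @param method `"loglog"` (default) or `"nls"`.
#' @param predictor,region_tag Passed to [allometric_model()].
#' @return An [allometric_model()].
#' @export
fit_power_law <- function(x, y, method = c("loglog", "nls"),
                          predictor = "UCL", region_tag = "fitted") {
  method <- match.arg(method)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (any(x <= 0) || any(y <= 0))
    stop("power law undefined for non-positive values")
  if (var(y) == 0) stop("constant response: power-law fit is degenerate")
  lx <- log(x); ly <- log(y)
  b <- cov(lx, ly) / var(lx)
  la <- mean(ly) - b * mean(lx)
  if (method == "loglog") {
    fitted_log <- la + b * lx
    r2 <- 1 - sum((ly - fitted_log)^2) / sum((ly - mean(ly))^2)
    a <- exp(la)
  } else {
    obj <- function(p) sum((y - exp(p[1]) * x^p[2])^2)
    opt <- optim(c(la, b), obj, method = "BFGS")
    a <- exp(opt$par[1]); b <- opt$par[2]
    r2 <- 1 - opt$value / sum((y - mean(y))^2)
  }
  if (b <= 0) stop("fitted exponent is non-positive; not an allometric growth law")
  bias <- mean(y - a * x^b)
  allometric_model(a, b, bias_correction_mm = bias, predictor = predictor,
                   region_tag = region_tag, n_fit = length(x),
                   r_squared = max(0, min(1, r2)))
}

#' Predict mantle length from a beak measurement
#'
#' @param model An [allometric_model()].
#' @param beak_length_mm Beak measurement (mm), positive; vectorized.
#' @param apply_correction Add the model's stored bias correction
#'   (default `TRUE`).
#' @return Predicted mantle length (mm).
#' @export
predict_ml <- function(model, beak_length_mm, apply_correction = TRUE) {
  stopifnot(inherits(model, "allometric_model"))
  if (any(beak_length_mm <= 0, na.rm = TRUE))
    stop("beak_length_mm must be positive")
  ml <- model$coefficient_a * beak_length_mm^model$exponent_b
  if (apply_correction) ml <- ml + model$bias_correction_mm
  ml
}

#' Construct or calibrate a length-mass model
#'
#' `mass = a_g * ML^b` with `a_g` in grams.  The default preset is a
#' two-anchor calibration against reconstructed subsection means
#' (ML 7.3 mm ~ 0.033 g and ML 86.9 mm ~ 20.8 g), because the original
#' length-mass coefficients are not printed in the source material; it is
#' an approximation and should be overridden when the true coefficients are
#' available.
#'
#' @param coefficient_a_g Grams multiplier.
#' @param exponent_b Dimensionless exponent.
#' @param source_tag Provenance label.
#' @return Object of class `mass_model`.
#' @export
mass_model <- function(coefficient_a_g, exponent_b,
                       source_tag = "user") {
  stopifnot(coefficient_a_g > 0, exponent_b > 0)
  structure(list(coefficient_a_g = coefficient_a_g, exponent_b = exponent_b,
                 source_tag = source_tag),
            class = "mass_model")
}

#' Two-anchor calibration of a length-mass power law
#'
#' Solves `mass = a_g * ML^b` exactly through two (ML, mass) anchor points.
#'
#' @param ml_mm Length-2 vector of anchor mantle lengths (mm).
#' @param mass_g Length-2 vector of anchor masses (g).
#' @param source_tag Provenance label.
#' @return A [mass_model()].
#' @export
calibrate_mass_model <- function(ml_mm, mass_g, source_tag = "two-anchor") {
  stopifnot(length(ml_mm) == 2L, length(mass_g) == 2L,
            all(ml_mm > 0), all(mass_g > 0), ml_mm[1] != ml_mm[2])
  b <- log(mass_g[2] / mass_g[1]) / log(ml_mm[2] / ml_mm[1])
  a <- mass_g[1] / ml_mm[1]^b
  mass_model(a, b, source_tag = source_tag)
}

#' Default length-mass preset
#'
#' Calibrated through the anchors (7.3 mm, 0.033 g) and (86.9 mm, 20.8 g);
#' gives `a_g ~ 1.87e-4`, `b ~ 2.60`.  Synthetic stand-in for an unpublished
#' regional equation -- see the package vignette.
#'
#' @return A [mass_model()].
#' @export
mass_model_preset <- function() {
  calibrate_mass_model(c(7.3, 86.9), c(0.033, 20.8),
                       source_tag = "calibrated-anchor (synthetic stand-in)")
}

#' Predict body mass from mantle length
#'
#' @param model A [mass_model()].
#' @param ml_mm Mantle length (mm), positive; vectorized.
#' @return Mass (g).
#' @export
predict_mass <- function(model, ml_mm) {
  stopifnot(inherits(model, "mass_model"))
  if (any(ml_mm <= 0, na.rm = TRUE)) stop("ml_mm must be positive")
  model$coefficient_a_g * ml_mm^model$exponent_b
}

#' Reconstruct size-at-formation for every subsection of a trajectory
#'
#' Each subsection is mapped to the beak length at which its material was
#' deposited, then through the allometric chain to mantle length and mass.
#' The anchor is the subsection's posterior edge by default (material at
#' the cut is the newest laid down at that size); `"midpoint"` is available
#' for sensitivity analysis.
#'
#' @param traj A [beak_trajectory()] whose subsections carry crest
#'   coordinates (see [apply_subsection_grid()]).
#' @param model An [allometric_model()] (UCL-based).
#' @param mass_model A [mass_model()]; `NULL` to skip mass.
#' @param anchor `"posterior_edge"` (default) or `"midpoint"`.
#' @return data.frame with `index`, `anchor_mm`, `ml_est_mm`, `mass_est_g`.
#' @export
size_at_subsections <- function(traj, model,
                                mass_model = mass_model_preset(),
                                anchor = c("posterior_edge", "midpoint")) {
  stopifnot(inherits(traj, "beak_trajectory"))
  anchor <- match.arg(anchor)
  s <- traj$subsections
  if (anyNA(s$crest_start_mm) || anyNA(s$crest_end_mm))
    stop("subsections lack crest coordinates; use build_subsection_grid() ",
         "and apply_subsection_grid() first")
  x <- switch(anchor,
              posterior_edge = s$crest_end_mm,
              midpoint = (s$crest_start_mm + s$crest_end_mm) / 2)
  ml <- predict_ml(model, x)
  data.frame(index = s$index, anchor_mm = x, ml_est_mm = ml,
             mass_est_g = if (is.null(mass_model)) NA_real_ else
               predict_mass(mass_model, ml))
}
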