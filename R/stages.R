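# Four-stage ecological periodization: classification by reconstructed
# size, stage durations under linear growth, population biomass partition.

#' Ecological stage definitions
#'
#' The four-stage periodization: (1) epipelagic squid, ML < 20 mm, feeding
#' mostly on copepods; (2) epi-/occasionally mesopelagic squid, ML
#' 20-50 mm, shifting to larger crustaceans, fish and cephalopods; (3)
#' meso-/bathypelagic squid, ML >= 50 mm, mostly fish and cephalopods with
#' frequent cannibalism; (4) non-feeding bathypelagic gelatinous females,
#' ML > 200 mm.  ML bins are half-open `[low, high)`, so 20 mm falls in
#' stage 2 and 50 mm in stage 3; stage 4 requires the gelatinous flag.
#'
#' @return data.frame of stage definitions.
#' @export
stage_definitions <- function() {
  data.frame(
    stage_id = 1:4,
    ml_low_mm = c(0, 20, 50, 200),
    ml_high_mm = c(20, 50, Inf, Inf),
    requires_gelatinous = c(FALSE, FALSE, FALSE, TRUE),
    habitat = c("epipelagic", "epipelagic (occasionally deeper)",
                "meso- and bathypelagic", "bathypelagic"),
    diet = c("copepods and small crustaceans",
             "larger crustaceans, fish, cephalopods",
             "fish and cephalopods (incl. cannibalism)",
             "non-feeding"),
    stringsAsFactors = FALSE)
}

#' Classify an individual into an ecological stage
#'
#' @param ml_mm Mantle length (mm), positive; vectorized.
#' @param gelatinous Logical (recycled): gelatinous-degeneration females
#'   with ML >= 200 mm are stage 4.  A gelatinous flag below 200 mm is
#'   classified stage 3 with a warning (the gelatinous stage is defined
#'   only above 200 mm).
#' @return Integer stage ids (1-4).
#' @export
classify_stage <- function(ml_mm, gelatinous = FALSE) {
  if (any(ml_mm <= 0, na.rm = TRUE)) stop("ml_mm must be positive")
  gelatinous <- rep_len(gelatinous, length(ml_mm))
  base <- ifelse(ml_mm < 20, 1L, ifelse(ml_mm < 50, 2L, 3L))
  gel_ok <- gelatinous & ml_mm >= 200
  if (any(gelatinous & !gel_ok, na.rm = TRUE))
    warning("gelatinous flag with ML < 200 mm: classified by size only")
  ifelse(gel_ok, 4L, base)
}

#' Growth scenario for stage-duration arithmetic
#'
#' @param growth_rate_mm_per_day Linear growth rate (mm/day), positive.
#' @param hatchling_ml_mm Hatchling mantle length (mm), default 3.5.
#' @param days_per_month Calendar convention, default 30.44.
#' @return Object of class `growth_scenario`.
#' @export
growth_scenario <- function(growth_rate_mm_per_day,
                            hatchling_ml_mm = 3.5,
                            days_per_month = 30.44) {
  stopifnot(growth_rate_mm_per_day > 0, hatchling_ml_mm > 0,
            days_per_month > 0)
  structure(list(growth_rate_mm_per_day = growth_rate_mm_per_day,
                 hatchling_ml_mm = hatchling_ml_mm,
                 days_per_month = days_per_month),
            class = "growth_scenario")
}

#' Duration of a size interval under linear growth
#'
#' `months = (to_ml - from_ml) / rate / days_per_month`.  Linear growth is
#' an explicit simplification; durations scale exactly inversely with the
#' growth rate.
#'
#' @param from_ml,to_ml Interval endpoints (mm), `to_ml >= from_ml`.
#' @param scenario A [growth_scenario()].
#' @return Duration in months.
#' @export
stage_duration <- function(from_ml, to_ml, scenario) {
  stopifnot(inherits(scenario, "growth_scenario"))
  if (any(to_ml < from_ml)) stop("to_ml must be >= from_ml")
  (to_ml - from_ml) / scenario$growth_rate_mm_per_day /
    scenario$days_per_month
}

#' Partition population biomass across ecological stages
#'
#' Percentages are each component's share of the summed biomass, rounded
#' to integers for reporting (so they sum to 100 up to rounding).  An
#' optional gelatinous-female component is derived from a named base
#' component as `base * sex_ratio * survival_fraction` and reported
#' separately (it is a subset of the base component, not an addition to
#' the total).
#'
#' @param components data.frame with columns `label`, `biomass_mt`
#'   (megatonnes, >= 0).
#' @param gelatinous Optional list with `base` (a label in `components`),
#'   `sex_ratio`, `survival_fraction`.
#' @return List with `table` (label, biomass_mt, percent, percent_exact),
#'   `total_mt`, and optionally `gelatinous_mt`, `gelatinous_percent`.
#' @export
biomass_partition <- function(components, gelatinous = NULL) {
  stopifnot(is.data.frame(components),
            all(c("label", "biomass_mt") %in% names(components)),
            all(components$biomass_mt >= 0))
  total <- sum(components$biomass_mt)
  if (total == 0) stop("zero total biomass")
  pct <- components$biomass_mt / total * 100
  out <- list(table = data.frame(label = components$label,
                                 biomass_mt = components$biomass_mt,
                                 percent = round(pct),
                                 percent_exact = pct,
                                 stringsAsFactors = FALSE),
              total_mt = total)
  if (!is.null(gelatinous)) {
    stopifnot(gelatinous$base %in% components$label,
              gelatinous$sex_ratio >= 0, gelatinous$sex_ratio <= 1,
              gelatinous$survival_fraction >= 0,
              gelatinous$survival_fraction <= 1)
    base_mt <- components$biomass_mt[components$label == gelatinous$base]
    gel <- base_mt * gelatinous$sex_ratio * gelatinous$survival_fraction
    out$gelatinous_mt <- gel
    out$gelatinous_percent <- gel / total * 100
  }
  out
}
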