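#' beaktraj: life-history reconstruction from beak isotope trajectories
#'
#' Cephalopod beaks grow by accretion: the rostrum tip carries the oldest
#' chitin, the posterior edge of the crest the newest.  Sequential
#' subsections cut along the crest therefore form an ontogenetic archive of
#' the animal's diet (d15N, trophic level) and habitat (d13C).  This package
#' implements the full analysis chain for such trajectories: tidy data
#' import, beak allometry, trophic-level estimation, individual
#' specialization, rank-based trajectory statistics, isotopic-niche
#' geometry, Bayesian diet mixing, and an ecological life-stage classifier,
#' together with a synthetic-data generator that makes every step testable
#' without access to the original measurements.
#'
#' @importFrom stats var sd cor cov complete.cases pnorm pchisq pt qchisq
#'   rnorm runif rWishart dnorm ptukey optim p.adjust acf
#'   rbinom dhyper rgamma
#' @importFrom utils read.csv write.csv combn head tail
#' @importFrom grDevices chull
#' @keywords internal
"_PACKAGE"

# ---- domain constructors ----------------------------------------------------

#' Construct a single beak trajectory
#'
#' An individual's record: metadata plus an ordered table of crest
#' subsections.  Subsection indices are 1-based, anterior (rostrum tip) to
#' posterior (crest end).  Unanalysed subsections are kept as rows with `NA`
#' isotope values rather than dropped, so that positional information (which
#' subsection failed) is never lost.
#'
#' @param individual_id Character scalar, unique within a population.
#' @param subsections data.frame with columns `index`, `d13c`, `d15n` and
#'   optionally `cn_ratio`, `sample_mass_mg`, `crest_start_mm`,
#'   `crest_end_mm`.
#' @param sex One of `"female"`, `"male"`, `"unknown"`.
#' @param mantle_length_mm Measured adult mantle length (mm), positive.
#' @param body_mass_g Optional measured body mass (g).
#' @param maturity_stage Optional ordinal maturity label ("0".."VI").
#' @param gelatinous Logical; `TRUE` for spent females in gelatinous
#'   degeneration.
#' @param station Free-form station / haul metadata.
#' @return An object of class `beak_trajectory`.
#' @export
beak_trajectory <- function(individual_id, subsections,
                            sex = "unknown",
                            mantle_length_mm = NA_real_,
                            body_mass_g = NA_real_,
                            maturity_stage = NA_character_,
                            gelatinous = FALSE,
                            station = NA_character_) {
  stopifnot(is.character(individual_id), length(individual_id) == 1L)
  sex <- match.arg(sex, c("female", "male", "unknown"))
  if (!is.data.frame(subsections) || !all(c("index", "d13c", "d15n") %in%
                                          names(subsections)))
    stop("`subsections` must be a data.frame with columns index, d13c, d15n")
  if (nrow(subsections) < 2L)
    stop("a trajectory needs at least 2 subsections (individual ",
         individual_id, ")")
  if (anyDuplicated(subsections$index))
    stop("duplicate subsection indices for individual ", individual_id)
  subsections <- subsections[order(subsections$index), , drop = FALSE]
  for (col in c("cn_ratio", "sample_mass_mg", "crest_start_mm",
                "crest_end_mm"))
    if (is.null(subsections[[col]])) subsections[[col]] <- NA_real_
  if (!is.na(mantle_length_mm) && mantle_length_mm <= 0)
    stop("mantle_length_mm must be positive")
  bad_cn <- !is.na(subsections$cn_ratio) & subsections$cn_ratio <= 0
  if (any(bad_cn)) stop("cn_ratio must be positive where present")
  rownames(subsections) <- NULL
  structure(list(individual_id = individual_id,
                 sex = sex,
                 mantle_length_mm = as.numeric(mantle_length_mm),
                 body_mass_g = as.numeric(body_mass_g),
                 maturity_stage = maturity_stage,
                 gelatinous = isTRUE(gelatinous),
                 station = station,
                 subsections = subsections),
            class = "beak_trajectory")
}

#' @export
print.beak_trajectory <- function(x, ...) {
  n_ok <- sum(!is.na(x$subsections$d13c) | !is.na(x$subsections$d15n))
  cat(sprintf("<beak_trajectory %s: %s, ML %s mm, %d subsections (%d analysed)>\n",
              x$individual_id, x$sex,
              format(x$mantle_length_mm), nrow(x$subsections), n_ok))
  invisible(x)
}

#' Construct a population sample of beak trajectories
#'
#' @param trajectories List of [beak_trajectory()] objects with unique ids.
#' @param whole_beak Optional data.frame of individuals analysed as whole
#'   powdered beaks (columns `individual_id`, `sex`, `ml_mm`, `d13c`,
#'   `d15n`), used for population-level pooling in niche analyses.
#' @return An object of class `beak_population`.
#' @export
beak_population <- function(trajectories, whole_beak = NULL) {
  if (length(trajectories) == 0L) stop("empty population")
  stopifnot(all(vapply(trajectories, inherits, logical(1), "beak_trajectory")))
  ids <- vapply(trajectories, `[[`, character(1), "individual_id")
  if (anyDuplicated(ids))
    stop("duplicate individual ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(trajectories) <- ids
  structure(list(trajectories = trajectories, whole_beak = whole_beak),
            class = "beak_population")
}

#' @export
print.beak_population <- function(x, ...) {
  cat(sprintf("<beak_population: %d trajectories%s>\n",
              length(x$trajectories),
              if (is.null(x$whole_beak)) "" else
                sprintf(" + %d whole-beak individuals", nrow(x$whole_beak))))
  invisible(x)
}

#' @export
length.beak_population <- function(x) length(x$trajectories)

# ---- tidy CSV io ------------------------------------------------------------

.pop_columns <- c("individual_id", "subsection", "d13c", "d15n", "cn_ratio",
                  "sample_mass_mg", "crest_start_mm", "crest_end_mm",
                  "sex", "ml_mm", "mass_g", "maturity_stage", "gelatinous",
                  "station")

#' Read a population of beak trajectories from tidy CSV
#'
#' The canonical exchange format is long/tidy: one row per individual x
#' subsection, UTF-8, header row, `.` decimal separator.  Required columns:
#' `individual_id`, `subsection`, `d13c`, `d15n`.  Optional columns:
#' `cn_ratio`, `sample_mass_mg`, `crest_start_mm`, `crest_end_mm`, `sex`,
#' `ml_mm`, `mass_g`, `maturity_stage`, `gelatinous`, `station`.  Blank
#' isotope cells are preserved as missing measurements; the row (and hence
#' the subsection's position in the trajectory) is retained.
#'
#' @param path Path to a CSV file.
#' @return A [beak_population()].
#' @seealso [write_population()] for the inverse.
#' @export
read_population <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("individual_id", "subsection", "d13c", "d15n")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  key <- paste(df$individual_id, df$subsection)
  if (anyDuplicated(key))
    stop("duplicate (individual, subsection) pairs: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (!is.null(df$sex)) {
    bad <- !df$sex %in% c("female", "male", "unknown", NA, "")
    if (any(bad))
      stop("unknown sex code in rows ",
           paste(which(bad), collapse = ", "), ": ",
           paste(unique(df$sex[bad]), collapse = ", "))
  }
  population_from_tidy(df)
}

#' Assemble a population from an in-memory tidy data.frame
#'
#' Same schema as [read_population()]; useful when the table comes from the
#' simulator or another pipeline rather than a file.
#'
#' @param df Tidy data.frame, one row per individual x subsection.
#' @return A [beak_population()].
#' @export
population_from_tidy <- function(df) {
  meta1 <- function(v) if (is.null(v)) NA else v[1L]
  trajectories <- lapply(split(df, df$individual_id), function(d) {
    d <- d[order(d$subsection), , drop = FALSE]
    sex <- meta1(d$sex)
    if (is.na(sex) || !nzchar(sex)) sex <- "unknown"
    sub <- data.frame(index = as.integer(d$subsection),
                      d13c = as.numeric(d$d13c),
                      d15n = as.numeric(d$d15n))
    for (col in c("cn_ratio", "sample_mass_mg", "crest_start_mm",
                  "crest_end_mm"))
      sub[[col]] <- if (is.null(d[[col]])) NA_real_ else as.numeric(d[[col]])
    beak_trajectory(
      individual_id = as.character(d$individual_id[1L]),
      subsections = sub,
      sex = sex,
      mantle_length_mm = as.numeric(meta1(d$ml_mm)),
      body_mass_g = as.numeric(meta1(d$mass_g)),
      maturity_stage = as.character(meta1(d$maturity_stage)),
      gelatinous = isTRUE(as.logical(meta1(d$gelatinous))),
      station = as.character(meta1(d$station)))
  })
  # keep original file order of individuals
  first_seen <- unique(as.character(df$individual_id))
  beak_population(trajectories[first_seen])
}

#' Flatten a population to a tidy data.frame
#'
#' @param pop A [beak_population()].
#' @return data.frame with one row per individual x subsection.
#' @export
population_to_tidy <- function(pop) {
  stopifnot(inherits(pop, "beak_population"))
  out <- lapply(pop$trajectories, function(tr) {
    s <- tr$subsections
    data.frame(individual_id = tr$individual_id,
               subsection = s$index,
               d13c = s$d13c, d15n = s$d15n,
               cn_ratio = s$cn_ratio, sample_mass_mg = s$sample_mass_mg,
               crest_start_mm = s$crest_start_mm,
               crest_end_mm = s$crest_end_mm,
               sex = tr$sex, ml_mm = tr$mantle_length_mm,
               mass_g = tr$body_mass_g,
               maturity_stage = tr$maturity_stage,
               gelatinous = tr$gelatinous, station = tr$station,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a population to tidy CSV
#'
#' Inverse of [read_population()]: `read_population(write_population(pop, f))`
#' is lossless, including missing-measurement cells.
#'
#' @param pop A [beak_population()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_population <- function(pop, path) {
  write.csv(population_to_tidy(pop), path, row.names = FALSE, na = "")
  invisible(path)
}

# ---- subsection geometry ----------------------------------------------------

#' Tile a beak crest into cutting subsections
#'
#' The cutting scheme uses fine subsections (target width `fine_mm`) from
#' the rostrum tip to the crest midpoint, and coarse subsections (target
#' width `coarse_mm`) from the midpoint to the end of the tanned crest.
#' "As close to the target as possible" is realized by dividing each half
#' into `round(half / target)` equal tiles (ties round half-up, never fewer
#' than one), then rescaling the width uniformly within the half so the
#' tiles fit exactly.  The tiling is deterministic and exact:
#' the widths always sum to `crest_length_mm`.
#'
#' @param crest_length_mm Total tanned crest length (mm), positive.
#' @param fine_mm Target width of anterior-half subsections (default 1 mm).
#' @param coarse_mm Target width of posterior-half subsections (default 2 mm).
#' @return data.frame with columns `index`, `crest_start_mm`,
#'   `crest_end_mm`, `zone` (`"fine"` / `"coarse"`).
#' @export
build_subsection_grid <- function(crest_length_mm, fine_mm = 1,
                                  coarse_mm = 2) {
  if (!is.finite(crest_length_mm) || crest_length_mm <= 0)
    stop("crest_length_mm must be positive")
  if (fine_mm <= 0 || coarse_mm <= 0) stop("tile widths must be positive")
  half <- crest_length_mm / 2
  round_half_up <- function(x) floor(x + 0.5)
  n_fine <- max(1L, as.integer(round_half_up(half / fine_mm)))
  n_coarse <- max(1L, as.integer(round_half_up(half / coarse_mm)))
  edges <- c(seq(0, half, length.out = n_fine + 1L),
             seq(half, crest_length_mm, length.out = n_coarse + 1L)[-1L])
  n <- n_fine + n_coarse
  data.frame(index = seq_len(n),
             crest_start_mm = edges[seq_len(n)],
             crest_end_mm = edges[seq_len(n) + 1L],
             zone = rep(c("fine", "coarse"), c(n_fine, n_coarse)),
             stringsAsFactors = FALSE)
}

#' Attach crest coordinates from a grid to a trajectory
#'
#' @param traj A [beak_trajectory()].
#' @param grid Output of [build_subsection_grid()] covering at least the
#'   trajectory's subsection indices.
#' @return The trajectory with `crest_start_mm` / `crest_end_mm` filled in.
#' @export
apply_subsection_grid <- function(traj, grid) {
  stopifnot(inherits(traj, "beak_trajectory"))
  idx <- traj$subsections$index
  if (max(idx) > nrow(grid))
    stop("grid has ", nrow(grid), " subsections but trajectory uses index ",
         max(idx))
  traj$subsections$crest_start_mm <- grid$crest_start_mm[idx]
  traj$subsections$crest_end_mm <- grid$crest_end_mm[idx]
  traj
}

# ---- quality control --------------------------------------------------------

#' Advisory quality-control flags for an isotope measurement
#'
#' QC is advisory, never a filter: the observed beak-chitin C:N band and the
#' instrumental replicate precision are reported as flags, and it is the
#' analyst's call what to do with them.  Defaults: C:N band 3.05-3.86
#' (observed span in beak chitin), replicate SD threshold 0.2 per mil.
#'
#' @param d13c,d15n Isotope values (per mil); may be `NA`.
#' @param cn_ratio Optional mass C:N ratio.
#' @param replicate_sd Optional replicate standard deviation (per mil).
#' @param qc List with elements `cn_band` (length-2 numeric) and
#'   `precision_permil`.
#' @return Character vector of flags (possibly empty): `"cn_out_of_band"`
#'   (warning level), `"low_precision"` (info level), `"non_finite_delta"`.
#' @export
validate_measurement <- function(d13c = NA_real_, d15n = NA_real_,
                                 cn_ratio = NA_real_,
                                 replicate_sd = NA_real_,
                                 qc = list(cn_band = c(3.05, 3.86),
                                           precision_permil = 0.2)) {
  flags <- character(0)
  vals <- c(d13c, d15n)
  if (any(!is.na(vals) & !is.finite(vals)))
    flags <- c(flags, "non_finite_delta")
  if (!is.na(cn_ratio) &&
      (cn_ratio < qc$cn_band[1] || cn_ratio > qc$cn_band[2]))
    flags <- c(flags, "cn_out_of_band")
  if (!is.na(replicate_sd) && replicate_sd > qc$precision_permil)
    flags <- c(flags, "low_precision")
  flags
}
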