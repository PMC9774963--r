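# Packaged fixture: the published per-individual summary table
# (14 adult squid, per-isotope ranges, specialization indices).  These are
# printed summary values transcribed for acceptance testing -- they are
# not raw measurements.

#' Published per-individual trajectory summary fixture
#'
#' One row per individual x character (`d13c`, `d15n`, `tl`): sample
#' counts, printed min / max / mean +/- SE, specialization index `s`,
#' subsection numbers of the extremes, and the two range columns
#' (min-to-max, newest-to-oldest).  `NA` marks cells printed as not
#' analysed / not applicable (the d13C row of individual M7, whose d13C
#' series succeeded in only 4 of 17 subsections).
#'
#' Known transcription caveat, preserved as printed: individual F1's d15N
#' min-max (7.9-13.5) is inconsistent with its printed min-to-max range
#' (4.60, where 13.5 - 7.9 = 5.6); the TL range column (1.47 ~ 5.6/3.8)
#' indicates the 4.60 is a typo in the source table.  Consumers of this
#' fixture should screen rows with [table1_consistent_rows()].
#'
#' @return data.frame fixture.
#' @export
table1_fixture <- function() {
  tab <- read.csv(system.file("extdata", "table1_summary.csv",
                              package = "beaktraj"),
                  stringsAsFactors = FALSE)
  tab
}

#' Rows of the summary fixture whose printed extremes match their range
#'
#' Returns, for a given character (`"d15n"` by default), the individual
#' ids whose printed `max - min` agrees with the printed min-to-max range
#' within `tol`.  The printed min / max are rounded to 0.1 per mil while
#' the ranges are printed to 0.01, so the default tolerance is 0.1 (half
#' an ulp of each rounded endpoint); only a genuine inconsistency (F1's
#' d15N row) fails it.
#'
#' @param character_ `"d13c"`, `"d15n"` or `"tl"`.
#' @param tol Agreement tolerance (per mil).
#' @return Character vector of individual ids.
#' @export
table1_consistent_rows <- function(character_ = "d15n", tol = 0.1) {
  tab <- table1_fixture()
  tab <- tab[tab$character == character_ & !is.na(tab$range_min_max), ]
  ok <- abs((tab$max_value - tab$min_value) - tab$range_min_max) <= tol
  tab$squid[ok]
}
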