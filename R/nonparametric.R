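# Rank-based tests implemented from first principles: Mann-Whitney U,
# Kruskal-Wallis + Dunn, Skillings-Mack + Nemenyi for incomplete blocks,
# Pearson chi-square and Fisher's exact test.

.test_result <- function(statistic, statistic_name, p_value, df = NA_real_,
                         method = "", extra = list()) {
  structure(c(list(statistic = statistic, statistic_name = statistic_name,
                   df = df, p_value = p_value, method = method), extra),
            class = "beaktraj_test")
}

#' @export
print.beaktraj_test <- function(x, ...) {
  cat(sprintf("%s: %s = %.4g%s, p = %.4g\n", x$method, x$statistic_name,
              x$statistic,
              if (is.na(x$df)) "" else sprintf(", df = %g", x$df),
              x$p_value))
  invisible(x)
}

# ---- Mann-Whitney -----------------------------------------------------------

#' Mann-Whitney U test
#'
#' Two-sample rank-sum test with midranks for ties.  The reported statistic
#' is `min(U_a, U_b)` (so `U_a + U_b = n_a * n_b` always).  P-value
#' methods: `"exact"` enumerates the null distribution by network counting
#' (only valid without ties), `"normal"` uses the normal approximation with
#' continuity correction and tie-corrected variance, and the default
#' `"auto"` picks exact when the data are tie-free and both groups have at
#' most `exact_limit` observations, otherwise normal.
#'
#' @param group_a,group_b Numeric vectors, non-empty.
#' @param p_method `"auto"`, `"exact"` or `"normal"`.
#' @param exact_limit Largest per-group n for which `"auto"` uses the exact
#'   distribution (default 10).
#' @return A test-result list: `statistic` (U), `p_value`, `u_a`, `u_b`.
#' @export
mann_whitney_u <- function(group_a, group_b,
                           p_method = c("auto", "exact", "normal"),
                           exact_limit = 10L) {
  p_method <- match.arg(p_method)
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  r <- rank(c(a, b))
  u_a <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_b <- n1 * n2 - u_a
  u <- min(u_a, u_b)
  ties <- anyDuplicated(c(a, b)) > 0L
  if (p_method == "auto")
    p_method <- if (!ties && max(n1, n2) <= exact_limit) "exact" else "normal"
  if (p_method == "exact") {
    if (ties) stop("exact p-value is not defined with ties; use p_method = 'normal'")
    p <- .mwu_exact_p(u, n1, n2)
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    tie_tab <- table(c(a, b))
    sigma2 <- n1 * n2 / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- (u - mu + 0.5) / sqrt(sigma2)     # u <= mu, shift toward the mean
    p <- min(1, 2 * pnorm(z))
  }
  .test_result(u, "U", p,
               method = sprintf("Mann-Whitney U (%s p, midranks)", p_method),
               extra = list(u_a = u_a, u_b = u_b, n = c(n1, n2)))
}

# exact null distribution of U: the counts of arrangements with a given U
# are the coefficients of the Gaussian binomial [n1+n2 choose n1]_q,
# built up exactly by polynomial products
.mwu_exact_p <- function(u, n1, n2) {
  poly <- 1
  for (i in seq_len(n1)) {
    # multiply by (1 - q^(n2 + i)) / (1 - q^i) as power series
    poly <- .poly_mult_cyclotomic(poly, n2 + i, i, n1 * n2)
  }
  total <- choose(n1 + n2, n1)
  cdf_lo <- sum(poly[seq_len(floor(u) + 1L)]) / total
  sf_hi <- sum(poly[(n1 * n2 - floor(u) + 1L):(n1 * n2 + 1L)]) / total
  min(1, cdf_lo + sf_hi)
}

# multiply power series by (1 + q + ... + q^(num-1)) then divide by
# (1 + q + ... + q^(den-1)); both exact in integers, truncated at maxdeg
.poly_mult_cyclotomic <- function(poly, num, den, maxdeg) {
  p <- numeric(maxdeg + 1L)
  p[seq_along(poly)] <- poly
  # multiply by (1 - q^num): p - shift(p, num)
  q <- p
  if (num <= maxdeg)
    q[(num + 1L):(maxdeg + 1L)] <- q[(num + 1L):(maxdeg + 1L)] -
      p[seq_len(maxdeg + 1L - num)]
  # divide by (1 - q^den): cumulative sums with lag den
  for (k in (den + 1L):(maxdeg + 1L))
    q[k] <- q[k] + q[k - den]
  q
}

# ---- Kruskal-Wallis + Dunn --------------------------------------------------

#' Kruskal-Wallis H test
#'
#' K-sample rank test with midranks and the standard tie correction;
#' p-value from the chi-square approximation on k - 1 df.  Identical data
#' across all groups give H = 0, p = 1.
#'
#' @param groups List of numeric vectors (>= 2 groups, each non-empty).
#' @return Test-result list with `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(lengths(groups) == 0L)) stop("every group must be non-empty")
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  rsums <- tapply(r, g, sum)
  h <- 12 / (n * (n + 1)) * sum(rsums^2 / lengths(groups)) - 3 * (n + 1)
  tie_tab <- table(x)
  correction <- 1 - sum(tie_tab^3 - tie_tab) / (n^3 - n)
  k <- length(groups)
  if (correction == 0)  # every value identical
    return(.test_result(0, "H", 1, df = k - 1,
                        method = "Kruskal-Wallis (tie-corrected)"))
  h <- h / correction
  .test_result(h, "H", pchisq(h, k - 1, lower.tail = FALSE), df = k - 1,
               method = "Kruskal-Wallis (tie-corrected)")
}

#' Dunn's post hoc test after Kruskal-Wallis
#'
#' Pairwise z statistics on mean ranks with tie correction.  The default
#' reports unadjusted two-sided p-values; `"holm"` and `"bonferroni"`
#' adjustments are available.
#'
#' @param groups List of numeric vectors.
#' @param adjust `"none"` (default), `"holm"` or `"bonferroni"`.
#' @return List with matrices `z` and `p_value` (k x k, diagonal `NA`).
#' @export
dunn_posthoc <- function(groups, adjust = c("none", "holm", "bonferroni")) {
  adjust <- match.arg(adjust)
  stopifnot(is.list(groups), length(groups) >= 2L)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ni <- lengths(groups)
  tie_tab <- table(x)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (n - 1))
  k <- length(groups)
  z <- p <- matrix(NA_real_, k, k)
  pairs <- combn(k, 2)
  zs <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ni[i] + 1 / ni[j]))
    (rbar[i] - rbar[j]) / se
  })
  ps <- 2 * pnorm(-abs(zs))
  ps <- switch(adjust, none = ps, holm = p.adjust(ps, "holm"),
               bonferroni = p.adjust(ps, "bonferroni"))
  for (c_ in seq_len(ncol(pairs))) {
    i <- pairs[1, c_]; j <- pairs[2, c_]
    z[i, j] <- z[j, i] <- zs[c_]
    p[i, j] <- p[j, i] <- ps[c_]
  }
  list(z = z, p_value = p, adjust = adjust)
}

# ---- Skillings-Mack ---------------------------------------------------------

# shared machinery: adjusted rank sums T and their null covariance
.sm_core <- function(data) {
  if (!is.matrix(data)) data <- as.matrix(data)
  t_ <- ncol(data)
  if (t_ < 2L) stop("need at least 2 treatments")
  keep <- rowSums(!is.na(data)) >= 2L
  if (any(!keep))
    warning(sum(!keep), " block(s) with <2 observed treatments dropped")
  data <- data[keep, , drop = FALSE]
  if (nrow(data) == 0L) stop("no usable blocks")
  observed_any <- colSums(!is.na(data)) > 0L
  if (any(!observed_any))
    stop("treatment(s) observed in no block: ",
         paste(which(!observed_any), collapse = ", "))
  n <- nrow(data)
  A <- matrix(0, n, t_)
  for (i in seq_len(n)) {
    obs <- which(!is.na(data[i, ]))
    k <- length(obs)
    r <- rank(data[i, obs])
    A[i, obs] <- sqrt(12 / (k + 1)) * (r - (k + 1) / 2)
  }
  T <- colSums(A)
  # null covariance: var of adjusted rank = k_i - 1 for observed cells,
  # pairwise covariance -1 when both observed in the block
  Sigma <- matrix(0, t_, t_)
  for (i in seq_len(n)) {
    obs <- !is.na(data[i, ])
    k <- sum(obs)
    Si <- matrix(0, t_, t_)
    Si[obs, obs] <- -1
    diag(Si)[obs] <- k - 1
    Sigma <- Sigma + Si
  }
  list(T = T, Sigma = Sigma, n_blocks = n, t = t_, data = data)
}

# Moore-Penrose pseudo-inverse via SVD (Sigma is singular by construction)
.pinv <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*% diag(1 / s$d[pos], sum(pos)) %*%
    t(s$u[, pos, drop = FALSE])
}

#' Skillings-Mack test for incomplete block designs
#'
#' Rank test for treatment differences across blocks when some block x
#' treatment cells are missing (here: beak subsections across individuals
#' whose beaks have different numbers of subsections).  Observed cells are
#' midranked within each block, centred and scaled by
#' `sqrt(12 / (k_i + 1))`, and summed per treatment; the statistic is the
#' quadratic form of these sums under the null covariance implied by the
#' missingness pattern (generalized inverse).  With complete data the
#' statistic reduces exactly to Friedman's chi-square.  P-value from the
#' chi-square distribution on t - 1 df.  Blocks with fewer than two
#' observed treatments are dropped with a warning.
#'
#' @param data Numeric matrix, blocks (individuals) x treatments
#'   (subsections); `NA` marks missing cells.
#' @return Test-result list with `statistic` (SM), `df`, `p_value`.
#' @export
skillings_mack <- function(data) {
  core <- .sm_core(data)
  sm <- drop(core$T %*% .pinv(core$Sigma) %*% core$T)
  .test_result(sm, "SM", pchisq(sm, core$t - 1, lower.tail = FALSE),
               df = core$t - 1,
               method = "Skillings-Mack (chi-square approximation)")
}

#' Nemenyi post hoc test for (incomplete) block designs
#'
#' Pairwise comparisons following [skillings_mack()].  The contrast for a
#' treatment pair is the difference of adjusted rank sums standardized by
#' its null covariance; two-sided p-values come from the studentized range
#' distribution with t groups (infinite df), which for complete data
#' coincides with the classical Friedman-Nemenyi test on mean ranks.
#'
#' @param data Numeric matrix, blocks x treatments, `NA` allowed.
#' @return List with matrices `z` (standardized contrasts) and `p_value`
#'   (symmetric, diagonal `NA`).
#' @export
nemenyi_posthoc <- function(data) {
  core <- .sm_core(data)
  t_ <- core$t
  z <- p <- matrix(NA_real_, t_, t_)
  for (i in seq_len(t_ - 1L)) for (j in (i + 1L):t_) {
    v <- core$Sigma[i, i] + core$Sigma[j, j] - 2 * core$Sigma[i, j]
    if (v <= 0) next
    zij <- (core$T[i] - core$T[j]) / sqrt(v)
    z[i, j] <- z[j, i] <- zij
    pij <- ptukey(abs(zij) * sqrt(2), nmeans = t_, df = Inf,
                  lower.tail = FALSE)
    p[i, j] <- p[j, i] <- min(1, pij)
  }
  list(z = z, p_value = p)
}

# ---- contingency tests ------------------------------------------------------

#' Pearson chi-square test on a contingency table
#'
#' `sum((O - E)^2 / E)` with expected counts from the product of margins;
#' no continuity correction by default (configurable for 2x2).
#'
#' @param table Matrix of non-negative counts.
#' @param correct Apply Yates continuity correction (2x2 only).
#' @return Test-result list with `statistic` (chi2), `df`, `p_value`,
#'   `expected`.
#' @export
chi_square_test <- function(table, correct = FALSE) {
  m <- as.matrix(table)
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  if (any(rs == 0) || any(cs == 0)) stop("zero-margin table")
  e <- outer(rs, cs) / n
  d <- abs(m - e)
  if (correct && all(dim(m) == 2L)) d <- pmax(0, d - 0.5)
  stat <- sum(d^2 / e)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  .test_result(stat, "chi2", pchisq(stat, df, lower.tail = FALSE), df = df,
               method = sprintf("Pearson chi-square%s",
                                if (correct) " (Yates)" else ""),
               extra = list(expected = e))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by hypergeometric enumeration: the sum of the
#' probabilities of all tables (with the observed margins) no more likely
#' than the observed one (with a small relative tolerance for float ties).
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return Test-result list with `statistic` (odds-ratio estimate, sample),
#'   `p_value`.
#' @export
fisher_exact <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == 2L)) stop("Fisher's exact test here is restricted to 2x2 tables")
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  if (any(rs == 0) || any(cs == 0)) stop("zero-margin table")
  support <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
  dens <- dhyper(support, rs[1], rs[2], cs[1])
  p_obs <- dhyper(m[1, 1], rs[1], rs[2], cs[1])
  p <- min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  .test_result(or, "OR", p, method = "Fisher exact (two-sided, enumeration)")
}
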