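test_that("Mann-Whitney reproduces the published by-sex comparisons", {
  cols <- table1_sex_columns()
  r1 <- mann_whitney_u(cols$d13c_minmax_f, cols$d13c_minmax_m)
  expect_equal(r1$statistic, 17.5)
  expect_equal(round(r1$p_value, 2), 0.67)
  r2 <- mann_whitney_u(cols$d13c_firstlast_f, cols$d13c_firstlast_m)
  expect_equal(r2$statistic, 20)
  expect_equal(round(r2$p_value, 2), 0.95)
  r3 <- mann_whitney_u(cols$d15n_firstlast_f, cols$d15n_firstlast_m)
  expect_equal(r3$statistic, 22)
  expect_equal(round(r3$p_value, 2), 0.85)
})

test_that("U halves always sum to n_a * n_b and exact matches wilcox", {
  set.seed(11)
  for (i in 1:10) {
    a <- rnorm(sample(2:9, 1)); b <- rnorm(sample(2:9, 1))
    r <- mann_whitney_u(a, b)
    expect_equal(r$u_a + r$u_b, length(a) * length(b))
    expect_equal(mann_whitney_u(a, b, "exact")$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value)
    expect_equal(mann_whitney_u(a, b, "normal")$p_value,
                 wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
  }
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("Kruskal-Wallis matches base R and degenerates correctly", {
  set.seed(12)
  g <- list(rnorm(8), rnorm(10) + 0.4, rnorm(7) - 0.2)
  mine <- kruskal_wallis(g)
  oracle <- kruskal.test(g)
  expect_equal(mine$statistic, unname(oracle$statistic))
  expect_equal(mine$p_value, oracle$p.value)
  # ties
  gt <- list(c(1, 2, 2, 3), c(2, 3, 3, 4), c(1, 1, 4, 4))
  expect_equal(kruskal_wallis(gt)$statistic,
               unname(kruskal.test(gt)$statistic))
  # all identical values
  r0 <- kruskal_wallis(list(rep(2, 4), rep(2, 5)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # two-group case roughly agrees with Mann-Whitney
  a <- rnorm(15); b <- rnorm(15) + 0.6
  expect_lt(abs(kruskal_wallis(list(a, b))$p_value -
                mann_whitney_u(a, b, "normal")$p_value), 0.03)
})

test_that("Kruskal-Wallis asymptotic p agrees with a permutation oracle", {
  set.seed(13)
  g <- list(rnorm(5), rnorm(5) + 1.2, rnorm(5) - 0.3)
  h_obs <- kruskal_wallis(g)$statistic
  x <- unlist(g); lab <- rep(1:3, each = 5)
  perm <- replicate(4000, {
    sh <- sample(lab)
    kruskal_wallis(split(x, sh))$statistic
  })
  p_perm <- mean(perm >= h_obs - 1e-12)
  expect_lt(abs(kruskal_wallis(g)$p_value - p_perm), 0.03)
})

test_that("Dunn post hoc gives symmetric z matrices and sane adjustment", {
  set.seed(14)
  g <- list(rnorm(10), rnorm(10) + 2, rnorm(10))
  d <- dunn_posthoc(g)
  expect_equal(d$z[1, 2], d$z[2, 1])
  expect_true(all(is.na(diag(d$p_value))))
  expect_lt(d$p_value[1, 2], 0.01)   # separated pair
  dh <- dunn_posthoc(g, adjust = "holm")
  expect_true(all(dh$p_value >= d$p_value, na.rm = TRUE))
})

test_that("Skillings-Mack equals Friedman on complete blocks", {
  set.seed(15)
  for (i in 1:8) {
    n <- sample(4:10, 1); k <- sample(3:6, 1)
    m <- matrix(rnorm(n * k), n, k)
    sm <- skillings_mack(m)
    fr <- friedman.test(m)
    expect_equal(sm$statistic, unname(fr$statistic), tolerance = 1e-10)
    expect_equal(sm$df, unname(fr$parameter))
  }
})

test_that("Skillings-Mack statistic matches an independent construction with a missing cell", {
  # independent oracle: build T and Sigma directly from first principles
  sm_oracle <- function(m) {
    t_ <- ncol(m); Tv <- numeric(t_); Sig <- matrix(0, t_, t_)
    for (i in seq_len(nrow(m))) {
      obs <- which(!is.na(m[i, ])); k <- length(obs)
      A <- numeric(t_)
      A[obs] <- sqrt(12 / (k + 1)) * (rank(m[i, obs]) - (k + 1) / 2)
      Tv <- Tv + A
      Si <- matrix(0, t_, t_); Si[obs, obs] <- -1; diag(Si)[obs] <- k - 1
      Sig <- Sig + Si
    }
    ev <- eigen(Sig, symmetric = TRUE)
    keep <- ev$values > 1e-9
    ginv <- ev$vectors[, keep] %*% diag(1 / ev$values[keep]) %*%
      t(ev$vectors[, keep])
    drop(Tv %*% ginv %*% Tv)
  }
  set.seed(16)
  m <- matrix(rnorm(12), 4, 3)
  m[2, 3] <- NA
  expect_equal(skillings_mack(m)$statistic, sm_oracle(m), tolerance = 1e-10)
  m2 <- matrix(rnorm(30), 6, 5); m2[cbind(c(1, 3, 5), c(2, 4, 1))] <- NA
  expect_equal(skillings_mack(m2)$statistic, sm_oracle(m2),
               tolerance = 1e-10)
})

test_that("Skillings-Mack detects a dominant treatment and handles edge cases", {
  set.seed(17)
  m <- matrix(rnorm(40), 10, 4)
  m[, 2] <- m[, 2] + 3          # stochastically dominant treatment
  m[1, 1] <- NA
  expect_lt(skillings_mack(m)$p_value, 0.01)
  # a treatment observed nowhere
  m2 <- matrix(rnorm(12), 4, 3); m2[, 2] <- NA
  expect_error(skillings_mack(m2), "no block")
  # blocks with <2 observations are dropped with a warning
  m3 <- matrix(rnorm(12), 4, 3); m3[1, 2:3] <- NA
  expect_warning(skillings_mack(m3), "dropped")
})

test_that("Nemenyi post hoc agrees with the classical mean-rank formula on complete data", {
  # independent oracle: Friedman-Nemenyi on mean ranks, studentized range
  nemenyi_oracle <- function(m) {
    n <- nrow(m); k <- ncol(m)
    rmean <- colMeans(t(apply(m, 1, rank)))
    p <- matrix(NA_real_, k, k)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      q <- abs(rmean[i] - rmean[j]) / sqrt(k * (k + 1) / (6 * n))
      p[i, j] <- p[j, i] <- ptukey(q * sqrt(2), k, Inf, lower.tail = FALSE)
    }
    p
  }
  set.seed(18)
  m <- matrix(rnorm(28), 7, 4)
  expect_equal(nemenyi_posthoc(m)$p_value, nemenyi_oracle(m),
               tolerance = 1e-10)
  # all-equal data: every pairwise p = 1
  m0 <- matrix(5, 6, 3)
  p0 <- nemenyi_posthoc(m0)$p_value
  expect_true(all(p0[upper.tri(p0)] == 1))
  # monotone treatment effect: extreme pair has the smallest p
  set.seed(19)
  m1 <- matrix(rnorm(40), 10, 4) + rep(c(0, 1, 2, 3), each = 10) * 0.8
  p1 <- nemenyi_posthoc(m1)$p_value
  expect_equal(which.min(p1[1, ]), 4L)
})

test_that("chi-square and Fisher match hand computation and base R", {
  # hand-computed 2x3 table
  m <- matrix(c(10, 20, 30, 20, 10, 30), nrow = 2, byrow = TRUE)
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  expect_equal(chi_square_test(m)$statistic, sum((m - e)^2 / e))
  expect_equal(chi_square_test(m)$statistic,
               unname(chisq.test(m, correct = FALSE)$statistic))
  # independence
  r0 <- chi_square_test(matrix(5, 2, 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # Fisher: perfect separation vs enumeration and base R
  sep <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(fisher_exact(sep)$p_value, 2 / choose(20, 10))
  expect_equal(fisher_exact(sep)$p_value, fisher.test(sep)$p.value)
  set.seed(20)
  for (i in 1:10) {
    tb <- matrix(rpois(4, 6) + 1, 2)
    expect_equal(fisher_exact(tb)$p_value, fisher.test(tb)$p.value,
                 tolerance = 1e-10)
  }
  expect_error(chi_square_test(matrix(c(0, 0, 1, 2), 2)), "zero-margin")
  expect_error(fisher_exact(matrix(1, 3, 2)), "2x2")
})
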