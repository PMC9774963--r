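test_that("delta notation matches the defining formula", {
  expect_equal(delta_value(0.011, 0.011), 0)
  expect_equal(delta_value(1.001 * 0.0112, 0.0112), 1.0, tolerance = 1e-9)
  expect_equal(delta_value(0.98 * 0.0112, 0.0112), -20.0, tolerance = 1e-9)
  expect_error(delta_value(1, 0), "positive")
})

test_that("trophic-level estimation is affine with the documented slope", {
  p <- trophic_params(baseline_d15n = 8.8)
  # baseline recovery: beak value 4.8 below the baseline maps to TL 2.0
  expect_equal(estimate_tl(8.8 - 4.8, p), 2.0)
  # slope 1/TEF: the baseline cancels in differences
  d <- runif(10, 5, 17)
  expect_equal(estimate_tl(d + 3.8, p) - estimate_tl(d, p), rep(1, 10))
  expect_equal(diff(estimate_tl(c(0, 4.90), p)), 4.90 / 3.8)
})

test_that("printed TL ranges equal printed d15N ranges / 3.8", {
  tab <- table1_fixture()
  # spot values: F2 and F3
  f2 <- tab[tab$squid == "F2", ]
  expect_equal(round(f2$range_min_max[f2$character == "d15n"] / 3.8, 2), 1.29)
  f3 <- tab[tab$squid == "F3", ]
  expect_equal(round(f3$range_min_max[f3$character == "d15n"] / 3.8, 2), 1.69)
  # every individual whose printed extremes are self-consistent
  ok <- table1_consistent_rows("d15n")
  expect_false("F1" %in% ok)       # the known typo row
  expect_length(ok, 13L)
  for (id in ok) {
    r15 <- tab$range_min_max[tab$squid == id & tab$character == "d15n"]
    rtl <- tab$range_min_max[tab$squid == id & tab$character == "tl"]
    expect_lt(abs(rtl - r15 / 3.8), 0.01 + 1e-12)
  }
})

test_that("trajectory summary matches a brute-force oracle", {
  pop <- simulate_population(trajectory_sim_params(missing_prob = 0.15),
                             seed = 9)
  p <- trophic_params(baseline_d15n = 8.8)
  for (tr in pop$trajectories[1:5]) {
    sm <- summarize_trajectory(tr, p)
    for (iso in c("d13c", "d15n")) {
      v <- tr$subsections[[iso]]; idx <- tr$subsections$index
      keep <- !is.na(v)
      if (sum(keep) < 2) { expect_false(sm[[iso]]$available); next }
      v2 <- v[keep]; i2 <- idx[keep]
      expect_equal(sm[[iso]]$min, min(v2))
      expect_equal(sm[[iso]]$max, max(v2))
      expect_equal(sm[[iso]]$argmin_subsection, i2[which.min(v2)])
      expect_equal(sm[[iso]]$mean, mean(v2))
      expect_equal(sm[[iso]]$se, sd(v2) / sqrt(length(v2)))
      expect_equal(sm[[iso]]$range_min_to_max, max(v2) - min(v2))
      expect_equal(sm[[iso]]$range_first_to_last,
                   abs(v2[length(v2)] - v2[1]))
      # min-to-max dominates newest-to-oldest
      expect_gte(sm[[iso]]$range_min_to_max + 1e-12,
                 sm[[iso]]$range_first_to_last)
    }
    # TL summary is the d15N summary mapped through the affine transform
    if (sm$d15n$available)
      expect_equal(sm$tl$range_min_to_max,
                   sm$d15n$range_min_to_max / 3.8)
  }
})

test_that("monotone trajectories have terminal extremes; interior maxima split the ranges", {
  mono <- beak_trajectory("m", data.frame(index = 1:6, d13c = 1:6 / 2,
                                          d15n = seq(9, 14)))
  s <- summarize_trajectory(mono)
  expect_equal(s$d15n$range_min_to_max, s$d15n$range_first_to_last)
  expect_equal(s$d15n$argmin_subsection, 1L)
  expect_equal(s$d15n$argmax_subsection, 6L)
  bump <- beak_trajectory("b", data.frame(index = 1:6,
                                          d13c = c(1, 2, 5, 4, 3, 2),
                                          d15n = c(9, 10, 14, 13, 12, 11)))
  sb <- summarize_trajectory(bump)
  expect_lt(sb$d15n$range_first_to_last, sb$d15n$range_min_to_max)
  expect_equal(sb$d15n$argmax_subsection, 3L)
})

test_that("specialization index obeys its limiting cases", {
  flat <- beak_trajectory("flat", data.frame(index = 1:4,
                                             d13c = rep(-20, 4),
                                             d15n = rep(10, 4)))
  spread <- beak_trajectory("spread", data.frame(index = 1:4,
                                                 d13c = c(-21, -20, -19, -18),
                                                 d15n = c(8, 10, 12, 14)))
  pop <- beak_population(list(flat, spread))
  r <- specialization_index(flat, pop, "d15n")
  expect_equal(r$s, 0)
  expect_equal(r$classification, "specialist")

  # engineered V_within == V_among -> s = 0.5 exactly
  a <- beak_trajectory("a", data.frame(index = 1:3, d13c = c(-20, -19, -18),
                                       d15n = c(9, 10, 11)))
  b <- beak_trajectory("b", data.frame(index = 1:3, d13c = c(-22, -21, -20),
                                       d15n = c(7, 8, 9)))
  pop2 <- beak_population(list(a, b))
  r2 <- specialization_index(a, pop2, "d15n")
  # V_within = var(9,10,11) = 1; means are 10 and 8 -> V_among = 2
  expect_equal(r2$v_within, 1)
  expect_equal(r2$v_among, 2)
  expect_equal(r2$s, 1 / 3)

  # identical means across individuals -> V_among = 0 -> s = 1
  c1 <- beak_trajectory("c1", data.frame(index = 1:3, d13c = c(-21, -20, -19),
                                         d15n = c(9, 10, 11)))
  c2 <- beak_trajectory("c2", data.frame(index = 1:3, d13c = c(-19, -20, -21),
                                         d15n = c(11, 10, 9)))
  pop3 <- beak_population(list(c1, c2))
  expect_equal(specialization_index(c1, pop3, "d15n")$s, 1)
  expect_error(specialization_index(flat,
                                    beak_population(list(flat, flat2 = {
                                      f <- flat; f$individual_id <- "f2"; f
                                    })), "d15n"),
               "zero total variance")
})

test_that("shifting one individual's values moves s only through V_among", {
  set.seed(21)
  pop <- simulate_population(trajectory_sim_params(n_individuals = 6),
                             seed = 21)
  tr <- pop$trajectories[[1]]
  base <- specialization_index(tr, pop, "d15n")
  shifted <- pop
  shifted$trajectories[[1]]$subsections$d15n <-
    shifted$trajectories[[1]]$subsections$d15n + 3
  after <- specialization_index(shifted$trajectories[[1]], shifted, "d15n")
  expect_equal(after$v_within, base$v_within)   # within-variance unchanged
  expect_gt(after$v_among, base$v_among)        # the shift inflates among
  expect_lt(after$s, base$s)
})

test_that("Spearman correlation matches base R and handles the poles", {
  expect_equal(spearman_rho(1:8, (1:8)^2)$rho, 1)
  expect_equal(spearman_rho(1:8, -(1:8))$rho, -1)
  expect_equal(spearman_rho(1:8, (1:8)^2)$p_value, 0)
  set.seed(6)
  x <- rnorm(6); y <- x + rnorm(6)
  mine <- spearman_rho(x, y)
  oracle <- cor.test(x, y, method = "spearman")
  expect_equal(mine$rho, unname(oracle$estimate))
  # pairwise deletion
  x2 <- c(x, NA); y2 <- c(y, 5)
  expect_equal(spearman_rho(x2, y2)$n, 6L)
  expect_error(spearman_rho(rep(1, 5), 1:5), "all-tied")
})
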