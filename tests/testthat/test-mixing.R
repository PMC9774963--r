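test_that("feasibility screening honours the mixing polygon", {
  lib <- arctic_source_library()
  tef <- tef_spec()
  # a consumer at a corrected source mean is a hull vertex: passes
  at_vertex <- data.frame(d13c = lib$mean_d13c[1] + tef$mean["d13c"],
                          d15n = lib$mean_d15n[1] + tef$mean["d15n"])
  expect_true(feasibility_check(at_vertex, lib, tef)$fitting)
  # far outside on d15N: fails
  outside <- data.frame(d13c = -20, d15n = max(lib$mean_d15n) + 10)
  expect_false(feasibility_check(outside, lib, tef)$fitting)
  # engineered screen: 23 inside, 8 outside -> "23 of 31"
  set.seed(40)
  centre <- unname(c(mean(lib$mean_d13c) + tef$mean["d13c"],
                     mean(lib$mean_d15n) + tef$mean["d15n"]))
  inside <- data.frame(d13c = centre[1] + rnorm(23, 0, 0.2),
                       d15n = centre[2] + rnorm(23, 0, 0.2))
  out <- data.frame(d13c = rep(centre[1], 8), d15n = centre[2] + 15)
  rep_ <- feasibility_check(rbind(inside, out), lib, tef)
  expect_equal(rep_$report, "23 of 31")
  # 2-source degenerate polygon falls back to a tolerant segment rule
  src2 <- two_sources()
  mid <- data.frame(
    d13c = sum(src2$mean_d13c) / 2 + tef$mean["d13c"] + 0.3,
    d15n = sum(src2$mean_d15n) / 2 + tef$mean["d15n"])
  expect_warning(fc <- feasibility_check(mid, src2, tef), "degenerate")
  expect_true(fc$fitting)
})

test_that("posterior draws live on the simplex and recover two-source truth", {
  src <- two_sources()
  truth <- mixture_truth(c(low = 0.7, high = 0.3), n_consumers = 30)
  cons <- simulate_consumers(truth, src, seed = 41)
  fit <- fit_mixing(cons, src, n_iter = 8000, burn_in = 2000, seed = 42)
  expect_true(all(abs(rowSums(fit$p_draws) - 1) < 1e-10))
  expect_true(all(fit$p_draws >= 0 & fit$p_draws <= 1))
  expect_lt(abs(fit$summary$mean[fit$summary$source == "low"] - 0.7),
            2 * fit$summary$sd[fit$summary$source == "low"] + 0.02)
  expect_gt(fit$acceptance, 0.1)
  expect_lt(fit$acceptance, 0.6)
})

test_that("symmetric problems and degenerate source sets behave as forced", {
  src <- two_sources()
  # consumer at the exact midpoint of the corrected sources
  tef <- tef_spec()
  mid <- data.frame(
    d13c = mean(src$mean_d13c) + tef$mean["d13c"],
    d15n = mean(src$mean_d15n) + tef$mean["d15n"])
  fit <- fit_mixing(mid, src, n_iter = 12000, burn_in = 3000, seed = 43)
  expect_lt(abs(fit$summary$mean[1] - 0.5), 0.1)
  # single source: p = 1 identically
  fit1 <- fit_mixing(mid, src[1, ], seed = 44)
  expect_true(all(fit1$p_draws == 1))
  # indistinguishable sources are refused by name
  twin <- rbind(src, source_spec("low2", -20.05, 0.5, 5.05, 0.5))
  expect_error(fit_mixing(mid, twin, seed = 45), "low2")
})

test_that("prior-only run returns symmetric Dirichlet marginals", {
  lib <- arctic_source_library()
  fit <- fit_mixing(NULL, lib, n_iter = 22000, burn_in = 2000, seed = 46)
  expect_true(all(abs(rowSums(fit$p_draws) - 1) < 1e-10))
  K <- nrow(lib)
  # Dirichlet(1,...,1): mean 1/K, sd sqrt((K-1)/(K^2 (K+1)))
  expect_equal(unname(colMeans(fit$p_draws)), rep(1 / K, K),
               tolerance = 0.02)
  expect_equal(unname(apply(fit$p_draws, 2, sd)),
               rep(sqrt((K - 1) / (K^2 * (K + 1))), K), tolerance = 0.1)
})

test_that("likelihood variance composition collapses correctly without TEF/residual noise", {
  # with sd_tef ~ 0 and residual ~ 0 the generative variance is sum p^2 s^2
  src <- two_sources()
  tef0 <- tef_spec(sd_d13c = 1e-9, sd_d15n = 1e-9)
  truth <- mixture_truth(c(low = 0.6, high = 0.4), n_consumers = 4000)
  cons <- simulate_consumers(truth, src, tef0, seed = 47)
  p <- c(0.6, 0.4)
  expect_equal(var(cons$d15n), sum(p^2 * src$sd_d15n^2), tolerance = 0.05)
  expect_equal(mean(cons$d15n),
               sum(p * (src$mean_d15n + tef0$mean["d15n"])),
               tolerance = 0.05)
})

test_that("source aggregation is draw-wise and conserving", {
  lib <- arctic_source_library()
  truth <- mixture_truth(setNames(c(.2, .2, .15, .05, .25, .15), lib$name),
                         n_consumers = 25)
  cons <- simulate_consumers(truth, lib, seed = 48)
  fit <- fit_mixing(cons, lib, n_iter = 6000, burn_in = 2000, seed = 49)
  groups <- c(copepods = "Crustacea", euphausiids = "Crustacea",
              shrimps = "Crustacea", chaetognaths = "Chaetognatha",
              cephalopods = "Cephalopoda+fish", fish = "Cephalopoda+fish")
  agg <- aggregate_sources(fit, groups)
  expect_true(all(abs(rowSums(agg$p_draws) - 1) < 1e-10))
  # supergroup mean = sum of member means
  expect_equal(agg$summary$mean[agg$summary$source == "Crustacea"],
               sum(fit$summary$mean[1:3]), tolerance = 1e-12)
  # supergroup SD matches brute-force draw-wise recomputation and is
  # bounded by the sum of member SDs
  brute <- sd(rowSums(fit$p_draws[, 1:3]))
  expect_equal(agg$summary$sd[agg$summary$source == "Crustacea"], brute)
  expect_lte(brute, sum(fit$summary$sd[1:3]) + 1e-12)
  # everything into one group -> p = 1 in every draw
  all1 <- aggregate_sources(fit, setNames(rep("all", 6), lib$name))
  expect_true(all(abs(all1$p_draws - 1) < 1e-10))
  expect_error(aggregate_sources(fit, groups[-1]), "unmapped")
})

test_that("diet-profile comparison dispatches and detects differences", {
  src <- two_sources()
  mkpost <- function(p1, n = 2000) {
    draws <- cbind(rep(p1, n), rep(1 - p1, n))
    colnames(draws) <- src$name
    structure(list(p_draws = draws, sources = src$name,
                   summary = data.frame(source = src$name,
                                        mean = c(p1, 1 - p1),
                                        sd = c(0, 0))),
              class = "diet_posterior")
  }
  same <- compare_diet_profiles(mkpost(0.5), mkpost(0.5))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  diff_ <- compare_diet_profiles(mkpost(0.9), mkpost(0.1))
  expect_lt(diff_$p_value, 0.001)
  fish <- compare_diet_profiles(mkpost(0.9), mkpost(0.1), method = "fisher")
  expect_equal(fish$statistic_name, "OR")
  expect_lt(fish$p_value, 0.001)
})

test_that("consumer simulation follows the generative law and is seeded", {
  src <- two_sources()
  truth <- mixture_truth(c(low = 1, high = 0), n_consumers = 2000)
  cons <- simulate_consumers(truth, src, seed = 50)
  tef <- tef_spec()
  expect_equal(mean(cons$d13c), unname(src$mean_d13c[1] + tef$mean["d13c"]),
               tolerance = 0.05)
  expect_equal(mean(cons$d15n), unname(src$mean_d15n[1] + tef$mean["d15n"]),
               tolerance = 0.08)
  expect_identical(simulate_consumers(truth, src, seed = 51),
                   simulate_consumers(truth, src, seed = 51))
  expect_error(mixture_truth(c(a = 0.5, b = 0.4)), "sum to 1")
})
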