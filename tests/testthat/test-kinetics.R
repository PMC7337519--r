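# The exponential leaving model: ECDFs, the MCMC posterior for k_leave,
# credible bands, the exponentiality check and condition comparisons.

test_that("empirical CDF is right-continuous with the expected values", {
  e <- empirical_cdf(c(1, 2, 4))
  expect_equal(e$values[e$grid == 2], 2 / 3)
  expect_equal(min(e$values), 1 / 3)
  expect_equal(e$values[length(e$values)], 1)
  expect_error(empirical_cdf(numeric(0)), "at least one")

  # Glivenko-Cantelli: sup-distance to the true exponential CDF shrinks
  # at roughly n^(-1/2)
  set.seed(5)
  for (n in c(400, 40000)) {
    x <- rexp(n, 0.7)
    e <- empirical_cdf(x)
    d <- max(abs(e$values - (1 - exp(-0.7 * e$grid))))
    expect_lt(d, 2 / sqrt(n))
  }
})

test_that("posterior for the leaving rate recovers simulated rates", {
  set.seed(41)
  x <- rexp(1000, 0.5)
  fit <- fit_leave_rate(x, chains = 2, warmup = 400, draws = 600, seed = 4)
  expect_true(fit$converged)
  expect_lt(abs(fit$mean - 0.5) / 0.5, 0.05)
  expect_lt(fit$ci[1], 0.5)
  expect_gt(fit$ci[2], 0.5)
  # maximum-likelihood limit: posterior mean near n / sum(t) at large n
  expect_lt(abs(fit$mean - length(x) / sum(x)) / fit$mean, 0.02)
})

test_that("MCMC matches deterministic grid integration of the posterior", {
  set.seed(42)
  x <- rexp(60, 1.2)
  fit <- fit_leave_rate(x, prior_a = 2, prior_b = 1,
                        chains = 4, warmup = 500, draws = 1000, seed = 5)
  oracle <- grid_posterior_moments(length(x), sum(x), a = 2, b = 1)
  mcse <- fit$sd / sqrt(fit$ess)
  expect_lt(abs(fit$mean - oracle$mean), 3 * mcse)
  expect_lt(abs(fit$sd / oracle$sd - 1), 0.1)
})

test_that("the fit depends on the data only through (n, sum t)", {
  set.seed(43)
  x <- rexp(100, 0.8)
  f1 <- fit_leave_rate(x, chains = 2, warmup = 200, draws = 200, seed = 7)
  f2 <- fit_leave_rate(sample(x), chains = 2, warmup = 200, draws = 200,
                       seed = 7)
  expect_identical(f1$samples, f2$samples)
  # and identical settings reproduce draws exactly
  f3 <- fit_leave_rate(x, chains = 2, warmup = 200, draws = 200, seed = 7)
  expect_identical(f1$samples, f3$samples)
})

test_that("single-dwell posteriors are wide and prior sensitivity fades", {
  fit1 <- fit_leave_rate(2, prior_a = 1.1, prior_b = 0.1,
                         chains = 2, warmup = 400, draws = 800, seed = 8)
  # with one 2-min dwell the rate is poorly determined but mostly below
  # ~2 per min
  expect_gt(mean(fit1$samples < 2), 0.85)
  expect_gt(fit1$ci[2] / fit1$ci[1], 5)

  set.seed(44)
  x <- rexp(500, 0.5)
  fa <- fit_leave_rate(x, prior_a = 2, prior_b = 1,
                       chains = 2, warmup = 300, draws = 500, seed = 9)
  fb <- fit_leave_rate(x, prior_a = 5, prior_b = 3,
                       chains = 2, warmup = 300, draws = 500, seed = 9)
  expect_lt(abs(fa$mean - fb$mean) / fa$mean, 0.05)

  expect_error(fit_leave_rate(c(1, -2)), "positive")
  expect_error(fit_leave_rate(numeric(0)), "at least one")
})

test_that("detection-threshold offset corrects left-truncated dwells", {
  # observable dwells are threshold + Exp(k); the offset likelihood
  # recovers k where the naive fit is biased low
  set.seed(145)
  k <- 0.45; thr <- 0.5
  x <- thr + rexp(800, k)
  naive <- fit_leave_rate(x, chains = 2, warmup = 300, draws = 500, seed = 10)
  corr <- fit_leave_rate(x, detection_min = thr,
                         chains = 2, warmup = 300, draws = 500, seed = 10)
  expect_lt(naive$ci[2], k)
  expect_lt(corr$ci[1], k)
  expect_gt(corr$ci[2], k)
  expect_error(fit_leave_rate(c(0.1, 1), detection_min = 0.5), "observed")
})

test_that("right-censored records lower the rate estimate when included", {
  set.seed(46)
  x <- rexp(200, 0.5)
  cens <- rep(c(FALSE, TRUE), c(170, 30))
  inc <- fit_leave_rate(x, censored = cens, chains = 2,
                        warmup = 300, draws = 400, seed = 11)
  exc <- fit_leave_rate(x[!cens], chains = 2,
                        warmup = 300, draws = 400, seed = 11)
  expect_lt(inc$mean, exc$mean)
  expect_equal(inc$n_obs, 170)
})

test_that("credible bands collapse with the posterior and cover the ECDF", {
  degenerate <- structure(list(samples = rep(2, 500)), class = "kinetic_fit")
  grid <- seq(0.1, 5, by = 0.1)
  band <- ecdf_credible_band(degenerate, grid)
  expect_equal(band$lower, 1 - exp(-2 * grid))
  expect_equal(band$upper, band$lower)
  expect_true(all(diff(band$lower) >= 0))
  expect_true(all(band$upper >= band$lower))
  expect_true(all(band$upper <= 1 & band$lower >= 0))

  # narrower posterior gives a narrower band
  wide <- structure(list(samples = exp(rnorm(4000, log(1), 0.2))),
                    class = "kinetic_fit")
  narrow <- structure(list(samples = exp(rnorm(4000, log(1), 0.02))),
                      class = "kinetic_fit")
  bw <- ecdf_credible_band(wide, grid)
  bn <- ecdf_credible_band(narrow, grid)
  expect_true(all(bn$upper - bn$lower <= bw$upper - bw$lower + 1e-12))

  # well-specified data: the ECDF sits inside the band at most grid points
  set.seed(47)
  x <- rexp(500, 0.6)
  fit <- fit_leave_rate(x, chains = 2, warmup = 300, draws = 600, seed = 12)
  e <- empirical_cdf(x)
  b <- ecdf_credible_band(fit, e$grid)
  inside <- mean(e$values >= b$lower - 0.05 & e$values <= b$upper + 0.05)
  expect_gt(inside, 0.9)
})

test_that("the exponentiality check separates exponential from mixtures", {
  set.seed(48)
  x <- rexp(300, 0.5)
  fit <- fit_leave_rate(x, chains = 2, warmup = 300, draws = 500, seed = 13)
  g <- gof_exponential(x, fit, n_pp = 400, seed = 13)
  expect_gt(g$p_value, 0.05)
  expect_false(g$low_power)

  # 50/50 hyperexponential (rates 0.2 and 5 per min) is flagged
  y <- simulate_dwell_sample(300, 0.2, 0,
                             contamination = list(fraction = 0.5, rate = 5),
                             seed = 14)$duration_min
  fit_y <- fit_leave_rate(y, chains = 2, warmup = 300, draws = 500, seed = 14)
  g_y <- gof_exponential(y, fit_y, n_pp = 400, seed = 14)
  expect_lt(g_y$p_value, 0.05)

  # dead-end contamination inflates the discrepancy as the fraction grows
  stats_at <- vapply(c(0, 0.1), function(fr) {
    mean(vapply(1:8, function(r) {
      z <- simulate_dwell_sample(300, 0.5, 0,
        contamination = if (fr > 0) list(fraction = fr, deadend_at = 60),
        seed = 100 * fr + r)$duration_min
      fz <- fit_leave_rate(z, chains = 2, warmup = 200, draws = 600,
                           seed = r)
      gof_exponential(z, fz, n_pp = 150, seed = r)$stat
    }, numeric(1)))
  }, numeric(1))
  expect_gt(stats_at[2], stats_at[1])

  # tiny samples are computed but flagged low power
  fit_s <- fit_leave_rate(c(1, 2, 3), chains = 2, warmup = 200,
                          draws = 200, seed = 15)
  expect_true(gof_exponential(c(1, 2, 3), fit_s, n_pp = 50,
                              seed = 15)$low_power)
})

test_that("condition comparison orders dwell distributions correctly", {
  x <- c(1, 2, 3, 4)
  same <- compare_conditions(x, x)
  expect_equal(same$ecdf_a, same$ecdf_b)
  expect_equal(same$fraction_a_ge_b, 1)

  set.seed(49)
  fast <- rexp(20000, 2)    # short-lived dwells
  slow <- rexp(20000, 0.5)
  cmp <- compare_conditions(fast, slow, labels = c("fast", "slow"))
  expect_gt(cmp$fraction_a_ge_b, 0.99)
  expect_lt(abs(cmp$median_b / cmp$median_a - 4), 0.3)
  expect_error(compare_conditions(numeric(0), 1:3), "non-empty")
})

test_that("derived cleavage rate propagates both posteriors", {
  set.seed(50)
  x <- rexp(400, 0.45)
  fit <- fit_leave_rate(x, chains = 2, warmup = 300, draws = 500, seed = 16)
  pc <- cut_posterior(200, 88)
  dr <- derive_cut_rate(fit, pc, seed = 16)
  expect_lt(abs(dr$k_cut$mean - fit$mean * pc$mean) / dr$k_cut$mean, 0.05)
  expect_lt(abs((dr$k_cut$mean + dr$k_unloop$mean) - fit$mean), 1e-9)
  expect_gt(dr$k_cut$sd, 0)
})
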