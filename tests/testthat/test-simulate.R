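test_that("the default configuration encodes the intended study conditions", {
  cfg <- default_sim_config()
  expect_equal(cfg$k, 12L)
  expect_equal(cfg$prevalence, 841 / 1761)  # ~0.4775
  expect_equal(cfg$n_range, c(58L, 390L))
  expect_equal(cfg$cutoff_range, c(14.96, 92.5))
  expect_equal(cfg$missing_cutoffs, 2L)
  # calibration anchor: accuracy at 30 ng/mL
  acc <- true_accuracy(cfg, cutoff = 30)
  expect_equal(acc$sensitivity, 0.861, tolerance = 1e-9)
  expect_equal(acc$specificity, 0.848, tolerance = 1e-9)
})

test_that("closed-form true accuracy behaves as a pair of normal CDFs", {
  cfg <- sim_config(mu_d = log(40) + 1, sigma_d = 1,
                    mu_nd = log(40) - 1, sigma_nd = 1)
  acc <- true_accuracy(cfg, cutoff = 40)
  expect_equal(acc$sensitivity, pnorm(1), tolerance = 1e-12)
  expect_equal(acc$specificity, pnorm(1), tolerance = 1e-12)
  # cutoff at the diseased median
  expect_equal(true_accuracy(cfg, cutoff = exp(cfg$mu_d))$sensitivity, 0.5)
  # identical distributions: sens + spec = 1 at every cutoff (J = 0)
  cfg0 <- sim_config(mu_d = log(30), mu_nd = log(30), sigma_d = 1.1, sigma_nd = 1.1)
  acc0 <- true_accuracy(cfg0, cutoff = c(5, 20, 30, 70, 200))
  expect_equal(acc0$sensitivity + acc0$specificity, rep(1, 5), tolerance = 1e-12)
})

test_that("truth curves are monotone in the cutoff", {
  cfg <- default_sim_config()
  acc <- true_accuracy(cfg, shift_d = 0.3, shift_nd = -0.2,
                       cutoff = seq(5, 150, length.out = 100))
  expect_true(all(diff(acc$sensitivity) <= 0))
  expect_true(all(diff(acc$specificity) >= 0))
})

test_that("simulation is reproducible and internally consistent", {
  cfg <- default_sim_config()
  s1 <- simulate_studies(cfg)
  s2 <- simulate_studies(cfg)
  expect_identical(as.data.frame(s1$data), as.data.frame(s2$data))
  expect_identical(s1$truth$cutoff, s2$truth$cutoff)
  d <- s1$data
  n_d <- d$tp + d$fn; n_nd <- d$fp + d$tn
  expect_true(all(n_d >= 5 & n_nd >= 5))
  n <- n_d + n_nd
  expect_true(all(n >= cfg$n_range[1] & n <= cfg$n_range[2]))
  expect_equal(sum(is.na(d$cutoff)), 2)
  expect_true(all(s1$truth$cutoff >= cfg$cutoff_range[1] &
                    s1$truth$cutoff <= cfg$cutoff_range[2]))
  # a different seed gives different data
  s3 <- simulate_studies(sim_config(seed = 2, missing_cutoffs = 2L))
  expect_false(identical(s1$data$tp, s3$data$tp))
})

test_that("no heterogeneity and a fixed cutoff give one shared truth", {
  cfg <- sim_config(tau_d = 0, tau_nd = 0, cutoff_law = "fixed-list",
                    cutoffs = 30, seed = 7)
  s <- simulate_studies(cfg)
  expect_equal(length(unique(round(s$truth$sensitivity, 12))), 1)
  expect_equal(length(unique(round(s$truth$specificity, 12))), 1)
  expect_equal(unique(s$truth$cutoff), 30)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(prevalence = 1.2), "invalid", class = "dta_config_error")
  expect_error(sim_config(sigma_d = 0), "invalid", class = "dta_config_error")
  expect_error(sim_config(shift_correlation = 1.5), "invalid", class = "dta_config_error")
  expect_error(sim_config(cutoff_law = "fixed-list"), "fixed-list",
               class = "dta_config_error")
})

test_that("direct bivariate simulation respects margins and its seed", {
  Sigma <- matrix(c(0.49, -0.3, -0.3, 0.81), 2, 2)
  d1 <- simulate_bivariate_studies(12, c(1.5, -1.8), Sigma, seed = 11)
  d2 <- simulate_bivariate_studies(12, c(1.5, -1.8), Sigma, seed = 11)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_true(all(d1$tp + d1$fn >= 5 & d1$fp + d1$tn >= 5))
})

test_that("simulation configs round-trip through YAML and JSON", {
  cfg <- sim_config(seed = 9, tau_d = 0.3)
  fy <- tempfile(fileext = ".yaml"); fj <- tempfile(fileext = ".json")
  write_sim_config(cfg, fy); write_sim_config(cfg, fj)
  expect_equal(read_sim_config(fy), cfg, tolerance = 1e-6)  # YAML float precision
  expect_equal(read_sim_config(fj), cfg, tolerance = 1e-12)
})
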