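test_that("REML fit agrees with an independent mixed-model implementation", {
  skip_if_not_installed("metafor")
  sim <- simulate_studies(default_sim_config())
  tr <- logit_transform(sim$data)
  dat <- data.frame(study = rep(tr$study_id, each = 2),
                    outcome = factor(rep(c("sens", "fpr"), nrow(tr)),
                                     levels = c("sens", "fpr")),
                    yi = as.vector(rbind(tr$y1, tr$y2)),
                    vi = as.vector(rbind(tr$v1, tr$v2)))
  m <- metafor::rma.mv(yi, vi, mods = ~ outcome - 1, random = ~ outcome | study,
                       struct = "UN", data = dat, method = "REML")
  fit <- dta_bivariate(sim$data)
  expect_equal(unname(fit$mu), unname(coef(m)), tolerance = 1e-4)
  expect_equal(unname(fit$tau^2), unname(m$tau2), tolerance = 1e-3)
  expect_equal(fit$rho, m$rho, tolerance = 1e-3)
})

test_that("profiled restricted log-likelihood matches metafor at fixed variances", {
  skip_if_not_installed("metafor")
  d <- toy_data()
  tr <- logit_transform(d)
  dat <- data.frame(study = rep(tr$study_id, each = 2),
                    outcome = factor(rep(c("sens", "fpr"), nrow(tr)),
                                     levels = c("sens", "fpr")),
                    yi = as.vector(rbind(tr$y1, tr$y2)),
                    vi = as.vector(rbind(tr$v1, tr$v2)))
  pts <- list(c(0.4, 0.6, 0.2), c(0.9, 1.1, -0.6), c(0.2, 1.4, 0.8))
  mine <- vapply(pts, function(p) profile_loglik(d, p[1], p[2], p[3]), numeric(1))
  ref <- vapply(pts, function(p) {
    m <- metafor::rma.mv(yi, vi, mods = ~ outcome - 1, random = ~ outcome | study,
                         struct = "UN", data = dat, method = "REML",
                         tau2 = c(p[1]^2, p[2]^2), rho = p[3])
    as.numeric(logLik(m))
  }, numeric(1))
  # implementations may differ by a data-independent constant
  expect_equal(diff(mine), diff(ref), tolerance = 1e-6)
  # and against the naive in-test evaluator, with its constants, exactly
  naive <- vapply(pts, function(p) oracle_reml_loglik_naive(tr, p[1], p[2], p[3]),
                  numeric(1))
  expect_equal(mine, naive, tolerance = 1e-9)
})

test_that("identical studies collapse to zero between-study variance", {
  d <- identical_data(k = 5, tp = 80, fp = 12, fn = 20, tn = 88)
  fit <- suppressWarnings(dta_bivariate(d))
  expect_lt(fit$tau[1], 1e-3)
  expect_lt(fit$tau[2], 1e-3)
  expect_equal(unname(fit$mu[1]), logit(80 / 100), tolerance = 1e-6)
  expect_equal(unname(fit$mu[2]), logit(12 / 100), tolerance = 1e-6)
  expect_warning(threshold_correlation(fit), "undefined")
})

test_that("with zero between-study variance the fit is the closed-form GLS", {
  d <- toy_data()
  tr <- logit_transform(d)
  res <- dtathresh:::profile_fit(tr, 0, 0, 0)
  expect_equal(res$beta[1], sum(tr$y1 / tr$v1) / sum(1 / tr$v1), tolerance = 1e-12)
  expect_equal(res$beta[2], sum(tr$y2 / tr$v2) / sum(1 / tr$v2), tolerance = 1e-12)
})

test_that("the REML optimum dominates 100 random feasible points", {
  sim <- simulate_studies(sim_config(seed = 3))
  fit <- dta_bivariate(sim$data)
  set.seed(99)
  lls <- replicate(100, {
    profile_loglik(sim$data, runif(1, 0.01, 2), runif(1, 0.01, 2),
                   runif(1, -0.98, 0.98))
  })
  expect_true(all(fit$loglik >= lls - 1e-8))
})

test_that("likelihood ratios follow their defining algebra", {
  expect_equal(unlist(lr_from_sens_spec(0.5, 0.5)), c(lr_pos = 1, lr_neg = 1, dor = 1))
  r <- lr_from_sens_spec(0.9, 0.85)
  expect_equal(r$lr_pos, 6, tolerance = 1e-12)
  expect_equal(r$lr_neg, 0.1 / 0.85, tolerance = 1e-12)
  expect_equal(r$dor, 51, tolerance = 1e-12)
  # dor equals the cross-product ratio of the matching 2x2
  expect_equal(r$dor, (90 * 85) / (10 * 15), tolerance = 1e-12)
  expect_error(lr_from_sens_spec(1, 0.5), "continuity", class = "dta_domain_error")
})

test_that("a chance-line fit yields 0.5/0.5 accuracy and unit ratios", {
  d <- identical_data(k = 3, tp = 50, fp = 50, fn = 50, tn = 50)
  fit <- suppressWarnings(dta_bivariate(d))
  s <- pooled_summary(fit, mc_draws = 5000, seed = 1)
  expect_equal(s$sensitivity, 0.5, tolerance = 1e-6)
  expect_equal(s$specificity, 0.5, tolerance = 1e-6)
  expect_equal(s$lr_pos, 1, tolerance = 1e-5)
  expect_equal(s$dor, 1, tolerance = 1e-5)
})

test_that("DOR identity holds exactly on every pooled summary", {
  for (seed in 1:5) {
    sim <- simulate_studies(sim_config(seed = seed))
    s <- pooled_summary(dta_bivariate(sim$data, starts = 5), mc_draws = 1000, seed = 1)
    expect_equal(s$dor, s$lr_pos / s$lr_neg, tolerance = 1e-9)
    expect_true(s$i2_sens >= 0 && s$i2_sens <= 100)
    expect_true((s$lr_pos > 1) == (s$sensitivity > 1 - s$specificity))
  }
})

test_that("Monte-Carlo CI endpoints are stable across seeds at 1e5 draws", {
  sim <- simulate_studies(default_sim_config())
  fit <- dta_bivariate(sim$data)
  s1 <- pooled_summary(fit, mc_draws = 1e5, seed = 1)
  s2 <- pooled_summary(fit, mc_draws = 1e5, seed = 2)
  rel <- function(a, b) abs(a - b) / abs(a)
  expect_lt(max(rel(s1$lr_pos_ci, s2$lr_pos_ci)), 0.005)
  expect_lt(max(rel(s1$lr_neg_ci, s2$lr_neg_ci)), 0.005)
  expect_lt(max(rel(s1$dor_ci, s2$dor_ci)), 0.005)
  # same seed reproduces identical intervals
  s3 <- pooled_summary(fit, mc_draws = 1e5, seed = 1)
  expect_identical(s1$lr_pos_ci, s3$lr_pos_ci)
})

test_that("Cochran's Q and I-squared match hand computation", {
  d <- identical_data(k = 3)
  expect_equal(unname(cochran_q_i2(d, "sensitivity")[c("Q", "I2")]), c(0, 0))
  toy <- data.frame(y1 = c(0, 0, 3), v1 = c(1, 1, 1),
                    y2 = c(0, 0, 3), v2 = c(1, 1, 1))
  q <- cochran_q_i2(toy, "sensitivity")
  expect_equal(unname(q["Q"]), 6)                       # yhat = 1
  expect_equal(unname(q["I2"]), 100 * 4 / 6, tolerance = 1e-12)  # 66.7%
})

test_that("threshold correlation reports both sign conventions", {
  sim <- simulate_studies(default_sim_config())
  fit <- dta_bivariate(sim$data)
  rho <- threshold_correlation(fit)
  expect_equal(as.numeric(rho), fit$rho)
  expect_equal(attr(rho, "sens_spec"), -fit$rho)
  expect_lte(abs(as.numeric(rho)), 1)
})

test_that("cutoff variation induces a strong between-study correlation", {
  # threshold effect emerges mechanically from per-study cutoffs
  hits <- 0
  for (seed in 1:40) {
    sim <- simulate_studies(sim_config(seed = seed))
    fit <- dta_bivariate(sim$data, starts = 4)
    if (is.finite(fit$rho) && abs(fit$rho) > 0.5 && !fit$at_boundary) hits <- hits + 1
  }
  expect_gte(hits, 36)  # >= 90% of replicates
})

test_that("degenerate inputs are refused with the documented errors", {
  d1 <- identical_data(k = 1)
  expect_error(dta_bivariate(d1), "at least 2", class = "dta_insufficient_data")
  d2 <- identical_data(k = 2)
  expect_warning(dta_bivariate(d2), "2 studies")
  sim <- simulate_studies(default_sim_config())
  expect_error(pooled_summary(dta_bivariate(sim$data, covariate = "cutoff_group")),
               "not found")
})
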