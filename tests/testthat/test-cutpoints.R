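# Fit whose coefficients are set directly, for geometry checks with known truth.
synthetic_cutpoint_fit <- function(a_d, b_d, a_nd, b_nd, transform = "log",
                                   c_range = c(10, 100)) {
  fit <- list(
    transform = transform,
    coef_diseased = c(a_d, b_d), coef_nondiseased = c(a_nd, b_nd),
    aic = NA_real_, all_aics = NULL, tie = FALSE,
    included_studies = character(0), c_range = c_range,
    weights = "size", eval_range = c(0.5 * c_range[1], 1.2 * c_range[2])
  )
  class(fit) <- "dta_cutpoints"
  fit
}

test_that("noise-free data on the model lines are interpolated", {
  d <- exact_line_data()
  fit <- dta_cutpoints(d, transform = "log")
  # recovery limited only by integer-count granularity at n = 1e8
  expect_equal(unname(fit$coef_diseased), c(-6.6, 1.4), tolerance = 1e-6)
  expect_equal(unname(fit$coef_nondiseased), c(-3.0, 1.4), tolerance = 1e-6)
})

test_that("with equal weights the WLS fit equals closed-form OLS", {
  d <- toy_data()
  fit <- dta_cutpoints(d, transform = "log", weights = "equal")
  tr <- logit_transform(d)
  x <- log(d$cutoff)
  y <- logit(1 - tr$sens)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  expect_equal(unname(fit$coef_diseased), c(a, b), tolerance = 1e-12)
})

test_that("transform selection reports all candidates and breaks ties to log", {
  sim <- simulate_studies(default_sim_config())
  fit <- dta_cutpoints(sim$data)
  expect_named(fit$all_aics, c("identity", "log", "sqrt"))
  expect_true(all(is.finite(fit$all_aics)))
  expect_equal(fit$aic, min(fit$all_aics))
  # identical counts across studies: zero slopes, identical fit under every
  # transform, hence an exact AIC tie resolved toward log
  d <- as_dta_data(data.frame(study_id = paste0("s", 1:4), tp = 80, fp = 12,
                              fn = 20, tn = 88, cutoff = c(20, 30, 50, 80)))
  tie_fit <- dta_cutpoints(d)
  expect_equal(tie_fit$transform, "log")
  expect_true(tie_fit$tie)
  expect_true(all(tie_fit$all_aics == tie_fit$all_aics[[1]]))
  # forcing a transform bypasses selection
  expect_equal(dta_cutpoints(sim$data, transform = "sqrt")$transform, "sqrt")
})

test_that("cutoff-model preconditions are enforced", {
  d <- toy_data()
  d2 <- as_dta_data(as.data.frame(d)[1:2, ])
  expect_error(dta_cutpoints(d2), "3 studies", class = "dta_insufficient_data")
  d3 <- as_dta_data(data.frame(study_id = c("a", "b", "c"), tp = c(10, 11, 12),
                               fp = c(3, 4, 5), fn = c(5, 5, 5), tn = c(20, 21, 22),
                               cutoff = c(30, 30, 30)))
  expect_error(dta_cutpoints(d3), "unidentifiable", class = "dta_unidentifiable")
})

test_that("predicted accuracy is monotone and flags extrapolation", {
  fit <- synthetic_cutpoint_fit(-6.6, 1.4, -3.0, 1.4)
  cc <- seq(6, 115, length.out = 50)
  p <- predict(fit, cc, warn_extrapolation = FALSE)
  expect_true(all(diff(p$sensitivity) <= 0))
  expect_true(all(diff(p$specificity) >= 0))
  expect_true(p$extrapolated[1] && p$extrapolated[50] && !p$extrapolated[25])
  expect_warning(predict(fit, 5), "extrapolation")
  # where both lines cross zero the accuracy is 0.5
  p50 <- predict(fit, exp(6.6 / 1.4), warn_extrapolation = FALSE)
  expect_equal(p50$sensitivity, 0.5, tolerance = 1e-12)
  p50b <- predict(fit, exp(3.0 / 1.4), warn_extrapolation = FALSE)
  expect_equal(p50b$specificity, 0.5, tolerance = 1e-12)
})

test_that("the Youden optimum of mirrored lines sits at the symmetry point", {
  # lines mirror images on the f scale: optimum at u* = -(a_d + a_nd)/(2b)
  a_d <- -6.6; a_nd <- -3.0; b <- 1.4
  fit <- synthetic_cutpoint_fit(a_d, b, a_nd, b)
  yo <- youden_cutoff(fit)
  expect_equal(yo$cutoff, exp(-(a_d + a_nd) / (2 * b)), tolerance = 1e-6)
  expect_equal(yo$youden, yo$sensitivity + yo$specificity - 1, tolerance = 1e-12)
  # predict_accuracy at the optimum reproduces the stored values exactly
  p <- predict(fit, yo$cutoff, warn_extrapolation = FALSE)
  expect_equal(p$sensitivity, yo$sensitivity)
  expect_equal(p$specificity, yo$specificity)
})

test_that("a useless test yields the no-optimum signal", {
  # diseased and non-diseased lines identical: J = 0 everywhere
  fit <- synthetic_cutpoint_fit(-3.0, 1.4, -3.0, 1.4)
  yo <- youden_cutoff(fit)
  expect_true(is.na(yo$cutoff))
  expect_match(yo$note, "J <= 0")
})

test_that("LR curves satisfy the DOR identity and chance-point behavior", {
  fit <- synthetic_cutpoint_fit(-6.6, 1.4, -3.0, 1.4)
  cv <- lr_curves(fit)
  dor <- cv$lr_pos / cv$lr_neg
  lr <- lr_from_sens_spec(cv$sensitivity, cv$specificity)
  expect_equal(dor, lr$dor, tolerance = 1e-9)
  # at the non-diseased 50% point, spec = 0.5 so LR- = 2(1 - sens)
  at <- predict(fit, exp(3.0 / 1.4), warn_extrapolation = FALSE)
  expect_equal((1 - at$sensitivity) / at$specificity, 2 * (1 - at$sensitivity),
               tolerance = 1e-9)
})

test_that("rule-in and rule-out thresholds are located and ordered", {
  fit <- synthetic_cutpoint_fit(-6.6, 1.4, -3.0, 1.4)
  th <- lr_thresholds(fit)
  expect_false(is.na(th$rule_in_cutoff))
  expect_false(is.na(th$rule_out_cutoff))
  expect_lt(th$rule_out_cutoff, th$rule_in_cutoff)
  # the crossing reproduces the target on the fitted curve
  p_in <- predict(fit, th$rule_in_cutoff, warn_extrapolation = FALSE)
  expect_equal(p_in$sensitivity / (1 - p_in$specificity), 10, tolerance = 1e-6)
  p_out <- predict(fit, th$rule_out_cutoff, warn_extrapolation = FALSE)
  expect_equal((1 - p_out$sensitivity) / p_out$specificity, 0.1, tolerance = 1e-6)
  expect_error(lr_thresholds(fit, lr_pos_target = 0.5), "targets",
               class = "dta_config_error")
})

test_that("threshold absence is reported as a value, not extrapolated", {
  # nearly flat, highly accurate test: LR+ above 2 everywhere on the grid
  fit <- synthetic_cutpoint_fit(-4, 0.01, 2, 0.01, c_range = c(20, 80))
  th <- lr_thresholds(fit, lr_pos_target = 2, lr_neg_target = 0.001)
  expect_equal(th$rule_in_cutoff, fit$eval_range[1])  # met everywhere: lower edge
  expect_match(th$note_rule_in, "whole grid")
  expect_true(is.na(th$rule_out_cutoff))
  expect_match(th$note_rule_out, "not achieved")
})

test_that("the cluster bootstrap is seeded and degenerates on exact data", {
  d <- exact_line_data()
  fit <- dta_cutpoints(d, transform = "log")
  b1 <- bootstrap_cutoff_ci(d, fit, B = 60, seed = 5)
  b2 <- bootstrap_cutoff_ci(d, fit, B = 60, seed = 5)
  expect_identical(b1$boot_cutoffs, b2$boot_cutoffs)
  # zero-noise data: every successful refit returns the same optimum
  expect_lt(diff(b1$ci), 1e-4)
  expect_false(b1$unstable)
})

test_that("the full threshold report is internally consistent", {
  sim <- simulate_studies(default_sim_config())
  fit <- dta_cutpoints(sim$data)
  rep <- threshold_report(fit, sim$data, B = 50, seed = 3)
  expect_equal(rep$transform, fit$transform)
  if (!is.na(rep$youden_cutoff)) {
    p <- predict(fit, rep$youden_cutoff, warn_extrapolation = FALSE)
    expect_equal(p$sensitivity, rep$sens_at_opt)
    expect_equal(p$specificity, rep$spec_at_opt)
  }
  if (!is.na(rep$rule_in_cutoff) && !is.na(rep$rule_out_cutoff)) {
    expect_true(rep$thresholds_ordered)
  }
  expect_equal(rep$bootstrap$B, 50L)
})
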