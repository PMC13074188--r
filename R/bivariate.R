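## Bivariate logit-normal random-effects model for diagnostic test accuracy.
##
## Per study i the empirical logits Y_i = (logit sens_i, logit FPR_i)' are
## modelled as Y_i ~ N(X_i beta, Sigma + C_i) with C_i = diag(v1_i, v2_i) the
## delta-method within-study covariance (the two arms are independent) and
## Sigma the 2x2 between-study covariance. Fixed effects are profiled out by
## generalized least squares at each candidate Sigma; Sigma is estimated by
## restricted maximum likelihood over the unconstrained parameterization
## (log tau1, log tau2, atanh rho).

## Build 2 x (2p) design rows for study i given a per-study model-matrix row
## x_i (p-vector): row 1 = (x_i', 0'), row 2 = (0', x_i'). beta stacks the
## sensitivity block before the FPR block.
make_designs <- function(k, xmat = NULL) {
  if (is.null(xmat)) xmat <- matrix(1, k, 1)
  p0 <- ncol(xmat)
  lapply(seq_len(k), function(i) {
    X <- matrix(0, 2, 2 * p0)
    X[1, seq_len(p0)] <- xmat[i, ]
    X[2, p0 + seq_len(p0)] <- xmat[i, ]
    X
  })
}

## Profiled (restricted) log-likelihood at fixed variance components.
## Returns the log-likelihood with all constants included, plus the GLS
## solution. Intercept-only fits use a fully vectorized 2x2 path.
profile_fit <- function(trans, tau1, tau2, rho, designs = NULL, reml = TRUE) {
  y1 <- trans$y1; y2 <- trans$y2; v1 <- trans$v1; v2 <- trans$v2
  k <- length(y1)
  s11 <- tau1^2; s22 <- tau2^2; s12 <- rho * tau1 * tau2
  a <- s11 + v1; d <- s22 + v2; b <- s12
  det_i <- a * d - b^2
  if (any(det_i <= 0)) return(list(ll = -Inf))
  w11 <- d / det_i; w22 <- a / det_i; w12 <- -b / det_i
  if (is.null(designs)) {
    A11 <- sum(w11); A22 <- sum(w22); A12 <- sum(w12)
    b1 <- sum(w11 * y1 + w12 * y2); b2 <- sum(w12 * y1 + w22 * y2)
    detA <- A11 * A22 - A12^2
    if (detA <= 0) return(list(ll = -Inf))
    beta <- c(A22 * b1 - A12 * b2, A11 * b2 - A12 * b1) / detA
    r1 <- y1 - beta[1]; r2 <- y2 - beta[2]
    quad <- sum(w11 * r1^2 + 2 * w12 * r1 * r2 + w22 * r2^2)
    p <- 2
    logdetA <- log(detA)
    Ainv <- matrix(c(A22, -A12, -A12, A11), 2, 2) / detA
  } else {
    p <- ncol(designs[[1]])
    A <- matrix(0, p, p); bv <- numeric(p)
    for (i in seq_len(k)) {
      Wi <- matrix(c(w11[i], w12[i], w12[i], w22[i]), 2, 2)
      Xi <- designs[[i]]
      XtW <- crossprod(Xi, Wi)
      A <- A + XtW %*% Xi
      bv <- bv + XtW %*% c(y1[i], y2[i])
    }
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) return(list(ll = -Inf))
    beta <- drop(backsolve(ch, forwardsolve(t(ch), bv)))
    quad <- 0
    for (i in seq_len(k)) {
      ri <- c(y1[i], y2[i]) - drop(designs[[i]] %*% beta)
      quad <- quad + w11[i] * ri[1]^2 + 2 * w12[i] * ri[1] * ri[2] + w22[i] * ri[2]^2
    }
    logdetA <- 2 * sum(log(diag(ch)))
    Ainv <- chol2inv(ch)
  }
  n_obs <- 2 * k
  ll <- if (reml) {
    -0.5 * ((n_obs - p) * log(2 * pi) + sum(log(det_i)) + logdetA + quad)
  } else {
    -0.5 * (n_obs * log(2 * pi) + sum(log(det_i)) + quad)
  }
  list(ll = ll, beta = beta, vcov = Ainv, p = p)
}

#' Profiled log-likelihood of the bivariate model at fixed variance components
#'
#' Evaluates the restricted (or ordinary) log-likelihood of the bivariate
#' logit-normal model with the fixed effects profiled out by GLS, at
#' user-chosen between-study standard deviations and correlation. Useful for
#' likelihood-surface audits.
#'
#' @param x a `dta_data` object (or the output of [logit_transform()]).
#' @param tau1,tau2 between-study sds of logit sensitivity and logit FPR.
#' @param rho between-study correlation in [-1, 1].
#' @param method `"reml"` (default) or `"ml"`.
#' @return The log-likelihood (scalar), `-Inf` if the covariance is not
#'   positive definite.
#' @export
profile_loglik <- function(x, tau1, tau2, rho, method = c("reml", "ml")) {
  method <- match.arg(method)
  trans <- if (inherits(x, "dta_data")) logit_transform(x) else x
  profile_fit(trans, tau1, tau2, rho, reml = (method == "reml"))$ll
}

## Deterministic + seeded-random starting values on the unconstrained scale
## (log tau1, log tau2, atanh rho).
start_values <- function(n_random, seed) {
  det <- rbind(
    c(log(0.1), log(0.1), 0),
    c(log(0.5), log(0.5), 0),
    c(log(1.0), log(1.0), 0),
    c(log(0.5), log(0.5), atanh(0.7)),
    c(log(0.5), log(0.5), atanh(-0.7))
  )
  if (n_random > 0) {
    state <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    rnd <- cbind(stats::runif(n_random, log(0.05), log(2)),
                 stats::runif(n_random, log(0.05), log(2)),
                 stats::runif(n_random, -1.5, 1.5))
    if (!is.null(state)) assign(".Random.seed", state, .GlobalEnv) else
      rm(".Random.seed", envir = .GlobalEnv)
    det <- rbind(det, rnd)
  }
  det
}

#' Fit the bivariate random-effects model for diagnostic accuracy
#'
#' Estimates mean logit sensitivity and mean logit false-positive rate together
#' with the between-study covariance by restricted maximum likelihood (REML;
#' `method = "ml"` gives ordinary ML, used for likelihood-ratio tests of
#' covariates). Optimization runs over `(log tau1, log tau2, atanh rho)` from
#' five deterministic plus `starts - 5` seeded random starting points, keeping
#' the best converged optimum.
#'
#' @param data a `dta_data` object (see [as_dta_data()], [read_studies()]).
#' @param covariate optional name of a categorical column of `data`; when
#'   given, the covariate enters both the logit-sensitivity and logit-FPR means
#'   (missing levels become `"unreported"`).
#' @param method `"reml"` (default) or `"ml"`.
#' @param correction,correction_mode continuity-correction settings, see
#'   [correct_counts()].
#' @param starts total number of starting points (>= 1; default 10).
#' @param start_seed seed for the random starting points (kept separate from
#'   the global RNG state).
#' @return An object of class `dta_bivariate` with components `mu` (fixed
#'   effects: logit sensitivity, logit FPR), `Sigma` (between-study
#'   covariance), `rho`, `beta`, `vcov` (fixed-effect covariance), `loglik`,
#'   `method`, `k`, `converged`, `trace`, `trans` (transformed studies) and the
#'   input `data`. Methods: `print`, `summary`, `coef`, `vcov`, `logLik`,
#'   `plot` (SROC), `residuals`, `simulate`.
#' @examples
#' sim <- simulate_studies(default_sim_config())
#' fit <- dta_bivariate(sim$data)
#' fit
#' @export
dta_bivariate <- function(data, covariate = NULL, method = c("reml", "ml"),
                          correction = 0.5,
                          correction_mode = "any-zero-all-cells",
                          starts = 10, start_seed = 42L) {
  method <- match.arg(method)
  stopifnot(inherits(data, "dta_data"))
  k <- nrow(data)
  if (k < 2) stop_dta("at least 2 studies are required for a pooled fit", "dta_insufficient_data")
  if (k == 2) warning("only 2 studies: between-study variance is barely identified")
  trans <- logit_transform(data, value = correction, mode = correction_mode)

  designs <- NULL
  xlev <- NULL
  if (!is.null(covariate)) {
    if (!covariate %in% names(data)) {
      stop_dta(sprintf("covariate '%s' not found in data", covariate), "dta_schema_error")
    }
    f <- as.character(data[[covariate]])
    f[is.na(f) | f == ""] <- "unreported"
    f <- factor(f)
    xlev <- levels(f)
    if (nlevels(f) < 2) {
      ## constant covariate: collapses to the intercept-only model
      designs <- NULL
    } else {
      xmat <- stats::model.matrix(~f)
      if (qr(xmat)$rank < ncol(xmat)) {
        stop_dta(sprintf("singular design for covariate '%s' (level separation)", covariate),
                 "dta_design_error")
      }
      designs <- make_designs(k, xmat)
    }
  }

  reml <- method == "reml"
  obj <- function(par) {
    res <- profile_fit(trans, exp(par[1]), exp(par[2]), tanh(par[3]),
                       designs = designs, reml = reml)
    if (!is.finite(res$ll)) 1e10 else -res$ll
  }
  sv <- start_values(max(0, starts - 5), start_seed)
  if (starts < 5) sv <- sv[seq_len(max(1, starts)), , drop = FALSE]
  runs <- apply(sv, 1, function(s) {
    stats::optim(s, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
  })
  vals <- vapply(runs, function(r) r$value, numeric(1))
  best <- runs[[which.min(vals)]]
  ## polish once from the best point
  best2 <- stats::optim(best$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-13))
  if (best2$value <= best$value) best <- best2
  if (min(vals) >= 1e10) {
    stop_dta("bivariate fit failed to converge from all starting points", "dta_fit_error")
  }
  par <- best$par
  tau1 <- exp(par[1]); tau2 <- exp(par[2]); rho <- tanh(par[3])
  at_boundary <- tau1 < 1e-4 || tau2 < 1e-4
  final <- profile_fit(trans, tau1, tau2, rho, designs = designs, reml = reml)
  Sigma <- matrix(c(tau1^2, rho * tau1 * tau2, rho * tau1 * tau2, tau2^2), 2, 2)
  p0 <- final$p / 2
  mu <- c(final$beta[1], final$beta[p0 + 1])
  names(mu) <- c("logit_sens", "logit_fpr")
  structure(
    list(
      mu = mu, Sigma = Sigma, tau = c(tau1 = tau1, tau2 = tau2), rho = rho,
      beta = final$beta, vcov = final$vcov, loglik = final$ll,
      method = method, k = k, n_params = final$p + 3,
      converged = best$convergence == 0 || at_boundary,
      at_boundary = at_boundary,
      covariate = covariate, covariate_levels = xlev,
      trace = data.frame(start = seq_len(nrow(sv)), objective = -vals),
      trans = trans, data = data, call = match.call()
    ),
    class = "dta_bivariate"
  )
}

#' Likelihood ratios and diagnostic odds ratio from accuracy
#'
#' `lr_pos = sens/(1-spec)`, `lr_neg = (1-sens)/spec`, `dor = lr_pos/lr_neg`.
#' Vectorized; proportions must lie strictly inside (0, 1) (apply a continuity
#' correction upstream for boundary proportions).
#'
#' @param sens,spec sensitivity and specificity in (0, 1).
#' @return Data frame with columns `lr_pos`, `lr_neg`, `dor`.
#' @examples
#' lr_from_sens_spec(0.9, 0.85)  # LR+ 6, LR- 0.1176, DOR 51
#' @export
lr_from_sens_spec <- function(sens, spec) {
  if (any(sens <= 0 | sens >= 1 | spec <= 0 | spec >= 1)) {
    stop_dta("sens and spec must be strictly inside (0,1); use a continuity correction upstream",
             "dta_domain_error")
  }
  lr_pos <- sens / (1 - spec)
  lr_neg <- (1 - sens) / spec
  data.frame(lr_pos = lr_pos, lr_neg = lr_neg, dor = lr_pos / lr_neg)
}

#' Between-study (threshold-effect) correlation
#'
#' Returns the fitted between-study correlation between logit sensitivity and
#' logit false-positive rate; a magnitude near 1 flags a threshold effect. The
#' correlation against logit *specificity* is the negative of this value and is
#' attached as attribute `"sens_spec"`. When either between-study variance is
#' estimated at (numerically) zero the correlation is undefined and `NA` is
#' returned with a warning.
#'
#' @param fit a [dta_bivariate()] fit.
#' @return Scalar correlation (possibly `NA`), with attribute `sens_spec`.
#' @export
threshold_correlation <- function(fit) {
  stopifnot(inherits(fit, "dta_bivariate"))
  if (fit$tau[1] < 1e-4 || fit$tau[2] < 1e-4) {
    warning("between-study variance at the zero boundary: correlation undefined")
    return(structure(NA_real_, sens_spec = NA_real_))
  }
  structure(fit$rho, sens_spec = -fit$rho)
}

#' Cochran's Q and I-squared for one accuracy component
#'
#' Descriptive univariate heterogeneity statistics from inverse-variance
#' fixed-effect pooling of the chosen logit outcome:
#' `Q = sum w_i (y_i - yhat)^2` with `w_i = 1/v_i`, and
#' `I2 = max(0, (Q - (k-1))/Q) * 100`.
#'
#' @param x a `dta_data` object or the output of [logit_transform()].
#' @param outcome `"sensitivity"` (uses `y1, v1`) or `"fpr"` (uses `y2, v2`;
#'   specificity has the same Q/I-squared as the FPR since logit spec = -y2).
#' @return Named vector `c(Q, I2, df)`.
#' @export
cochran_q_i2 <- function(x, outcome = c("sensitivity", "fpr")) {
  outcome <- match.arg(outcome)
  trans <- if (inherits(x, "dta_data")) logit_transform(x) else x
  y <- if (outcome == "sensitivity") trans$y1 else trans$y2
  v <- if (outcome == "sensitivity") trans$v1 else trans$v2
  k <- length(y)
  stopifnot(k >= 2)
  w <- 1 / v
  yhat <- sum(w * y) / sum(w)
  Q <- sum(w * (y - yhat)^2)
  I2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0
  c(Q = Q, I2 = I2, df = k - 1)
}

#' Pooled accuracy summary with Monte-Carlo intervals
#'
#' Back-transforms the fitted means to pooled sensitivity and specificity with
#' 95% Wald intervals on the logit scale; derives LR+, LR- and the DOR from the
#' pooled estimates, with percentile confidence intervals from `mc_draws`
#' Monte-Carlo samples of the fixed effects `N(mu, vcov)`; and appends
#' Cochran's Q / I-squared per component and the threshold-effect correlation.
#'
#' @param fit an intercept-only [dta_bivariate()] fit.
#' @param mc_draws number of Monte-Carlo draws (default 100000).
#' @param seed seed for the Monte-Carlo draws, recorded in the result.
#' @param level confidence level (default 0.95).
#' @param df degrees of freedom for the Wald interval quantile. The default
#'   `k - 2` is a small-sample (Knapp-Hartung-style) calibration appropriate
#'   for the handful-of-studies regime; `df = Inf` gives the normal-quantile
#'   convention of most published analyses.
#' @return A `pooled_summary` list.
#' @export
pooled_summary <- function(fit, mc_draws = 100000L, seed = 1L, level = 0.95,
                           df = NULL) {
  stopifnot(inherits(fit, "dta_bivariate"))
  if (length(fit$beta) != 2) {
    stop_dta("pooled_summary needs an intercept-only fit (no covariate)", "dta_domain_error")
  }
  df <- df %||% max(1, fit$k - 2)
  z <- stats::qt(1 - (1 - level) / 2, df = df)
  se <- sqrt(diag(fit$vcov))
  sens <- expit(fit$mu[1])
  spec <- 1 - expit(fit$mu[2])
  sens_ci <- expit(fit$mu[1] + c(-1, 1) * z * se[1])
  spec_ci <- rev(1 - expit(fit$mu[2] + c(-1, 1) * z * se[2]))
  lr <- lr_from_sens_spec(sens, spec)

  state <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  L <- chol(fit$vcov + diag(1e-14, 2))
  draws <- matrix(stats::rnorm(2 * mc_draws), mc_draws, 2) %*% L
  draws <- sweep(draws, 2, fit$mu, "+")
  if (!is.null(state)) assign(".Random.seed", state, .GlobalEnv)
  s_d <- expit(draws[, 1]); sp_d <- 1 - expit(draws[, 2])
  lrp_d <- s_d / (1 - sp_d); lrn_d <- (1 - s_d) / sp_d
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  lr_pos_ci <- stats::quantile(lrp_d, qs, names = FALSE)
  lr_neg_ci <- stats::quantile(lrn_d, qs, names = FALSE)
  dor_ci <- stats::quantile(lrp_d / lrn_d, qs, names = FALSE)

  q1 <- cochran_q_i2(fit$trans, "sensitivity")
  q2 <- cochran_q_i2(fit$trans, "fpr")
  rho <- suppressWarnings(threshold_correlation(fit))
  structure(
    list(
      sensitivity = unname(sens), sensitivity_ci = sens_ci,
      specificity = unname(spec), specificity_ci = spec_ci,
      lr_pos = lr$lr_pos, lr_pos_ci = lr_pos_ci,
      lr_neg = lr$lr_neg, lr_neg_ci = lr_neg_ci,
      dor = lr$dor, dor_ci = dor_ci,
      q_sens = q1[["Q"]], i2_sens = q1[["I2"]],
      q_spec = q2[["Q"]], i2_spec = q2[["I2"]],
      threshold_correlation = as.numeric(rho),
      threshold_correlation_spec = as.numeric(attr(rho, "sens_spec")),
      mc_draws = as.integer(mc_draws), seed = as.integer(seed), level = level,
      ci_df = df,
      k = fit$k
    ),
    class = "pooled_summary"
  )
}

#' @export
summary.dta_bivariate <- function(object, mc_draws = 100000L, seed = 1L,
                                  level = 0.95, df = NULL, ...) {
  pooled_summary(object, mc_draws = mc_draws, seed = seed, level = level, df = df)
}

#' @export
print.pooled_summary <- function(x, digits = 3, ...) {
  fmt <- function(est, ci) sprintf("%.*f (%.*f-%.*f)", digits, est, digits, ci[1], digits, ci[2])
  cat(sprintf("Pooled diagnostic accuracy (k = %d studies, %d%% CI)\n",
              x$k, round(100 * x$level)))
  cat("  sensitivity:", fmt(x$sensitivity, x$sensitivity_ci), "\n")
  cat("  specificity:", fmt(x$specificity, x$specificity_ci), "\n")
  cat("  LR+:", fmt(x$lr_pos, x$lr_pos_ci),
      " LR-:", fmt(x$lr_neg, x$lr_neg_ci), "\n")
  cat("  DOR:", fmt(x$dor, x$dor_ci),
      sprintf(" [Monte Carlo, %d draws, seed %d]\n", x$mc_draws, x$seed))
  cat(sprintf("  I2: sensitivity %.1f%%, specificity %.1f%%\n", x$i2_sens, x$i2_spec))
  if (is.finite(x$threshold_correlation)) {
    cat(sprintf("  between-study correlation (logit sens vs logit FPR): %.3f\n",
                x$threshold_correlation))
    cat(sprintf("    (vs logit specificity: %.3f)\n", x$threshold_correlation_spec))
  } else {
    cat("  between-study correlation: undefined (variance at zero boundary)\n")
  }
  invisible(x)
}

#' @export
print.dta_bivariate <- function(x, digits = 3, ...) {
  cat(sprintf("Bivariate random-effects fit (%s), k = %d studies\n",
              toupper(x$method), x$k))
  cat(sprintf("  pooled sensitivity %.3f, specificity %.3f\n",
              expit(x$mu[1]), 1 - expit(x$mu[2])))
  cat(sprintf("  tau1 = %.3f, tau2 = %.3f, rho = %.3f; logLik = %.3f\n",
              x$tau[1], x$tau[2], x$rho, x$loglik))
  if (!is.null(x$covariate)) cat(sprintf("  covariate: %s\n", x$covariate))
  if (x$at_boundary) cat("  note: between-study variance at the zero boundary\n")
  invisible(x)
}

#' @export
coef.dta_bivariate <- function(object, ...) object$beta

#' @export
vcov.dta_bivariate <- function(object, ...) object$vcov

#' @export
logLik.dta_bivariate <- function(object, ...) {
  structure(object$loglik, df = object$n_params, class = "logLik")
}

#' @export
residuals.dta_bivariate <- function(object, ...) {
  ## standardized marginal residuals on the logit scale
  t1 <- object$Sigma[1, 1]; t2 <- object$Sigma[2, 2]
  cbind(
    sens = (object$trans$y1 - object$mu[1]) / sqrt(t1 + object$trans$v1),
    fpr = (object$trans$y2 - object$mu[2]) / sqrt(t2 + object$trans$v2)
  )
}

#' @export
simulate.dta_bivariate <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n_d <- object$trans$n_diseased
  n_nd <- object$trans$n_nondiseased
  k <- object$k
  L <- chol(object$Sigma + diag(1e-12, 2))
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    eta <- sweep(matrix(stats::rnorm(2 * k), k, 2) %*% L, 2, object$mu, "+")
    tp <- stats::rbinom(k, n_d, expit(eta[, 1]))
    fp <- stats::rbinom(k, n_nd, expit(eta[, 2]))
    out[[s]] <- as_dta_data(
      data.frame(
        study_id = object$trans$study_id, tp = tp, fp = fp,
        fn = n_d - tp, tn = n_nd - fp, stringsAsFactors = FALSE
      ),
      provenance = "simulated from fitted bivariate model"
    )
  }
  if (nsim == 1) out[[1]] else out
}
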