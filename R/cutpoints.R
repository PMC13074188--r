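## Multiple-cutoff meta-analytic model. Across studies that dichotomize the
## biomarker at different cutoffs c_i, the two group-specific cumulative
## distributions are modelled on the logit scale as linear in a transform f:
##   logit(1 - sens_i) = a_d  + b_d  f(c_i)   (diseased CDF at the cutoff)
##   logit(spec_i)     = a_nd + b_nd f(c_i)   (non-diseased CDF at the cutoff)
## fitted by weighted least squares with group sample sizes as weights. The two
## fitted curves yield accuracy, Youden index and likelihood-ratio curves as
## continuous functions of the cutoff.

CUTPOINT_TRANSFORMS <- list(
  identity = function(c) c,
  log = function(c) log(c),
  sqrt = function(c) sqrt(c)
)

fit_cutpoint_lines <- function(data, transform, weights = "size",
                               value = 0.5, mode = "any-zero-all-cells") {
  keep <- !is.na(data$cutoff)
  if (sum(keep) < 3) {
    stop_dta("at least 3 studies with explicit cutoffs are required", "dta_insufficient_data")
  }
  sub <- as_dta_data(as.data.frame(data)[keep, , drop = FALSE],
                     provenance = attr(data, "provenance") %||% "subset")
  if (length(unique(sub$cutoff)) < 2) {
    stop_dta("all cutoffs are equal: the slope is unidentifiable", "dta_unidentifiable")
  }
  trans <- logit_transform(sub, value = value, mode = mode)
  f <- CUTPOINT_TRANSFORMS[[transform]]
  fc <- f(sub$cutoff)
  y_d <- logit(1 - trans$sens)   # diseased CDF on logit scale
  y_nd <- logit(trans$spec)      # non-diseased CDF on logit scale
  w_d <- switch(weights, size = trans$n_diseased,
                invvar = 1 / trans$v1, equal = rep(1, nrow(sub)))
  w_nd <- switch(weights, size = trans$n_nondiseased,
                 invvar = 1 / trans$v2, equal = rep(1, nrow(sub)))
  m_d <- stats::lm(y_d ~ fc, weights = w_d)
  m_nd <- stats::lm(y_nd ~ fc, weights = w_nd)
  ## combined AIC from the joint weighted Gaussian log-likelihood of both
  ## lines: 2 coefficients + 1 variance per line = 6 parameters
  ll <- as.numeric(stats::logLik(m_d)) + as.numeric(stats::logLik(m_nd))
  list(
    transform = transform,
    coef_diseased = unname(stats::coef(m_d)),
    coef_nondiseased = unname(stats::coef(m_nd)),
    lm_diseased = m_d, lm_nondiseased = m_nd,
    aic = -2 * ll + 2 * 6, loglik = ll,
    included_studies = sub$study_id,
    c_range = range(sub$cutoff),
    weights = weights, data = sub
  )
}

#' Fit the multiple-cutoff accuracy model
#'
#' Regresses logit specificity and logit(1 - sensitivity) (continuity-corrected
#' proportions) on a transform of the study cutoff by weighted least squares
#' (weights: the respective group sample sizes by default). With
#' `transform = "auto"` (default) the linear, logarithmic and square-root
#' transforms are compared by the combined AIC of the joint two-line weighted
#' Gaussian likelihood, ties broken toward `"log"` (concentrations live on a
#' positive, multiplicative scale); all three candidate AICs are retained for
#' audit.
#'
#' Studies without a reported cutoff are excluded (at least 3 cutoff-bearing
#' studies with non-identical cutoffs are required). Each study contributes one
#' cutoff here, so study-level random effects are not identifiable and the
#' model is a fixed-effects WLS fit.
#'
#' @param data a `dta_data` object with a `cutoff` column.
#' @param transform `"auto"`, `"log"`, `"identity"` or `"sqrt"`.
#' @param weights `"size"` (group sample size, default), `"invvar"`
#'   (inverse delta-method variance) or `"equal"`.
#' @param value,mode continuity-correction settings, see [correct_counts()].
#' @return An object of class `dta_cutpoints`: transform name, coefficient
#'   pairs `coef_diseased` / `coef_nondiseased` (intercept, slope), `aic`,
#'   `all_aics` (named, when `transform = "auto"`), `tie` flag,
#'   `included_studies`, observed `c_range` and the default evaluation range
#'   `eval_range = [0.5 c_min, 1.2 c_max]`. Methods: `print`, `coef`,
#'   `predict`, `plot`.
#' @examples
#' sim <- simulate_studies(default_sim_config())
#' cp <- dta_cutpoints(sim$data)
#' predict(cp, cutoff = c(20, 30, 40))
#' @export
dta_cutpoints <- function(data, transform = c("auto", "log", "identity", "sqrt"),
                          weights = c("size", "invvar", "equal"),
                          value = 0.5, mode = "any-zero-all-cells") {
  stopifnot(inherits(data, "dta_data"))
  transform <- match.arg(transform)
  weights <- match.arg(weights)
  if (transform == "auto") {
    fits <- lapply(names(CUTPOINT_TRANSFORMS), function(tr) {
      fit_cutpoint_lines(data, tr, weights, value, mode)
    })
    names(fits) <- names(CUTPOINT_TRANSFORMS)
    aics <- vapply(fits, `[[`, numeric(1), "aic")
    best_val <- min(aics)
    ## near-ties at the minimum (including degenerate perfect fits at -Inf)
    near <- abs(aics - best_val) < 1e-8 |
      (!is.finite(aics) & !is.finite(best_val) & aics < 0)
    chosen <- if (near[["log"]]) "log" else names(which.min(aics))
    res <- fits[[chosen]]
    res$all_aics <- aics
    res$tie <- near[["log"]] && sum(near) > 1
    res$selected <- TRUE
  } else {
    res <- fit_cutpoint_lines(data, transform, weights, value, mode)
    res$all_aics <- stats::setNames(res$aic, transform)
    res$tie <- FALSE
    res$selected <- FALSE
  }
  res$eval_range <- c(0.5 * res$c_range[1], 1.2 * res$c_range[2])
  class(res) <- "dta_cutpoints"
  res
}

#' @export
print.dta_cutpoints <- function(x, ...) {
  cat(sprintf("Multiple-cutoff model (%s transform, %s weights), %d studies\n",
              x$transform, x$weights, length(x$included_studies)))
  cat(sprintf("  non-diseased line (logit spec):      %.4f + %.4f f(c)\n",
              x$coef_nondiseased[1], x$coef_nondiseased[2]))
  cat(sprintf("  diseased line (logit(1 - sens)):     %.4f + %.4f f(c)\n",
              x$coef_diseased[1], x$coef_diseased[2]))
  cat(sprintf("  combined AIC: %.2f", x$aic))
  if (length(x$all_aics) > 1) {
    cat("  [", paste(sprintf("%s %.2f", names(x$all_aics), x$all_aics), collapse = ", "), "]")
  }
  cat("\n")
  if (isTRUE(x$tie)) cat("  note: AIC tie broken toward the log transform\n")
  cat(sprintf("  observed cutoffs: %.2f-%.2f ng/mL\n", x$c_range[1], x$c_range[2]))
  invisible(x)
}

#' @export
coef.dta_cutpoints <- function(object, ...) {
  c(a_nondiseased = object$coef_nondiseased[1], b_nondiseased = object$coef_nondiseased[2],
    a_diseased = object$coef_diseased[1], b_diseased = object$coef_diseased[2])
}

#' Predicted accuracy at a cutoff
#'
#' @param object a [dta_cutpoints()] fit.
#' @param cutoff positive cutoff value(s), ng/mL.
#' @param warn_extrapolation warn when a cutoff lies outside the observed
#'   cutoff range (default TRUE).
#' @param ... unused.
#' @return Data frame with columns `cutoff`, `sensitivity`, `specificity`,
#'   `extrapolated`.
#' @export
predict.dta_cutpoints <- function(object, cutoff, warn_extrapolation = TRUE, ...) {
  stopifnot(all(cutoff > 0))
  f <- CUTPOINT_TRANSFORMS[[object$transform]]
  fc <- f(cutoff)
  sens <- 1 - expit(object$coef_diseased[1] + object$coef_diseased[2] * fc)
  spec <- expit(object$coef_nondiseased[1] + object$coef_nondiseased[2] * fc)
  extra <- cutoff < object$c_range[1] | cutoff > object$c_range[2]
  if (warn_extrapolation && any(extra)) {
    warning("some cutoffs lie outside the observed cutoff range (extrapolation)")
  }
  data.frame(cutoff = cutoff, sensitivity = sens, specificity = spec,
             extrapolated = extra)
}

#' Youden-optimal cutoff
#'
#' Maximizes `J(c) = sensitivity(c) + specificity(c) - 1` over a dense grid on
#' the evaluation range, followed by local refinement (golden-section search in
#' the bracketing grid cells). Deterministic given the grid specification.
#'
#' @param fit a [dta_cutpoints()] fit.
#' @param grid_points number of grid points (default 2001).
#' @param range evaluation range (default `fit$eval_range`).
#' @return List with `cutoff`, `youden`, `sensitivity`, `specificity`. If
#'   `J <= 0` everywhere the test is useless on this range: `cutoff` is `NA`
#'   and `note` explains.
#' @export
youden_cutoff <- function(fit, grid_points = 2001, range = NULL) {
  stopifnot(inherits(fit, "dta_cutpoints"))
  rng <- range %||% fit$eval_range
  grid <- seq(rng[1], rng[2], length.out = grid_points)
  jfun <- function(c) {
    p <- predict(fit, c, warn_extrapolation = FALSE)
    p$sensitivity + p$specificity - 1
  }
  J <- jfun(grid)
  if (all(J <= 0)) {
    return(list(cutoff = NA_real_, youden = max(J), sensitivity = NA_real_,
                specificity = NA_real_, note = "J <= 0 everywhere on the grid"))
  }
  i <- which.max(J)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(grid_points, i + 1)]
  opt <- stats::optimize(jfun, c(lo, hi), maximum = TRUE, tol = 1e-10)
  p <- predict(fit, opt$maximum, warn_extrapolation = FALSE)
  list(cutoff = opt$maximum, youden = opt$objective,
       sensitivity = p$sensitivity, specificity = p$specificity)
}

#' Continuous likelihood-ratio curves
#'
#' Evaluates `LR+(c) = sens(c)/(1 - spec(c))` and
#' `LR-(c) = (1 - sens(c))/spec(c)` on a grid spanning the evaluation range
#' (default `[0.5 c_min, 1.2 c_max]`); points outside the observed cutoff range
#' are flagged as extrapolated.
#'
#' @param fit a [dta_cutpoints()] fit.
#' @param cutoffs optional explicit grid; default 512 equally spaced points.
#' @return Data frame `cutoff`, `sensitivity`, `specificity`, `lr_pos`,
#'   `lr_neg`, `extrapolated`.
#' @export
lr_curves <- function(fit, cutoffs = NULL) {
  stopifnot(inherits(fit, "dta_cutpoints"))
  if (is.null(cutoffs)) {
    cutoffs <- seq(fit$eval_range[1], fit$eval_range[2], length.out = 512)
  }
  p <- predict(fit, cutoffs, warn_extrapolation = FALSE)
  lr <- lr_from_sens_spec(pmin(pmax(p$sensitivity, 1e-12), 1 - 1e-12),
                          pmin(pmax(p$specificity, 1e-12), 1 - 1e-12))
  cbind(p[c("cutoff", "sensitivity", "specificity")], lr[c("lr_pos", "lr_neg")],
        extrapolated = p$extrapolated)
}

## Find all sign-change crossings of g(c) = 0 on a grid, refined by uniroot.
find_crossings <- function(g, grid) {
  vals <- g(grid)
  s <- sign(vals)
  idx <- which(s[-1] * s[-length(s)] < 0)
  roots <- vapply(idx, function(i) {
    stats::uniroot(g, c(grid[i], grid[i + 1]), tol = 1e-10)$root
  }, numeric(1))
  exact <- grid[vals == 0]
  sort(unique(c(roots, exact)))
}

#' Likelihood-ratio decision thresholds
#'
#' Locates the rule-in cutoff where `LR+(c)` crosses `lr_pos_target` (default
#' 10) and the rule-out cutoff where `LR-(c)` crosses `lr_neg_target` (default
#' 0.1), by grid bracketing plus root refinement on the continuous fitted
#' curves. When several crossings exist the one nearest the Youden optimum is
#' chosen and the multiplicity is reported. When a target is met everywhere on
#' the grid the corresponding grid edge is returned; when it is met nowhere the
#' threshold is `NA` with note `"not achieved on grid"` (absence is a value,
#' never an extrapolated fabrication).
#'
#' @param fit a [dta_cutpoints()] fit.
#' @param lr_pos_target rule-in LR+ target (default 10).
#' @param lr_neg_target rule-out LR- target (default 0.1).
#' @param grid_points grid density (default 2001).
#' @param range evaluation range (default `fit$eval_range`).
#' @return List with `rule_in_cutoff`, `rule_out_cutoff`, per-threshold notes
#'   and crossing multiplicities, and the targets.
#' @export
lr_thresholds <- function(fit, lr_pos_target = 10, lr_neg_target = 0.1,
                          grid_points = 2001, range = NULL) {
  stopifnot(inherits(fit, "dta_cutpoints"))
  if (!(lr_neg_target < 1 && 1 < lr_pos_target)) {
    stop_dta("LR targets must satisfy lr_neg_target < 1 < lr_pos_target", "dta_config_error")
  }
  rng <- range %||% fit$eval_range
  grid <- seq(rng[1], rng[2], length.out = grid_points)
  pred <- function(c) predict(fit, c, warn_extrapolation = FALSE)
  gpos <- function(c) { p <- pred(c); p$sensitivity / (1 - p$specificity) - lr_pos_target }
  gneg <- function(c) { p <- pred(c); (1 - p$sensitivity) / p$specificity - lr_neg_target }
  yo <- youden_cutoff(fit, grid_points = min(grid_points, 1001), range = rng)
  pick <- function(crossings) {
    if (length(crossings) <= 1) return(crossings)
    if (is.na(yo$cutoff)) return(crossings[1])
    crossings[which.min(abs(crossings - yo$cutoff))]
  }
  cr_pos <- find_crossings(gpos, grid)
  cr_neg <- find_crossings(gneg, grid)
  rule_in <- note_in <- NULL
  if (length(cr_pos) >= 1) {
    rule_in <- pick(cr_pos); note_in <- sprintf("%d crossing(s)", length(cr_pos))
  } else if (all(gpos(grid) >= 0)) {
    rule_in <- rng[1]; note_in <- "target met over the whole grid (lower edge)"
  } else {
    rule_in <- NA_real_; note_in <- "not achieved on grid"
  }
  rule_out <- note_out <- NULL
  if (length(cr_neg) >= 1) {
    rule_out <- pick(cr_neg); note_out <- sprintf("%d crossing(s)", length(cr_neg))
  } else if (all(gneg(grid) <= 0)) {
    rule_out <- rng[2]; note_out <- "target met over the whole grid (upper edge)"
  } else {
    rule_out <- NA_real_; note_out <- "not achieved on grid"
  }
  list(rule_in_cutoff = rule_in, rule_out_cutoff = rule_out,
       note_rule_in = note_in, note_rule_out = note_out,
       n_crossings_pos = length(cr_pos), n_crossings_neg = length(cr_neg),
       lr_pos_target = lr_pos_target, lr_neg_target = lr_neg_target,
       grid = c(min = rng[1], max = rng[2], points = grid_points))
}

#' Cluster bootstrap interval for the Youden-optimal cutoff
#'
#' Resamples studies with replacement, refits the cutoff model with the same
#' (already selected) transform, recomputes the Youden optimum, and returns
#' the percentile 2.5/97.5 interval. Replicates whose refit fails (e.g. all
#' resampled cutoffs equal) are dropped and counted; more than 20% failures
#' attaches an instability warning to the result.
#'
#' @param data a `dta_data` object with cutoffs.
#' @param fit a [dta_cutpoints()] fit on `data` (fixes the transform and
#'   weights); refitted internally if omitted.
#' @param B number of bootstrap replicates (default 1000).
#' @param seed integer seed (recorded in the result).
#' @param level interval level (default 0.95).
#' @return List with `ci` (length-2), `B`, `seed`, `n_failed`, `unstable`
#'   flag, and the vector of bootstrap optima `boot_cutoffs`.
#' @export
bootstrap_cutoff_ci <- function(data, fit = NULL, B = 1000L, seed = 1L,
                                level = 0.95) {
  stopifnot(inherits(data, "dta_data"))
  if (is.null(fit)) fit <- dta_cutpoints(data)
  keep <- !is.na(data$cutoff)
  base <- as.data.frame(data)[keep, , drop = FALSE]
  k <- nrow(base)
  set.seed(seed)
  boot <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- sample.int(k, k, replace = TRUE)
    bd <- base[idx, , drop = FALSE]
    bd$study_id <- sprintf("boot_%02d", seq_len(k))
    res <- tryCatch({
      bfit <- dta_cutpoints(as_dta_data(bd, provenance = "bootstrap"),
                            transform = fit$transform, weights = fit$weights)
      youden_cutoff(bfit)$cutoff
    }, error = function(e) NA_real_)
    boot[b] <- res
  }
  ok <- boot[!is.na(boot)]
  n_failed <- B - length(ok)
  unstable <- n_failed > 0.2 * B
  if (unstable) warning("more than 20% of bootstrap refits failed: interval is unstable")
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  list(ci = stats::quantile(ok, qs, names = FALSE), B = as.integer(B),
       seed = as.integer(seed), n_failed = n_failed, unstable = unstable,
       boot_cutoffs = boot)
}

#' Assemble the full threshold report
#'
#' Combines the Youden-optimal cutoff (with cluster-bootstrap interval) and the
#' likelihood-ratio rule-in / rule-out thresholds of a fitted cutoff model.
#'
#' @param fit a [dta_cutpoints()] fit.
#' @param data the `dta_data` the fit came from (needed for the bootstrap;
#'   omit to skip the bootstrap interval).
#' @param B,seed bootstrap settings, see [bootstrap_cutoff_ci()].
#' @param lr_pos_target,lr_neg_target see [lr_thresholds()].
#' @param grid_points grid density for optimum and crossing searches.
#' @return A `threshold_report` list: `youden_cutoff`, `youden_value`,
#'   `sens_at_opt`, `spec_at_opt`, `bootstrap_ci` (or NULL), `rule_in_cutoff`,
#'   `rule_out_cutoff`, notes, targets, and the evaluation-grid description.
#' @export
threshold_report <- function(fit, data = NULL, B = 1000L, seed = 1L,
                             lr_pos_target = 10, lr_neg_target = 0.1,
                             grid_points = 2001) {
  yo <- youden_cutoff(fit, grid_points = grid_points)
  th <- lr_thresholds(fit, lr_pos_target, lr_neg_target, grid_points)
  bs <- if (!is.null(data) && !is.na(yo$cutoff)) {
    bootstrap_cutoff_ci(data, fit, B = B, seed = seed)
  }
  ordered <- !is.na(th$rule_in_cutoff) && !is.na(th$rule_out_cutoff) &&
    th$rule_out_cutoff < th$rule_in_cutoff
  structure(
    list(
      youden_cutoff = yo$cutoff, youden_value = yo$youden,
      sens_at_opt = yo$sensitivity, spec_at_opt = yo$specificity,
      bootstrap_ci = bs$ci, bootstrap = bs,
      rule_in_cutoff = th$rule_in_cutoff, rule_out_cutoff = th$rule_out_cutoff,
      note_rule_in = th$note_rule_in, note_rule_out = th$note_rule_out,
      thresholds_ordered = ordered,
      lr_pos_target = lr_pos_target, lr_neg_target = lr_neg_target,
      grid = th$grid, transform = fit$transform
    ),
    class = "threshold_report"
  )
}

#' @export
print.threshold_report <- function(x, ...) {
  cat("Decision-threshold report (", x$transform, " transform)\n", sep = "")
  if (is.na(x$youden_cutoff)) {
    cat("  Youden optimum: none (J <= 0 on the evaluation grid)\n")
  } else {
    cat(sprintf("  Youden-optimal cutoff: %.1f ng/mL (J = %.3f; sens %.3f, spec %.3f)\n",
                x$youden_cutoff, x$youden_value, x$sens_at_opt, x$spec_at_opt))
    if (!is.null(x$bootstrap_ci)) {
      cat(sprintf("    95%% bootstrap CI: %.1f-%.1f ng/mL (B = %d, seed %d, %d failed)\n",
                  x$bootstrap_ci[1], x$bootstrap_ci[2], x$bootstrap$B,
                  x$bootstrap$seed, x$bootstrap$n_failed))
    }
  }
  fmt <- function(v, note) if (is.na(v)) note else sprintf("%.1f ng/mL (%s)", v, note)
  cat(sprintf("  rule-in (LR+ >= %g):  %s\n", x$lr_pos_target,
              fmt(x$rule_in_cutoff, x$note_rule_in)))
  cat(sprintf("  rule-out (LR- <= %g): %s\n", x$lr_neg_target,
              fmt(x$rule_out_cutoff, x$note_rule_out)))
  invisible(x)
}

#' Plot likelihood-ratio curves with decision thresholds
#'
#' @param x a [dta_cutpoints()] fit.
#' @param report optional [threshold_report()] to mark thresholds.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.dta_cutpoints <- function(x, report = NULL, ...) {
  cv <- lr_curves(x)
  graphics::plot(cv$cutoff, cv$lr_pos, type = "l", log = "y", col = "blue",
                 xlab = "Cutoff (ng/mL)", ylab = "Likelihood ratio",
                 ylim = range(c(cv$lr_pos, cv$lr_neg)), ...)
  graphics::lines(cv$cutoff, cv$lr_neg, col = "red")
  graphics::abline(h = c(10, 0.1), lty = 3, col = "grey50")
  if (!is.null(report)) {
    if (!is.na(report$youden_cutoff)) {
      graphics::abline(v = report$youden_cutoff, lty = 2, col = "darkgreen")
    }
    if (!is.na(report$rule_in_cutoff)) {
      graphics::points(report$rule_in_cutoff, report$lr_pos_target, pch = 4, cex = 1.4)
    }
    if (!is.na(report$rule_out_cutoff)) {
      graphics::points(report$rule_out_cutoff, report$lr_neg_target, pch = 4, cex = 1.4)
    }
  }
  invisible(x)
}
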