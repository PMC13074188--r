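## Summary ROC geometry from a bivariate fit. The curve is the
## conditional-expectation regression line on the logit scale,
##   E[logit TPR | logit FPR = f] = mu1 + (sigma12/sigma22) (f - mu2),
## mapped through the inverse logit. Confidence and prediction regions are
## chi-square ellipses on the logit scale around mu, with shape matrix vcov
## (confidence) or vcov + Sigma (prediction).

#' Summary ROC curve
#'
#' @param fit a [dta_bivariate()] fit.
#' @param fpr optional vector of false-positive rates at which to evaluate the
#'   curve; defaults to 201 points spanning the observed FPR range of the data
#'   (set `extrapolate = TRUE` for the full (0, 1) range).
#' @param extrapolate evaluate over (0.001, 0.999) instead of the observed
#'   range.
#' @return Data frame with columns `fpr`, `tpr`. When the between-study FPR
#'   variance is zero the slope is undefined and the horizontal line
#'   `tpr = expit(mu1)` is returned with a warning.
#' @export
sroc_curve <- function(fit, fpr = NULL, extrapolate = FALSE) {
  stopifnot(inherits(fit, "dta_bivariate"))
  if (is.null(fpr)) {
    rng <- if (extrapolate) c(0.001, 0.999) else {
      obs <- expit(fit$trans$y2)
      range(obs)
    }
    fpr <- seq(rng[1], rng[2], length.out = 201)
  }
  t22 <- fit$Sigma[2, 2]
  if (t22 < 1e-8) {
    warning("zero between-study FPR variance: SROC slope undefined, returning flat curve")
    return(data.frame(fpr = fpr, tpr = rep(expit(fit$mu[1]), length(fpr))))
  }
  slope <- fit$Sigma[1, 2] / t22
  tpr <- expit(fit$mu[1] + slope * (logit(fpr) - fit$mu[2]))
  data.frame(fpr = fpr, tpr = tpr)
}

ellipse_region <- function(center, shape, level, n_points) {
  if (min(eigen(shape, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    warning("shape matrix not positive definite; adding a small ridge")
    shape <- shape + diag(1e-10, 2)
  }
  r <- sqrt(stats::qchisq(level, df = 2))
  theta <- seq(0, 2 * pi, length.out = n_points + 1)
  circ <- r * cbind(cos(theta), sin(theta))
  pts <- circ %*% chol(shape)
  pts <- sweep(pts, 2, center, "+")
  data.frame(fpr = expit(pts[, 2]), tpr = expit(pts[, 1]))
}

#' Confidence and prediction regions around the summary point
#'
#' `confidence_region()` describes uncertainty in the *mean* operating point
#' (shape matrix = fixed-effect covariance); `prediction_region()` describes
#' where the true operating point of a *new* study is expected (shape matrix =
#' fixed-effect covariance + between-study covariance). Ellipses are built on
#' the logit scale with squared radius the chi-square(2) quantile at `level`,
#' discretized at `n_points` vertices, and mapped through the inverse logit
#' (which preserves containment, being monotone per coordinate).
#'
#' @param fit a [dta_bivariate()] fit.
#' @param level confidence level (default 0.95).
#' @param n_points number of polyline vertices (default 360, minimum 180).
#' @return Data frame of closed polyline coordinates `fpr`, `tpr`.
#' @export
confidence_region <- function(fit, level = 0.95, n_points = 360) {
  stopifnot(inherits(fit, "dta_bivariate"), n_points >= 180)
  ellipse_region(fit$mu, fit$vcov[1:2, 1:2], level, n_points)
}

#' @rdname confidence_region
#' @export
prediction_region <- function(fit, level = 0.95, n_points = 360) {
  stopifnot(inherits(fit, "dta_bivariate"), n_points >= 180)
  ellipse_region(fit$mu, fit$vcov[1:2, 1:2] + fit$Sigma, level, n_points)
}

#' Plot the summary ROC for a bivariate fit
#'
#' Draws per-study points (circle area proportional to study size), the summary
#' point, the SROC curve over the observed FPR range, and the 95% confidence
#' (solid) and prediction (dashed) regions.
#'
#' @param x a [dta_bivariate()] fit.
#' @param level region level (default 0.95).
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.dta_bivariate <- function(x, level = 0.95, ...) {
  obs_fpr <- expit(x$trans$y2)
  obs_tpr <- expit(x$trans$y1)
  n <- x$trans$n_diseased + x$trans$n_nondiseased
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = "Summary ROC", ...)
  graphics::abline(0, 1, col = "grey70")
  graphics::symbols(obs_fpr, obs_tpr, circles = sqrt(n / max(n)) * 0.03,
                    inches = FALSE, add = TRUE, fg = "grey40")
  cr <- confidence_region(x, level)
  pr <- prediction_region(x, level)
  graphics::lines(cr$fpr, cr$tpr, lty = 1, col = "red")
  graphics::lines(pr$fpr, pr$tpr, lty = 2, col = "red")
  sc <- sroc_curve(x)
  graphics::lines(sc$fpr, sc$tpr, col = "blue")
  graphics::points(expit(x$mu[2]), expit(x$mu[1]), pch = 18, cex = 1.6, col = "red")
  invisible(x)
}
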