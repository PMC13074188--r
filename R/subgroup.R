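## Subgroup bivariate fits and univariable metaregression.

#' Subgroup bivariate fits
#'
#' Fits an independent bivariate model (and pooled summary) to each level of a
#' categorical study-level variable. Levels with fewer than `min_k` studies are
#' not modelled (the default 3 follows standard practice for this model) and
#' carry a skip reason instead.
#'
#' @param data a `dta_data` object.
#' @param variable name of a categorical column of `data`; missing values form
#'   their own level `"unreported"`.
#' @param min_k minimum number of studies per level for a fit (default 3).
#' @param mc_draws,seed passed to [pooled_summary()].
#' @param ... passed to [dta_bivariate()].
#' @return A `dta_subgroups` list with one element per level: either
#'   `list(k, n, fit, summary)` or `list(k, n, skipped = TRUE, reason)`.
#' @export
dta_subgroups <- function(data, variable, min_k = 3, mc_draws = 100000L,
                          seed = 1L, ...) {
  stopifnot(inherits(data, "dta_data"))
  if (!variable %in% names(data)) {
    stop_dta(sprintf("variable '%s' not found in data", variable), "dta_schema_error")
  }
  f <- as.character(data[[variable]])
  f[is.na(f) | f == ""] <- "unreported"
  levels <- unique(f)
  out <- list()
  for (lv in levels) {
    idx <- which(f == lv)
    sub <- as_dta_data(as.data.frame(data)[idx, , drop = FALSE],
                       provenance = sprintf("subgroup %s = %s", variable, lv))
    n_tot <- sum(sub$tp + sub$fp + sub$fn + sub$tn)
    if (length(idx) < min_k) {
      out[[lv]] <- list(k = length(idx), n = n_tot, skipped = TRUE,
                        reason = sprintf("fewer than %d studies", min_k))
    } else {
      fit <- dta_bivariate(sub, ...)
      out[[lv]] <- list(k = length(idx), n = n_tot, skipped = FALSE, fit = fit,
                        summary = pooled_summary(fit, mc_draws = mc_draws, seed = seed))
    }
  }
  if (all(vapply(out, function(o) isTRUE(o$skipped), logical(1)))) {
    message(sprintf("all levels of '%s' have fewer than %d studies; nothing was fitted",
                    variable, min_k))
  }
  structure(list(variable = variable, levels = out), class = "dta_subgroups")
}

#' @export
print.dta_subgroups <- function(x, ...) {
  cat(sprintf("Subgroup analysis by '%s'\n", x$variable))
  for (lv in names(x$levels)) {
    o <- x$levels[[lv]]
    if (isTRUE(o$skipped)) {
      cat(sprintf("  %s: k = %d, not modelled (%s)\n", lv, o$k, o$reason))
    } else {
      s <- o$summary
      cat(sprintf("  %s: k = %d, N = %d, sens %.3f (%.3f-%.3f), spec %.3f (%.3f-%.3f)\n",
                  lv, o$k, o$n, s$sensitivity, s$sensitivity_ci[1], s$sensitivity_ci[2],
                  s$specificity, s$specificity_ci[1], s$specificity_ci[2]))
    }
  }
  invisible(x)
}

#' Turn subgroup results into a summary table
#'
#' @param x a `dta_subgroups` object.
#' @param ... unused.
#' @return Data frame with one row per level: k, N, pooled accuracy with CIs,
#'   LR+, LR- and DOR (NA for skipped levels).
#' @export
as.data.frame.dta_subgroups <- function(x, ...) {
  rows <- lapply(names(x$levels), function(lv) {
    o <- x$levels[[lv]]
    if (isTRUE(o$skipped)) {
      data.frame(level = lv, k = o$k, n = o$n, sensitivity = NA_real_,
                 sens_lo = NA_real_, sens_hi = NA_real_, specificity = NA_real_,
                 spec_lo = NA_real_, spec_hi = NA_real_, lr_pos = NA_real_,
                 lr_neg = NA_real_, dor = NA_real_, note = o$reason,
                 stringsAsFactors = FALSE)
    } else {
      s <- o$summary
      data.frame(level = lv, k = o$k, n = o$n, sensitivity = s$sensitivity,
                 sens_lo = s$sensitivity_ci[1], sens_hi = s$sensitivity_ci[2],
                 specificity = s$specificity, spec_lo = s$specificity_ci[1],
                 spec_hi = s$specificity_ci[2], lr_pos = s$lr_pos,
                 lr_neg = s$lr_neg, dor = s$dor, note = "",
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Univariable metaregression with a likelihood-ratio test
#'
#' Adds one categorical covariate to both mean components of the bivariate
#' model and compares against the intercept-only model with a likelihood-ratio
#' test. Both models are fitted by ordinary maximum likelihood (not REML), so
#' the log-likelihoods are comparable across fixed-effect structures; the test
#' has `2 * (levels - 1)` degrees of freedom against a chi-square reference.
#'
#' @param data a `dta_data` object.
#' @param covariate name of a categorical column; missing values form level
#'   `"unreported"`.
#' @param ... passed to [dta_bivariate()].
#' @return A `dta_metareg` list with the LRT statistic, df, p-value and both
#'   ML log-likelihoods.
#' @export
dta_metareg <- function(data, covariate, ...) {
  stopifnot(inherits(data, "dta_data"))
  f <- as.character(data[[covariate]])
  f[is.na(f) | f == ""] <- "unreported"
  n_lev <- length(unique(f))
  if (n_lev < 2) {
    ## degenerate contrast: both models coincide
    fit0 <- dta_bivariate(data, method = "ml", ...)
    res <- list(covariate = covariate, lrt = 0, df = 0, p_value = 1,
                loglik_null = fit0$loglik, loglik_full = fit0$loglik,
                n_levels = n_lev)
    class(res) <- "dta_metareg"
    return(res)
  }
  fit0 <- dta_bivariate(data, method = "ml", ...)
  fit1 <- dta_bivariate(data, covariate = covariate, method = "ml", ...)
  lrt <- max(0, 2 * (fit1$loglik - fit0$loglik))
  df <- 2 * (n_lev - 1)
  structure(
    list(covariate = covariate, lrt = lrt, df = df,
         p_value = stats::pchisq(lrt, df, lower.tail = FALSE),
         loglik_null = fit0$loglik, loglik_full = fit1$loglik,
         n_levels = n_lev, fit_null = fit0, fit_full = fit1),
    class = "dta_metareg"
  )
}

#' @export
print.dta_metareg <- function(x, ...) {
  cat(sprintf("Metaregression on '%s' (ML, joint test on both components)\n", x$covariate))
  cat(sprintf("  LRT = %.3f on %d df, p = %.4g\n", x$lrt, x$df, x$p_value))
  invisible(x)
}
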