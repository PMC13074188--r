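## Clinical utility: Fagan (pretest -> post-test) probability updating,
## Deeks' funnel-plot asymmetry test, and threshold-zone classification.

#' Post-test probability from a likelihood ratio
#'
#' Bayes' update on the odds scale: `odds_post = odds_pre * lr`, converted back
#' to a probability. Vectorized over both arguments.
#'
#' @param pretest pretest probability, strictly inside (0, 1).
#' @param lr positive likelihood ratio (LR+ for a positive result, LR- for a
#'   negative result).
#' @return Post-test probability.
#' @examples
#' post_test_probability(0.50, 5.65)   # ~0.85
#' post_test_probability(0.25, 0.164)  # ~0.05
#' @export
post_test_probability <- function(pretest, lr) {
  if (any(pretest <= 0 | pretest >= 1)) {
    stop_dta("pretest probability must be strictly inside (0,1)", "dta_domain_error")
  }
  if (any(lr <= 0)) stop_dta("likelihood ratio must be > 0", "dta_domain_error")
  odds <- pretest / (1 - pretest) * lr
  odds / (1 + odds)
}

#' Fagan table of post-test probabilities
#'
#' Applies [post_test_probability()] with the pooled LR+ and LR- at each
#' pretest probability. Display percentages are rounded half-up to the whole
#' percent; unrounded values are retained.
#'
#' @param summary a [pooled_summary()] object, or any list with elements
#'   `lr_pos` and `lr_neg`.
#' @param pretests pretest probabilities (default 25%, 50%, 75%).
#' @return A `fagan_table` data frame with columns `pretest`, `post_positive`,
#'   `post_negative` (unrounded) and `post_positive_pct`, `post_negative_pct`
#'   (whole-percent display values).
#' @export
fagan_table <- function(summary, pretests = c(0.25, 0.50, 0.75)) {
  lr_pos <- summary$lr_pos
  lr_neg <- summary$lr_neg
  pp <- post_test_probability(pretests, lr_pos)
  pn <- post_test_probability(pretests, lr_neg)
  out <- data.frame(
    pretest = pretests,
    post_positive = pp,
    post_negative = pn,
    post_positive_pct = round_half_up(100 * pp),
    post_negative_pct = round_half_up(100 * pn)
  )
  attr(out, "lr_pos") <- lr_pos
  attr(out, "lr_neg") <- lr_neg
  class(out) <- c("fagan_table", "data.frame")
  out
}

#' Deeks' funnel-plot asymmetry test
#'
#' Regresses the study log diagnostic odds ratio on the inverse square root of
#' the effective sample size `ESS = 4 n1 n2 / (n1 + n2)`, by weighted least
#' squares with weights ESS, and tests the slope against zero with a
#' two-sided t-test on `k - 2` degrees of freedom. A p-value below `alpha`
#' (default 0.10, the customary level for this test) flags small-study
#' asymmetry. Counts are continuity-corrected before taking logs.
#'
#' @param data a `dta_data` object with at least 3 studies.
#' @param alpha decision level (default 0.10).
#' @param value,mode continuity-correction settings, see [correct_counts()].
#' @return A `deeks_test` list: `slope`, `intercept`, `p_value`, `asymmetry`
#'   flag, `alpha`, and the per-study `ess`, `ln_dor`, `inv_sqrt_ess`.
#' @export
deeks_test <- function(data, alpha = 0.10, value = 0.5, mode = "any-zero-all-cells") {
  stopifnot(inherits(data, "dta_data"))
  if (nrow(data) < 3) stop_dta("Deeks' test requires at least 3 studies", "dta_insufficient_data")
  d <- correct_counts(data, value = value, mode = mode)
  n1 <- data$tp + data$fn
  n2 <- data$fp + data$tn
  ess <- 4 * n1 * n2 / (n1 + n2)
  ln_dor <- log((d$tp_c * d$tn_c) / (d$fp_c * d$fn_c))
  x <- 1 / sqrt(ess)
  if (diff(range(x)) < 1e-12) {
    stop_dta("all effective sample sizes are equal: the asymmetry slope is unidentifiable",
             "dta_unidentifiable")
  }
  m <- stats::lm(ln_dor ~ x, weights = ess)
  ct <- summary(m)$coefficients
  structure(
    list(
      slope = ct["x", "Estimate"], intercept = ct["(Intercept)", "Estimate"],
      p_value = ct["x", "Pr(>|t|)"], t_value = ct["x", "t value"],
      df = nrow(data) - 2, alpha = alpha,
      asymmetry = ct["x", "Pr(>|t|)"] < alpha,
      ess = ess, ln_dor = ln_dor, inv_sqrt_ess = x
    ),
    class = "deeks_test"
  )
}

#' @export
print.deeks_test <- function(x, ...) {
  cat("Deeks' funnel-plot asymmetry test\n")
  cat(sprintf("  slope = %.3f, t = %.3f on %d df, p = %.3f\n",
              x$slope, x$t_value, x$df, x$p_value))
  cat(sprintf("  %s at alpha = %.2f\n",
              if (x$asymmetry) "asymmetry flagged" else "no significant asymmetry", x$alpha))
  invisible(x)
}

#' Classify a measurement against rule-out / rule-in thresholds
#'
#' Three-tier zone classification: values at or below the rule-out bound are
#' `"rule-out"`, values at or above the rule-in bound are `"rule-in"`, and
#' values strictly between are `"gray"` (both bounds are inclusive towards
#' their own zone).
#'
#' @param value positive measurement(s), ng/mL.
#' @param thresholds a [threshold_report()] object, or a list/vector with
#'   elements `rule_out_cutoff` and `rule_in_cutoff`.
#' @return Factor with levels `rule-out`, `gray`, `rule-in`.
#' @examples
#' classify_measurement(c(25, 35, 50),
#'                      list(rule_out_cutoff = 30.1, rule_in_cutoff = 41.3))
#' @export
classify_measurement <- function(value, thresholds) {
  lo <- thresholds[["rule_out_cutoff"]]
  hi <- thresholds[["rule_in_cutoff"]]
  if (is.null(lo) || is.null(hi) || is.na(lo) || is.na(hi) || !(lo < hi)) {
    stop_dta("thresholds must satisfy rule_out_cutoff < rule_in_cutoff", "dta_config_error")
  }
  if (any(value <= 0)) stop_dta("measurements must be > 0", "dta_domain_error")
  zone <- ifelse(value <= lo, "rule-out", ifelse(value >= hi, "rule-in", "gray"))
  factor(zone, levels = c("rule-out", "gray", "rule-in"))
}
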