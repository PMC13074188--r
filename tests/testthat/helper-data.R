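# Small fixed datasets used across tests (built in code, no fixtures on disk).

toy_data <- function() {
  as_dta_data(data.frame(
    study_id = paste0("s", 1:4),
    tp = c(90, 80, 70, 95), fp = c(15, 10, 20, 5),
    fn = c(10, 20, 30, 5), tn = c(85, 90, 80, 95),
    cutoff = c(20, 30, 45, 60),
    stringsAsFactors = FALSE
  ))
}

# k identical studies sharing one 2x2 table (zero between-study variance).
identical_data <- function(k = 4, tp = 80, fp = 12, fn = 20, tn = 88) {
  as_dta_data(data.frame(
    study_id = paste0("s", seq_len(k)),
    tp = tp, fp = fp, fn = fn, tn = tn,
    stringsAsFactors = FALSE
  ))
}

# Counts lying (up to 1/n granularity) exactly on two log-linear accuracy
# lines; n large so granularity error is ~1e-8 on the proportion scale.
exact_line_data <- function(a_d = -6.6, b_d = 1.4, a_nd = -3.0, b_nd = 1.4,
                            cutoffs = c(15, 25, 40, 65, 90), n = 1e8) {
  q <- plogis(a_d + b_d * log(cutoffs))    # P(test neg | diseased) = 1 - sens
  s <- plogis(a_nd + b_nd * log(cutoffs))  # specificity
  fn <- round(q * n); tn <- round(s * n)
  as_dta_data(data.frame(
    study_id = paste0("s", seq_along(cutoffs)),
    tp = n - fn, fp = n - tn, fn = fn, tn = tn, cutoff = cutoffs,
    stringsAsFactors = FALSE
  ))
}
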