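## Study-level data model: one row per study with 2x2 counts, an optional
## positivity cutoff (ng/mL) and optional categorical covariates.

REQUIRED_COLS <- c("study_id", "tp", "fp", "fn", "tn")

#' Validate a study-level diagnostic accuracy table
#'
#' Coerces a data frame of per-study 2x2 counts into a validated `dta_data`
#' object. Each row is one study with counts of true positives (`tp`), false
#' positives (`fp`), false negatives (`fn`) and true negatives (`tn`), an
#' optional positive biomarker `cutoff` (ng/mL; `NA` allowed) and any number of
#' additional categorical covariate columns (e.g. pathology, design, assay,
#' reference standard).
#'
#' Validation enforces: unique study identifiers, non-negative integer counts,
#' at least one diseased (`tp + fn >= 1`) and one non-diseased (`fp + tn >= 1`)
#' subject per study, and strictly positive cutoffs where present.
#'
#' @param x data frame with columns `study_id`, `tp`, `fp`, `fn`, `tn` and
#'   optionally `cutoff` plus covariates.
#' @param provenance free-text note on where the counts came from.
#' @return A `dta_data` object (a data frame).
#' @examples
#' d <- as_dta_data(data.frame(
#'   study_id = c("a", "b"), tp = c(40, 60), fp = c(5, 10),
#'   fn = c(8, 12), tn = c(45, 70)
#' ))
#' nrow(d)
#' @export
as_dta_data <- function(x, provenance = "user-supplied") {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  missing_cols <- setdiff(REQUIRED_COLS, names(x))
  if (length(missing_cols) > 0) {
    stop_dta(
      sprintf("missing required column(s): %s", paste(missing_cols, collapse = ", ")),
      "dta_schema_error"
    )
  }
  x$study_id <- as.character(x$study_id)
  if (anyDuplicated(x$study_id)) {
    dup <- unique(x$study_id[duplicated(x$study_id)])
    stop_dta(
      sprintf("duplicate study_id value(s): %s", paste(dup, collapse = ", ")),
      "dta_validation_error"
    )
  }
  for (cc in c("tp", "fp", "fn", "tn")) {
    v <- x[[cc]]
    if (!is.numeric(v) || anyNA(v)) {
      stop_dta(sprintf("column '%s' must be numeric with no missing values", cc),
               "dta_parse_error")
    }
    if (any(v < 0) || any(v != round(v))) {
      bad <- x$study_id[v < 0 | v != round(v)][1]
      stop_dta(
        sprintf("column '%s' must hold non-negative integers (offending study: %s)",
                cc, bad),
        "dta_validation_error"
      )
    }
    x[[cc]] <- as.integer(round(v))
  }
  if (any(x$tp + x$fn < 1) || any(x$fp + x$tn < 1)) {
    stop_dta("every study needs >= 1 diseased (tp+fn) and >= 1 non-diseased (fp+tn) subject",
             "dta_validation_error")
  }
  if ("cutoff" %in% names(x)) {
    co <- x$cutoff
    if (!is.numeric(co)) stop_dta("column 'cutoff' must be numeric", "dta_parse_error")
    if (any(!is.na(co) & co <= 0)) {
      stop_dta("cutoff values must be > 0 where present", "dta_validation_error")
    }
  } else {
    x$cutoff <- NA_real_
  }
  attr(x, "provenance") <- provenance
  class(x) <- c("dta_data", "data.frame")
  x
}

#' Read a study-level table from a delimited text file
#'
#' Reads CSV or TSV (delimiter auto-detected from the header line, or set via
#' `sep`). Header names are matched case-insensitively; alternative column
#' names can be supplied through `col_map`. Any columns beyond the recognised
#' ones are kept as covariates.
#'
#' @param path path to a delimited text file, one row per study.
#' @param col_map optional named character vector mapping canonical names
#'   (`study_id`, `tp`, `fp`, `fn`, `tn`, `cutoff`) to the file's column names,
#'   e.g. `c(study_id = "Study", tp = "TP")`.
#' @param sep field delimiter; `NULL` (default) auto-detects comma vs tab.
#' @return A validated [as_dta_data()] object; row order is preserved.
#' @export
read_studies <- function(path, col_map = NULL, sep = NULL) {
  if (!file.exists(path)) stop_dta(sprintf("file not found: %s", path), "dta_io_error")
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "")
  nm <- names(raw)
  canonical <- c(REQUIRED_COLS, "cutoff")
  for (cn in canonical) {
    target <- if (!is.null(col_map) && cn %in% names(col_map)) col_map[[cn]] else cn
    hit <- which(tolower(nm) == tolower(target))
    if (length(hit) == 1) names(raw)[hit] <- cn
  }
  as_dta_data(raw, provenance = sprintf("read from %s", path))
}

#' Write a study-level table
#'
#' Writes the raw counts back to CSV, bit-exactly reproducing what
#' [read_studies()] read, and optionally a JSON provenance echo of the same
#' records.
#'
#' @param x a `dta_data` object.
#' @param path output CSV path.
#' @param json_path optional path for a JSON echo (counts + provenance).
#' @return `path`, invisibly.
#' @export
write_studies <- function(x, path, json_path = NULL) {
  stopifnot(inherits(x, "dta_data"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(provenance = attr(x, "provenance"), records = as.data.frame(x)),
      json_path, auto_unbox = TRUE, digits = NA, na = "null"
    )
  }
  invisible(path)
}

#' Continuity correction for zero cells
#'
#' Adds a small constant to 2x2 cells so logits and within-study variances are
#' finite. The default convention (mode `"any-zero-all-cells"`, the mainstream
#' choice in diagnostic meta-analysis software) adds `value` to all four cells
#' of any study containing at least one zero cell and leaves other studies
#' untouched. Raw integer counts are never mutated: corrected counts are stored
#' in columns `tp_c`, `fp_c`, `fn_c`, `tn_c` with a logical `corrected` flag.
#'
#' @param x a `dta_data` object.
#' @param value positive constant to add (default 0.5).
#' @param mode correction rule: `"any-zero-all-cells"` (default),
#'   `"only-zero-cells"` (add only to cells that are zero), `"always"` (add to
#'   all cells of all studies) or `"none"`.
#' @return `x` with corrected-count columns appended.
#' @examples
#' d <- as_dta_data(data.frame(study_id = "s", tp = 50, fp = 0, fn = 5, tn = 45))
#' correct_counts(d)[, c("tp_c", "fp_c", "fn_c", "tn_c")]
#' @export
correct_counts <- function(x, value = 0.5,
                           mode = c("any-zero-all-cells", "only-zero-cells",
                                    "always", "none")) {
  stopifnot(inherits(x, "dta_data"))
  mode <- match.arg(mode)
  if (value <= 0) stop_dta("continuity correction value must be > 0", "dta_validation_error")
  cells <- as.matrix(as.data.frame(x)[, c("tp", "fp", "fn", "tn")])
  storage.mode(cells) <- "double"
  has_zero <- apply(cells == 0, 1, any)
  corr <- cells
  if (mode == "any-zero-all-cells") {
    corr[has_zero, ] <- corr[has_zero, , drop = FALSE] + value
    corrected <- has_zero
  } else if (mode == "only-zero-cells") {
    corr[cells == 0] <- value
    corrected <- has_zero
  } else if (mode == "always") {
    corr <- corr + value
    corrected <- rep(TRUE, nrow(cells))
  } else {
    corrected <- rep(FALSE, nrow(cells))
  }
  x$tp_c <- corr[, "tp"]; x$fp_c <- corr[, "fp"]
  x$fn_c <- corr[, "fn"]; x$tn_c <- corr[, "tn"]
  x$corrected <- corrected
  x
}

#' Logit-scale transformation of study-level accuracy
#'
#' Computes, for each study, the empirical logit of sensitivity
#' (`y1 = logit(tp/(tp+fn))`) and of the false-positive rate
#' (`y2 = logit(fp/(fp+tn))`) together with their delta-method within-study
#' variances `v1 = 1/tp + 1/fn` and `v2 = 1/fp + 1/tn`, on continuity-corrected
#' counts. These are the inputs of the bivariate random-effects model.
#'
#' @param x a `dta_data` object.
#' @param value,mode continuity-correction settings passed to
#'   [correct_counts()]; columns `tp_c` etc. are reused if already present.
#' @return Data frame with columns `study_id`, `y1`, `y2`, `v1`, `v2`,
#'   `n_diseased`, `n_nondiseased`, `sens`, `spec`, `corrected`.
#' @examples
#' d <- as_dta_data(data.frame(study_id = "s", tp = 90, fp = 15, fn = 10, tn = 85))
#' logit_transform(d)
#' @export
logit_transform <- function(x, value = 0.5, mode = "any-zero-all-cells") {
  stopifnot(inherits(x, "dta_data"))
  if (!all(c("tp_c", "fp_c", "fn_c", "tn_c") %in% names(x))) {
    x <- correct_counts(x, value = value, mode = mode)
  }
  if (any(x$tp_c <= 0 | x$fp_c <= 0 | x$fn_c <= 0 | x$tn_c <= 0)) {
    stop_dta(paste0("zero effective cell after correction mode '", mode,
                    "'; sensitivity or specificity is degenerate"),
             "dta_degenerate_error")
  }
  sens <- x$tp_c / (x$tp_c + x$fn_c)
  fpr <- x$fp_c / (x$fp_c + x$tn_c)
  out <- data.frame(
    study_id = x$study_id,
    y1 = logit(sens),
    y2 = logit(fpr),
    v1 = 1 / x$tp_c + 1 / x$fn_c,
    v2 = 1 / x$fp_c + 1 / x$tn_c,
    n_diseased = x$tp + x$fn,
    n_nondiseased = x$fp + x$tn,
    sens = sens,
    spec = 1 - fpr,
    corrected = x$corrected,
    stringsAsFactors = FALSE
  )
  out
}

#' @export
print.dta_data <- function(x, ...) {
  cat(sprintf("Study-level diagnostic accuracy data: %d studies, %d diseased / %d non-diseased\n",
              nrow(x), sum(x$tp + x$fn), sum(x$fp + x$tn)))
  cat(sprintf("Provenance: %s\n", attr(x, "provenance") %||% "unknown"))
  print(as.data.frame(x), ...)
  invisible(x)
}
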