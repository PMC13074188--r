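## End-to-end pipeline: io -> bivariate -> SROC -> subgroups/metaregression ->
## clinical utility -> cutoff model, assembled into a machine-readable bundle.

#' Run the full diagnostic meta-analysis pipeline
#'
#' Executes every analysis stage on a study-level table and (optionally) writes
#' a results bundle: `results.json` with all parameters, seeds and unrounded
#' values, and `subgroups.csv` with one row per subgroup level. Stages that
#' cannot run (e.g. the cutoff model on a dataset without cutoffs, or subgroup
#' variables that are absent) are skipped with a reason in the manifest rather
#' than failing the run. Reruns with the same inputs and seeds reproduce every
#' number exactly.
#'
#' @param input a `dta_data` object, a path to a delimited study table, or a
#'   [sim_config()] object (which is simulated first).
#' @param out_dir optional output directory (created if needed); `NULL` skips
#'   writing.
#' @param subgroup_vars character vector of covariate columns to use for
#'   subgroup fits and metaregression (defaults to all non-core columns).
#' @param mc_draws Monte-Carlo draws for LR/DOR intervals.
#' @param mc_seed,boot_seed seeds for the Monte-Carlo CI draws and the
#'   bootstrap.
#' @param B bootstrap replicates for the Youden cutoff interval.
#' @param lr_pos_target,lr_neg_target decision-threshold targets.
#' @param pretests Fagan pretest probabilities.
#' @return A `dta_pipeline` list with elements `data`, `fit`, `summary`,
#'   `sroc`, `subgroups`, `metareg`, `fagan`, `deeks`, `cutpoints`,
#'   `thresholds`, `manifest` (per-stage status) and `config`.
#' @export
run_pipeline <- function(input, out_dir = NULL, subgroup_vars = NULL,
                         mc_draws = 100000L, mc_seed = 1L, boot_seed = 1L,
                         B = 1000L, lr_pos_target = 10, lr_neg_target = 0.1,
                         pretests = c(0.25, 0.50, 0.75)) {
  config <- list(mc_draws = mc_draws, mc_seed = mc_seed, boot_seed = boot_seed,
                 B = B, lr_pos_target = lr_pos_target,
                 lr_neg_target = lr_neg_target, pretests = pretests)
  sim_truth <- NULL
  if (inherits(input, "sim_config")) {
    sim <- simulate_studies(input)
    data <- sim$data
    sim_truth <- sim$truth
    config$sim_seed <- input$seed
  } else if (is.character(input)) {
    data <- read_studies(input)
  } else {
    stopifnot(inherits(input, "dta_data"))
    data <- input
  }
  manifest <- list()
  note <- function(stage, status, reason = NULL) {
    manifest[[stage]] <<- list(status = status, reason = reason)
  }

  fit <- dta_bivariate(data)
  note("bivariate", "ok")
  summ <- pooled_summary(fit, mc_draws = mc_draws, seed = mc_seed)
  note("summary", "ok")
  sroc <- list(curve = sroc_curve(fit),
               summary_point = c(fpr = unname(expit(fit$mu[2])),
                                 tpr = unname(expit(fit$mu[1]))),
               confidence = confidence_region(fit),
               prediction = prediction_region(fit))
  note("sroc", "ok")

  core <- c(REQUIRED_COLS, "cutoff", "tp_c", "fp_c", "fn_c", "tn_c", "corrected")
  if (is.null(subgroup_vars)) subgroup_vars <- setdiff(names(data), core)
  subgroups <- list(); metareg <- list()
  for (v in subgroup_vars) {
    if (!v %in% names(data)) {
      note(paste0("subgroup:", v), "skipped", "variable not present")
      next
    }
    subgroups[[v]] <- dta_subgroups(data, v, mc_draws = mc_draws, seed = mc_seed)
    lv <- unique(as.character(data[[v]]))
    if (length(lv[!is.na(lv)]) >= 2) {
      metareg[[v]] <- dta_metareg(data, v)
    } else {
      note(paste0("metareg:", v), "skipped", "single level")
    }
  }
  if (length(subgroup_vars)) note("subgroups", "ok")

  fagan <- fagan_table(summ, pretests = pretests)
  deeks <- deeks_test(data)
  note("clinical_utility", "ok")

  cutpoints <- thresholds <- NULL
  if (sum(!is.na(data$cutoff)) >= 3) {
    cutpoints <- dta_cutpoints(data)
    thresholds <- threshold_report(cutpoints, data, B = B, seed = boot_seed,
                                   lr_pos_target = lr_pos_target,
                                   lr_neg_target = lr_neg_target)
    note("cutpoints", "ok")
  } else {
    note("cutpoints", "skipped", "fewer than 3 studies report a cutoff")
  }

  bundle <- structure(
    list(data = data, fit = fit, summary = summ, sroc = sroc,
         subgroups = subgroups, metareg = metareg, fagan = fagan,
         deeks = deeks, cutpoints = cutpoints, thresholds = thresholds,
         sim_truth = sim_truth, manifest = manifest, config = config),
    class = "dta_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline(bundle, out_dir)
  bundle
}

pipeline_results_list <- function(x) {
  s <- x$summary
  res <- list(
    package_version = as.character(utils::packageVersion("dtathresh")),
    config = x$config,
    k = x$fit$k,
    pooled = list(
      sensitivity = s$sensitivity, sensitivity_ci = s$sensitivity_ci,
      specificity = s$specificity, specificity_ci = s$specificity_ci,
      lr_pos = s$lr_pos, lr_pos_ci = s$lr_pos_ci,
      lr_neg = s$lr_neg, lr_neg_ci = s$lr_neg_ci,
      dor = s$dor, dor_ci = s$dor_ci,
      i2_sens = s$i2_sens, i2_spec = s$i2_spec,
      q_sens = s$q_sens, q_spec = s$q_spec,
      threshold_correlation = s$threshold_correlation,
      mc_draws = s$mc_draws, mc_seed = s$seed
    ),
    model = list(mu = unname(x$fit$mu), tau = unname(x$fit$tau),
                 rho = x$fit$rho, loglik = x$fit$loglik, method = x$fit$method),
    metareg = lapply(x$metareg, function(m) {
      list(lrt = m$lrt, df = m$df, p_value = m$p_value)
    }),
    fagan = as.data.frame(x$fagan),
    deeks = list(slope = x$deeks$slope, p_value = x$deeks$p_value,
                 asymmetry = x$deeks$asymmetry, alpha = x$deeks$alpha),
    manifest = x$manifest
  )
  if (!is.null(x$thresholds)) {
    t <- x$thresholds
    res$thresholds <- list(
      youden_cutoff = t$youden_cutoff, youden_value = t$youden_value,
      sens_at_opt = t$sens_at_opt, spec_at_opt = t$spec_at_opt,
      bootstrap_ci = t$bootstrap_ci,
      bootstrap_B = t$bootstrap$B, bootstrap_seed = t$bootstrap$seed,
      rule_in_cutoff = t$rule_in_cutoff, rule_out_cutoff = t$rule_out_cutoff,
      transform = t$transform, all_aics = as.list(x$cutpoints$all_aics)
    )
  }
  res
}

write_pipeline <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(pipeline_results_list(x),
                       file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  if (length(x$subgroups)) {
    tabs <- lapply(names(x$subgroups), function(v) {
      cbind(variable = v, as.data.frame(x$subgroups[[v]]))
    })
    utils::write.csv(do.call(rbind, tabs), file.path(out_dir, "subgroups.csv"),
                     row.names = FALSE)
  }
  write_studies(x$data, file.path(out_dir, "studies.csv"))
  invisible(out_dir)
}

#' @export
print.dta_pipeline <- function(x, ...) {
  cat("Diagnostic accuracy meta-analysis pipeline\n\n")
  print(x$summary)
  cat("\n")
  print(x$deeks)
  if (!is.null(x$thresholds)) { cat("\n"); print(x$thresholds) }
  skipped <- Filter(function(m) m$status == "skipped", x$manifest)
  if (length(skipped)) {
    cat("\nSkipped stages:\n")
    for (nm in names(skipped)) cat(sprintf("  %s: %s\n", nm, skipped[[nm]]$reason))
  }
  invisible(x)
}

#' Read or write a simulation configuration as YAML/JSON
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @param config a [sim_config()] object (for writing).
#' @return `read_sim_config()` returns a `sim_config`; `write_sim_config()`
#'   returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  lst <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(sim_config, lst)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  lst <- unclass(config)
  lst$cutoffs <- lst$cutoffs %||% NULL
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}
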