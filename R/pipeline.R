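#' Build an analysis configuration
#'
#' Assembles and validates the configuration consumed by
#' [run_pipeline()]. The same structure can be stored as a YAML file
#' (fields with identical names) and loaded with [load_config()].
#'
#' @param exposures List of exposure sources, each a list with `path`,
#'   `cancer_type`, `smoking_related`.
#' @param outcome Path to the outcome summary-statistics file (IGAP
#'   datafile layout, see [read_outcome_table()]).
#' @param out_dir Output directory for the report bundle.
#' @param ld Optional path to an LD r-squared matrix.
#' @param proxies Optional path to a proxy candidate table.
#' @param p_threshold Genome-wide significance threshold. Default 5e-8.
#' @param r2_prune LD pruning threshold. Default 0.2.
#' @param r2_proxy Minimum proxy LD. Default 0.9.
#' @param priors Prior grid for the false-discovery assessment.
#' @param bfdr_method `"bfdp"` or `"fprp"`.
#' @param drop_palindromic Drop A/T and C/G instruments at harmonization.
#' @param dedupe De-duplicate cross-cancer rsIDs within pooled groups.
#' @param seed Seed recorded in the run log (the pipeline itself is
#'   deterministic given its inputs).
#' @return An `mr_config` list.
#' @export
mr_config <- function(exposures, outcome, out_dir, ld = NULL, proxies = NULL,
                      p_threshold = 5e-8, r2_prune = 0.2, r2_proxy = 0.9,
                      priors = c(0.5, 0.1, 0.01, 0.001),
                      bfdr_method = "bfdp", drop_palindromic = FALSE,
                      dedupe = FALSE, seed = NULL) {
  stopifnot(is.list(exposures), length(exposures) >= 1L)
  for (e in exposures) {
    if (is.null(e$path) || is.null(e$cancer_type) || is.null(e$smoking_related)) {
      stop("each exposure needs 'path', 'cancer_type' and 'smoking_related'",
           call. = FALSE)
    }
  }
  for (thr in c(p_threshold = p_threshold, r2_prune = r2_prune,
                r2_proxy = r2_proxy)) {
    if (!is.numeric(thr) || thr <= 0 || thr > 1) {
      stop("thresholds must lie in (0, 1]", call. = FALSE)
    }
  }
  structure(list(exposures = exposures, outcome = outcome, out_dir = out_dir,
                 ld = ld, proxies = proxies, p_threshold = p_threshold,
                 r2_prune = r2_prune, r2_proxy = r2_proxy, priors = priors,
                 bfdr_method = bfdr_method,
                 drop_palindromic = isTRUE(drop_palindromic),
                 dedupe = isTRUE(dedupe), seed = seed),
            class = "mr_config")
}

#' Load an analysis configuration from a YAML file
#'
#' @param path Path to a YAML file whose fields mirror [mr_config()]'s
#'   arguments.
#' @return An `mr_config` list.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw), names(formals(mr_config)))]
  do.call(mr_config, args)
}

format_pvalue <- function(p) {
  ifelse(p < 1e-3, toupper(formatC(p, format = "e", digits = 1)),
         formatC(signif(p, 3), format = "fg"))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("in stage '%s': %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full Mendelian randomization pipeline
#'
#' Executes instrument selection, harmonization, pooled per-group MR,
#' sensitivity analyses and Bayesian false-discovery assessment from a
#' single configuration, writing a machine-readable report bundle:
#' `results.tsv` (per-group odds ratios, confidence limits, p-values and
#' false-discovery columns, full precision), `results_formatted.tsv`
#' (odds ratios and limits at 2 decimals, p-values at 3 significant
#' figures or scientific notation below 1e-3, false-discovery values as
#' percentages at 2 decimals), `sensitivity.tsv` (Egger intercept test
#' and Cochran's Q per group), `harmonized.tsv`, `leave_one_out.tsv`,
#' `funnel.tsv`, `selection_report.json`, and `run_log.txt` (package
#' version, seed, thresholds, per-stage record counts). Outputs contain
#' no timestamps, so a rerun on identical inputs is byte-identical. A
#' configuration whose instruments have no outcome overlap produces empty
#' results with an explicit diagnostic rather than an error; a stage
#' failure leaves a `FAILED` marker naming the stage next to any outputs
#' already written.
#'
#' @param config An [mr_config()] list, or the path to a YAML file for
#'   [load_config()].
#' @return Invisibly, a list with `results`, `bfdr`, `sensitivity`,
#'   `harmonized`, `loo`, `funnel`, `selection`, and `diagnostics`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "mr_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("mrivw version: %s",
                         as.character(utils::packageVersion("mrivw"))),
                 sprintf("seed: %s", if (is.null(config$seed)) "none" else config$seed),
                 sprintf("p_threshold: %g", config$p_threshold),
                 sprintf("r2_prune: %g", config$r2_prune),
                 sprintf("r2_proxy: %g", config$r2_proxy),
                 sprintf("bfdr_method: %s", config$bfdr_method),
                 sprintf("priors: %s", paste(config$priors, collapse = ", ")),
                 sprintf("drop_palindromic: %s", config$drop_palindromic),
                 sprintf("dedupe: %s", config$dedupe))
  fail <- function(stage_name, e) {
    writeLines(c(sprintf("stage: %s", stage_name), conditionMessage(e)),
               file.path(config$out_dir, "FAILED"))
    stop(e)
  }

  outcome <- tryCatch(
    stage("read outcome", read_outcome_table(config$outcome)),
    error = function(e) fail("read outcome", e))
  ld <- if (!is.null(config$ld))
    tryCatch(stage("read LD matrix", read_ld_matrix(config$ld)),
             error = function(e) fail("read LD matrix", e)) else NULL
  proxies <- if (!is.null(config$proxies))
    tryCatch(stage("read proxies", read_proxy_table(config$proxies)),
             error = function(e) fail("read proxies", e)) else NULL

  harmonized <- list()
  selection <- list()
  dropped <- list()
  for (e in config$exposures) {
    ct <- e$cancer_type
    res <- tryCatch(stage(sprintf("selection [%s]", ct), {
      tab <- read_instrument_table(e$path, ct, e$smoking_related)
      select_instruments(tab, outcome$rsid, ld = ld, proxies = proxies,
                         p_threshold = config$p_threshold,
                         r2_prune = config$r2_prune,
                         r2_proxy = config$r2_proxy)
    }), error = function(err) fail(sprintf("selection [%s]", ct), err))
    selection[[ct]] <- res$report
    if (nrow(res$table) == 0L) next
    h <- tryCatch(stage(sprintf("harmonization [%s]", ct),
                        suppressWarnings(harmonize(res$table, outcome,
                                   drop_palindromic = config$drop_palindromic))),
                  error = function(err) fail(sprintf("harmonization [%s]", ct), err))
    dropped[[ct]] <- attr(h, "dropped")
    if (nrow(h)) harmonized[[ct]] <- h
    log_lines <- c(log_lines,
                   sprintf("%s: %d candidates, %d selected, %d harmonized",
                           ct, length(res$report$kept) +
                             length(res$report$dropped_significance) +
                             length(res$report$dropped_ld) +
                             length(res$report$proxied) +
                             length(res$report$dropped_no_proxy),
                           nrow(res$table), nrow(h)))
  }

  diagnostics <- character(0)
  if (length(harmonized) == 0L) {
    diagnostics <- "no instruments could be harmonized with the outcome data"
    log_lines <- c(log_lines, paste("DIAGNOSTIC:", diagnostics))
    h_all <- harmonize(new_instrument_table(
      data.frame(rsid = character(0), effect_allele = character(0),
                 other_allele = character(0), beta = numeric(0),
                 se = numeric(0), pvalue = numeric(0)),
      character(0), logical(0)), outcome)
    results <- pool_groups(h_all[0, ], "all")[0, ]
    bfdr <- bfdr_table(data.frame(group = "none", theta_ivw = 0, se_ivw = 1,
                                  pvalue = 1), config$priors,
                       config$bfdr_method)[0, ]
    sens <- sensitivity_table(h_all[0, ])
    loo_all <- funnel_all <- NULL
  } else {
    h_all <- do.call(rbind, c(harmonized, list(make.row.names = FALSE)))
    class(h_all) <- c("harmonized_instruments", "data.frame")
    results <- stage("mr", mr_table(h_all, dedupe = config$dedupe))
    bfdr <- stage("bfdr", bfdr_table(results, config$priors,
                                     config$bfdr_method))
    sens <- stage("sensitivity", sensitivity_table(h_all))
    per_group <- c(group_subsets(h_all, "per-cancer"),
                   group_subsets(h_all, "smoking"),
                   group_subsets(h_all, "non-smoking"),
                   group_subsets(h_all, "all"))
    loo_all <- list(); funnel_all <- list()
    for (label in names(per_group)) {
      hg <- per_group[[label]]
      if (nrow(hg) >= 3L) {
        loo_all[[label]] <- cbind(group = label, leave_one_out(hg))
      }
      if (nrow(hg) >= 2L) {
        r <- wald_ratios(hg)
        funnel_all[[label]] <- cbind(group = label, funnel_data(r))
      }
    }
    loo_all <- do.call(rbind, loo_all)
    funnel_all <- do.call(rbind, funnel_all)
  }

  results_bfdr <- if (nrow(results)) {
    cbind(results, bfdr[match(results$group, bfdr$group),
                        setdiff(names(bfdr), c("group", "method")),
                        drop = FALSE])
  } else results

  out <- config$out_dir
  utils::write.table(results_bfdr, file.path(out, "results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fmt <- results_bfdr
  if (nrow(fmt)) {
    for (col in c("odds_ratio", "ci_low", "ci_high")) {
      fmt[[col]] <- formatC(fmt[[col]], format = "f", digits = 2)
    }
    fmt$pvalue <- format_pvalue(fmt$pvalue)
    fmt$q_pvalue <- format_pvalue(fmt$q_pvalue)
    for (col in grep("^bfdr_", names(fmt), value = TRUE)) {
      fmt[[col]] <- formatC(100 * fmt[[col]], format = "f", digits = 2)
    }
  }
  utils::write.table(fmt, file.path(out, "results_formatted.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sens, file.path(out, "sensitivity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(harmonized)) {
    write_harmonized(h_all, file.path(out, "harmonized.tsv"))
  }
  if (!is.null(loo_all)) {
    utils::write.table(loo_all, file.path(out, "leave_one_out.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(funnel_all)) {
    utils::write.table(funnel_all, file.path(out, "funnel.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  sel_json <- lapply(selection, function(r)
    list(kept = r$kept, dropped_significance = r$dropped_significance,
         dropped_ld = as.list(r$dropped_ld), proxied = as.list(r$proxied),
         dropped_no_proxy = r$dropped_no_proxy))
  writeLines(jsonlite::toJSON(sel_json, auto_unbox = FALSE, pretty = TRUE),
             file.path(out, "selection_report.json"))
  writeLines(log_lines, file.path(out, "run_log.txt"))

  invisible(list(results = results_bfdr, bfdr = bfdr, sensitivity = sens,
                 harmonized = if (length(harmonized)) h_all else NULL,
                 loo = loo_all, funnel = funnel_all, selection = selection,
                 diagnostics = diagnostics))
}
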