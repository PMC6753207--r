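#' Filter instruments at genome-wide significance
#'
#' Retains exactly the rows whose exposure association p-value is strictly
#' below the threshold (the conventional genome-wide significance level,
#' \eqn{p < 5 \times 10^{-8}}, by default). A row at exactly the threshold
#' is dropped. Row order is preserved; an empty result is allowed.
#'
#' @param table An `instrument_table`.
#' @param threshold Significance threshold (strict `<`).
#' @return The filtered `instrument_table`.
#' @export
filter_significant <- function(table, threshold = 5e-8) {
  stopifnot(is.data.frame(table), is.numeric(threshold), threshold > 0)
  out <- table[table$pvalue < threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy LD pruning with lead-SNP retention
#'
#' Enforces instrument independence: variants are visited in order of
#' ascending exposure p-value (ties broken by rsID) and each accepted lead
#' SNP discards every remaining variant whose pairwise \eqn{r^2} with it
#' meets or exceeds `r2_max`. No retained pair has \eqn{r^2 \ge}
#' `r2_max`, and among variants in LD the one with the lowest association
#' p-value is always the one retained. The result is invariant to the
#' input row order; kept rows are returned in (p-value, rsID) order.
#'
#' @param table An `instrument_table`; every rsID must appear in `ld`.
#' @param ld An `ld_matrix` of pairwise squared correlations.
#' @param r2_max Pruning threshold; pairs with \eqn{r^2 \ge} this value
#'   cannot both be retained. Default 0.2.
#' @return A list with elements `table` (the pruned `instrument_table`) and
#'   `report` (list: `kept` rsIDs; `dropped_ld`, a named character vector
#'   mapping each discarded rsID to the lead SNP that displaced it).
#' @export
ld_prune <- function(table, ld, r2_max = 0.2) {
  stopifnot(is.data.frame(table), is.matrix(ld))
  missing <- setdiff(table$rsid, rownames(ld))
  if (length(missing)) {
    stop(sprintf("rsid '%s' absent from the LD matrix", missing[1]), call. = FALSE)
  }
  ord <- order(table$pvalue, table$rsid)
  tab <- table[ord, , drop = FALSE]
  n <- nrow(tab)
  status <- rep("pending", n)
  lead_of <- character(n)
  for (i in seq_len(n)) {
    if (status[i] != "pending") next
    status[i] <- "kept"
    if (i < n) {
      later <- which(status == "pending")
      r2 <- ld[tab$rsid[i], tab$rsid[later]]
      hit <- later[r2 >= r2_max]
      status[hit] <- "dropped"
      lead_of[hit] <- tab$rsid[i]
    }
  }
  kept <- status == "kept"
  dropped_ld <- stats::setNames(lead_of[!kept], tab$rsid[!kept])
  out <- tab[kept, , drop = FALSE]
  rownames(out) <- NULL
  list(table = out,
       report = list(kept = tab$rsid[kept], dropped_ld = dropped_ld))
}

# Allele map for one target/proxy pair as a named vector target -> proxy.
proxy_allele_map <- function(rows) {
  if (nrow(rows) != 2L ||
      anyDuplicated(rows$target_allele) || anyDuplicated(rows$proxy_allele)) {
    stop(sprintf("allele map for %s -> %s is not a bijection over two alleles",
                 rows$target_rsid[1], rows$proxy_rsid[1]), call. = FALSE)
  }
  stats::setNames(rows$proxy_allele, rows$target_allele)
}

#' Substitute proxy SNPs for instruments missing from the outcome data
#'
#' Instruments already present in the outcome dataset pass through
#' untouched. An absent instrument is replaced by its highest-\eqn{r^2}
#' proxy candidate with \eqn{r^2} strictly greater than `r2_min` (default
#' 0.9) whose rsID is present in the outcome data; a proxy at exactly the
#' threshold is not used. The proxy inherits the target's exposure beta,
#' standard error and p-value unchanged, while its effect and other
#' alleles are re-assigned through the target-to-proxy allele
#' correspondence; the proxy contributes its own outcome-side record
#' downstream. Absent instruments with no qualifying proxy are dropped.
#'
#' @param table An `instrument_table`.
#' @param outcome_rsids Character vector of rsIDs available in the outcome
#'   dataset.
#' @param proxies A `proxy_table` of candidates, or `NULL` for none.
#' @param r2_min Minimum proxy LD (strict `>`). Default 0.9.
#' @return A list with elements `table` (instruments after substitution,
#'   with `proxy_used`/`proxy_for` columns) and `report` (list: `kept`
#'   rsIDs used directly; `proxied`, named vector target -> proxy;
#'   `dropped_no_proxy` rsIDs).
#' @export
substitute_proxies <- function(table, outcome_rsids, proxies = NULL, r2_min = 0.9) {
  stopifnot(is.data.frame(table))
  n <- nrow(table)
  table$proxy_used <- rep(FALSE, n)
  table$proxy_for <- rep(NA_character_, n)
  present <- table$rsid %in% outcome_rsids
  proxied <- character(0)
  dropped <- character(0)
  keep <- present
  for (i in which(!present)) {
    target <- table$rsid[i]
    cand <- if (is.null(proxies)) proxies[0, ] else
      proxies[proxies$target_rsid == target &
              proxies$r2 > r2_min &
              proxies$proxy_rsid %in% outcome_rsids, , drop = FALSE]
    if (is.null(cand) || nrow(cand) == 0L) {
      dropped <- c(dropped, target)
      next
    }
    # highest r2 wins; ties broken by proxy rsid for determinism
    per_proxy <- unique(cand[order(-cand$r2, cand$proxy_rsid),
                             c("target_rsid", "proxy_rsid", "r2")])
    best <- per_proxy$proxy_rsid[1]
    map <- proxy_allele_map(cand[cand$proxy_rsid == best, , drop = FALSE])
    ea <- unname(map[table$effect_allele[i]])
    oa <- unname(map[table$other_allele[i]])
    if (is.na(ea) || is.na(oa)) {
      stop(sprintf("allele map for %s -> %s does not cover alleles %s/%s",
                   target, best, table$effect_allele[i], table$other_allele[i]),
           call. = FALSE)
    }
    table$rsid[i] <- best
    table$effect_allele[i] <- ea
    table$other_allele[i] <- oa
    table$proxy_used[i] <- TRUE
    table$proxy_for[i] <- target
    proxied[target] <- best
    keep[i] <- TRUE
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(table = out,
       report = list(kept = table$rsid[present], proxied = proxied,
                     dropped_no_proxy = dropped))
}

#' Run the full instrument-selection cascade
#'
#' Applies, in order: the genome-wide significance filter
#' ([filter_significant()]), greedy LD pruning ([ld_prune()], if an LD
#' matrix is supplied), and proxy substitution for instruments missing from
#' the outcome dataset ([substitute_proxies()]). The returned report
#' partitions every input rsID into exactly one of five groups.
#'
#' @param table An `instrument_table` of candidate instruments.
#' @param outcome_rsids rsIDs available in the outcome dataset.
#' @param ld Optional `ld_matrix`; `NULL` skips pruning.
#' @param proxies Optional `proxy_table`; `NULL` means no proxy search.
#' @param p_threshold Significance threshold (strict `<`). Default 5e-8.
#' @param r2_prune LD pruning threshold. Default 0.2.
#' @param r2_proxy Minimum proxy LD (strict `>`). Default 0.9.
#' @return A list with `table` (the selected `instrument_table`) and
#'   `report` (a `selection_report`: `kept`, `dropped_significance`,
#'   `dropped_ld`, `proxied`, `dropped_no_proxy`).
#' @export
select_instruments <- function(table, outcome_rsids, ld = NULL, proxies = NULL,
                               p_threshold = 5e-8, r2_prune = 0.2,
                               r2_proxy = 0.9) {
  input_rsids <- table$rsid
  sig <- filter_significant(table, p_threshold)
  dropped_significance <- setdiff(input_rsids, sig$rsid)
  if (!is.null(ld) && nrow(sig)) {
    pruned <- ld_prune(sig, ld, r2_prune)
    dropped_ld <- pruned$report$dropped_ld
    sig <- pruned$table
  } else {
    dropped_ld <- stats::setNames(character(0), character(0))
  }
  sub <- substitute_proxies(sig, outcome_rsids, proxies, r2_proxy)
  report <- structure(
    list(kept = sub$report$kept,
         dropped_significance = dropped_significance,
         dropped_ld = dropped_ld,
         proxied = sub$report$proxied,
         dropped_no_proxy = sub$report$dropped_no_proxy),
    class = "selection_report")
  list(table = sub$table, report = report)
}

#' Serialize a selection report as JSON
#'
#' @param report A `selection_report` from [select_instruments()].
#' @param path Optional path; when given the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
selection_report_json <- function(report, path = NULL) {
  json <- jsonlite::toJSON(
    list(kept = report$kept,
         dropped_significance = report$dropped_significance,
         dropped_ld = as.list(report$dropped_ld),
         proxied = as.list(report$proxied),
         dropped_no_proxy = report$dropped_no_proxy),
    auto_unbox = FALSE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Instrument selection report\n")
  cat(sprintf("  kept (direct):          %d\n", length(x$kept)))
  cat(sprintf("  dropped, significance:  %d\n", length(x$dropped_significance)))
  cat(sprintf("  dropped, LD pruning:    %d\n", length(x$dropped_ld)))
  cat(sprintf("  proxied:                %d\n", length(x$proxied)))
  cat(sprintf("  dropped, no proxy:      %d\n", length(x$dropped_no_proxy)))
  invisible(x)
}
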