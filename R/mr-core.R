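# 95% two-sided normal quantile, kept at full precision so confidence
# limits round to published 2-decimal tables correctly.
.z95 <- 1.959964

#' Per-SNP Wald ratio estimates
#'
#' For each harmonized instrument \eqn{j}, computes the Wald ratio
#' \deqn{\hat\theta_j = \hat\beta_{Yj} / \hat\beta_{Xj}} with its
#' first-order variance \deqn{se(\hat\beta_{Yj})^2 / \hat\beta_{Xj}^2,}
#' which uses only the outcome standard error and thereby assumes no
#' measurement error in the exposure association (the NOME assumption,
#' appropriate when the exposure GWAS is large). The inverse-variance
#' weight \eqn{w_j = 1/\mathrm{var}_j} is carried alongside.
#'
#' @param h A `harmonized_instruments` data.frame; every `beta_exposure`
#'   must be nonzero.
#' @return A `ratio_estimates` data.frame: `rsid`, `theta`, `variance`,
#'   `weight`, plus group labels.
#' @export
wald_ratios <- function(h) {
  stopifnot(is.data.frame(h), nrow(h) >= 1L)
  zero <- which(h$beta_exposure == 0)
  if (length(zero)) {
    stop(sprintf("undefined Wald ratio: beta_exposure is 0 for %s",
                 h$rsid[zero[1]]), call. = FALSE)
  }
  variance <- (h$se_outcome / h$beta_exposure)^2
  out <- data.frame(
    rsid = h$rsid,
    theta = h$beta_outcome / h$beta_exposure,
    variance = variance,
    weight = 1 / variance,
    cancer_type = if (is.null(h$cancer_type)) NA_character_ else h$cancer_type,
    smoking_related = if (is.null(h$smoking_related)) NA else h$smoking_related,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ratio_estimates", "data.frame")
  out
}

#' Fixed-effect inverse-variance weighted pooling of Wald ratios
#'
#' Pools per-SNP Wald ratios into the fixed-effect IVW causal estimate
#' \deqn{\hat\theta_{IVW} = \frac{\sum_j w_j \hat\theta_j}{\sum_j w_j},
#' \qquad w_j = \frac{\hat\beta_{Xj}^2}{se(\hat\beta_{Yj})^2},}
#' algebraically identical to
#' \eqn{\sum_j \hat\beta_{Yj}\hat\beta_{Xj} se(\hat\beta_{Yj})^{-2} /
#' \sum_j \hat\beta_{Xj}^2 se(\hat\beta_{Yj})^{-2}} and to the slope of a
#' weighted no-intercept regression of outcome on exposure betas. The
#' standard error is the fixed-effect \eqn{(\sum_j w_j)^{-1/2}}, the
#' p-value comes from the standard-normal two-sided tail, and the odds
#' ratio with its 95% confidence interval is obtained by exponentiating
#' \eqn{\hat\theta_{IVW} \pm 1.959964\, se}. Cochran's Q against the
#' pooled estimate is reported alongside.
#'
#' @param ratios A `ratio_estimates` data.frame with at least 2 rows; a
#'   single-instrument exposure is summarized by its Wald ratio directly
#'   via [wald_ratios()] instead.
#' @param group Label carried into the result row.
#' @return An `mr_result`: one-row data.frame with `group`, `n_snps`,
#'   `theta_ivw`, `se_ivw`, `odds_ratio`, `ci_low`, `ci_high`, `pvalue`,
#'   `q_statistic`, `q_pvalue`.
#' @export
ivw_pool <- function(ratios, group = "all") {
  stopifnot(is.data.frame(ratios))
  if (nrow(ratios) < 2L) {
    stop("at least 2 instruments are required for a pooled IVW estimate; ",
         "use wald_ratios() for a single-instrument summary", call. = FALSE)
  }
  w <- ratios$weight
  if (any(!is.finite(w) | w <= 0)) {
    stop("all inverse-variance weights must be positive and finite", call. = FALSE)
  }
  theta <- sum(w * ratios$theta) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- theta / se
  q <- cochran_q(ratios, theta)
  out <- data.frame(
    group = group,
    n_snps = nrow(ratios),
    theta_ivw = theta,
    se_ivw = se,
    odds_ratio = exp(theta),
    ci_low = exp(theta - .z95 * se),
    ci_high = exp(theta + .z95 * se),
    pvalue = 2 * stats::pnorm(-abs(z)),
    q_statistic = q$q,
    q_pvalue = q$pvalue,
    stringsAsFactors = FALSE)
  class(out) <- c("mr_result", "data.frame")
  out
}

group_subsets <- function(harmonized, grouping) {
  switch(grouping,
    "per-cancer" = {
      types <- unique(harmonized$cancer_type)
      stats::setNames(lapply(types, function(ct)
        harmonized[harmonized$cancer_type == ct, , drop = FALSE]), types)
    },
    "smoking" = list(
      "smoking_related" =
        harmonized[harmonized$smoking_related %in% TRUE, , drop = FALSE]),
    "non-smoking" = list(
      "non_smoking_related" =
        harmonized[harmonized$smoking_related %in% FALSE, , drop = FALSE]),
    "all" = list("all_cancers" = harmonized),
    stop(sprintf("unknown grouping '%s'", grouping), call. = FALSE))
}

#' Pooled MR estimates by cancer grouping
#'
#' Concatenates harmonized instruments across the cancers in each group
#' and produces one fixed-effect IVW result per group. An instrument
#' contributes once per cancer it instruments: cross-cancer duplicate
#' rsIDs stay as distinct rows by default (so group sizes add up across
#' disjoint groupings), with `dedupe = TRUE` keeping only the occurrence
#' with the smallest exposure p-value. Groups with fewer than `min_snps`
#' instruments are skipped with a message — a one-locus exposure cannot
#' support a pooled estimate and enters only aggregate groups.
#'
#' @param harmonized A `harmonized_instruments` data.frame carrying
#'   `cancer_type` and `smoking_related` labels.
#' @param grouping One of `"per-cancer"`, `"smoking"`, `"non-smoking"`,
#'   `"all"`.
#' @param dedupe Drop cross-cancer duplicate rsIDs within a group.
#'   Default `FALSE`.
#' @param min_snps Minimum instruments per reported group. Default 2.
#' @return An `mr_result` data.frame with one row per group.
#' @export
pool_groups <- function(harmonized,
                        grouping = c("per-cancer", "smoking", "non-smoking", "all"),
                        dedupe = FALSE, min_snps = 2L) {
  if (length(grouping) == 1L && !grouping %in%
        c("per-cancer", "smoking", "non-smoking", "all")) {
    stop(sprintf("unknown grouping '%s'", grouping), call. = FALSE)
  }
  grouping <- match.arg(grouping)
  subsets <- group_subsets(harmonized, grouping)
  rows <- list()
  for (label in names(subsets)) {
    h <- subsets[[label]]
    if (dedupe && anyDuplicated(h$rsid)) {
      h <- h[order(h$pvalue_exposure, h$rsid), , drop = FALSE]
      h <- h[!duplicated(h$rsid), , drop = FALSE]
    }
    if (nrow(h) < min_snps) {
      message(sprintf("group '%s' has %d instrument(s); skipping pooled estimate",
                      label, nrow(h)))
      next
    }
    rows[[label]] <- ivw_pool(wald_ratios(h), group = label)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(group = character(0), n_snps = integer(0),
                      theta_ivw = numeric(0), se_ivw = numeric(0),
                      odds_ratio = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), pvalue = numeric(0),
                      q_statistic = numeric(0), q_pvalue = numeric(0))
  }
  rownames(out) <- NULL
  class(out) <- c("mr_result", "data.frame")
  out
}

#' Full MR results table across all groupings
#'
#' Convenience wrapper producing the per-cancer rows followed by the
#' smoking-related, non-smoking-related and all-cancer aggregates — the
#' layout of a standard MR results table (group, number of SNPs, odds
#' ratio, confidence limits, p-value).
#'
#' @inheritParams pool_groups
#' @return An `mr_result` data.frame.
#' @export
mr_table <- function(harmonized, dedupe = FALSE, min_snps = 2L) {
  out <- rbind(
    pool_groups(harmonized, "per-cancer", dedupe, min_snps),
    pool_groups(harmonized, "smoking", dedupe, min_snps),
    pool_groups(harmonized, "non-smoking", dedupe, min_snps),
    pool_groups(harmonized, "all", dedupe, min_snps))
  rownames(out) <- NULL
  class(out) <- c("mr_result", "data.frame")
  out
}
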