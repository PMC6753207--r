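#' MR-Egger regression and directional-pleiotropy intercept test
#'
#' Weighted linear regression of outcome betas on exposure betas *with* an
#' intercept, using first-order weights \eqn{se(\hat\beta_{Yj})^{-2}}.
#' Each instrument is first re-oriented so that its exposure beta is
#' non-negative (the outcome beta's sign flips in tandem) — the orientation
#' under which the intercept is interpretable as the average pleiotropic
#' effect. A nonzero intercept indicates directional (unbalanced
#' horizontal) pleiotropy; if the intercept is not significantly different
#' from 0 there is no evidence against the no-directional-pleiotropy null.
#' Inference uses a Student t reference with \eqn{J - 2} degrees of
#' freedom and the estimated residual scale, matching a weighted
#' least-squares fit summary.
#'
#' @param h A `harmonized_instruments` data.frame with at least 3 rows and
#'   no zero exposure beta.
#' @return An `egger_result`: one-row data.frame with `intercept`,
#'   `intercept_se`, `intercept_pvalue`, `slope`, `slope_se`,
#'   `slope_pvalue`, `n_snps`.
#' @export
egger_regression <- function(h) {
  stopifnot(is.data.frame(h))
  n <- nrow(h)
  if (n < 3L) {
    stop("MR-Egger regression requires at least 3 instruments", call. = FALSE)
  }
  if (any(h$beta_exposure == 0)) {
    stop("beta_exposure must be nonzero for MR-Egger orientation", call. = FALSE)
  }
  s <- sign(h$beta_exposure)
  bx <- abs(h$beta_exposure)
  by <- h$beta_outcome * s
  w <- 1 / h$se_outcome^2

  # closed-form weighted least squares with intercept
  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  swxx <- sum(w * bx^2); swxy <- sum(w * bx * by)
  det <- sw * swxx - swx^2
  if (det <= 0) {
    stop("degenerate design: exposure betas carry no spread", call. = FALSE)
  }
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swy - slope * swx) / sw
  resid <- by - intercept - slope * bx
  sigma2 <- sum(w * resid^2) / (n - 2)
  var_slope <- sigma2 * sw / det
  var_intercept <- sigma2 * swxx / det
  t_int <- intercept / sqrt(var_intercept)
  t_slp <- slope / sqrt(var_slope)
  out <- data.frame(
    intercept = intercept,
    intercept_se = sqrt(var_intercept),
    intercept_pvalue = 2 * stats::pt(-abs(t_int), df = n - 2),
    slope = slope,
    slope_se = sqrt(var_slope),
    slope_pvalue = 2 * stats::pt(-abs(t_slp), df = n - 2),
    n_snps = n,
    stringsAsFactors = FALSE)
  class(out) <- c("egger_result", "data.frame")
  out
}

#' Cochran's Q heterogeneity statistic
#'
#' \deqn{Q = \sum_j w_j (\hat\theta_j - \hat\theta_{IVW})^2} with
#' first-order weights, referred to the upper tail of a chi-square
#' distribution with \eqn{J - 1} degrees of freedom. Q is zero exactly
#' when all ratios coincide and is invariant to instrument ordering.
#'
#' @param ratios A `ratio_estimates` data.frame with at least 2 rows.
#' @param theta_ivw Pooled estimate to measure dispersion against; when
#'   `NULL` the fixed-effect IVW estimate of `ratios` is used.
#' @return List with elements `q` and `pvalue`.
#' @export
cochran_q <- function(ratios, theta_ivw = NULL) {
  stopifnot(is.data.frame(ratios), nrow(ratios) >= 2L)
  w <- ratios$weight
  if (is.null(theta_ivw)) theta_ivw <- sum(w * ratios$theta) / sum(w)
  q <- sum(w * (ratios$theta - theta_ivw)^2)
  list(q = q,
       pvalue = stats::pchisq(q, df = nrow(ratios) - 1L, lower.tail = FALSE))
}

#' Leave-one-out re-estimation
#'
#' Recomputes the pooled fixed-effect IVW estimate \eqn{J} times, omitting
#' each instrument in turn, to reveal single-SNP dominance: if precision
#' and direction are stable across omissions, no individual variant drives
#' the pooled result.
#'
#' @param h A `harmonized_instruments` data.frame with at least 3 rows.
#' @return A `loo_result` data.frame with one row per omitted instrument:
#'   `omitted_rsid`, `theta_ivw_without`, `se_without`,
#'   `odds_ratio_without`, `ci_low`, `ci_high`, `pvalue`.
#' @export
leave_one_out <- function(h) {
  stopifnot(is.data.frame(h))
  if (nrow(h) < 3L) {
    stop("leave-one-out analysis requires at least 3 instruments", call. = FALSE)
  }
  ratios <- wald_ratios(h)
  rows <- lapply(seq_len(nrow(ratios)), function(j) {
    fit <- ivw_pool(ratios[-j, , drop = FALSE], group = "loo")
    data.frame(omitted_rsid = ratios$rsid[j],
               theta_ivw_without = fit$theta_ivw,
               se_without = fit$se_ivw,
               odds_ratio_without = fit$odds_ratio,
               ci_low = fit$ci_low,
               ci_high = fit$ci_high,
               pvalue = fit$pvalue,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("loo_result", "data.frame")
  out
}

#' Funnel-plot data export
#'
#' One row per instrument with the Wald ratio \eqn{\hat\theta_j} on the
#' x-axis and the inverse standard error \eqn{1/\sqrt{\mathrm{var}_j}}
#' (instrument strength) on the y-axis, plus the pooled IVW estimate as
#' the vertical reference. Asymmetry about the reference — equivalently, a
#' correlation between effect size and instrument strength — suggests
#' directional pleiotropy. Rendering is left to the plotting layer.
#'
#' @param ratios A `ratio_estimates` data.frame (at least 1 row).
#' @param theta_ivw Pooled reference; when `NULL` and at least two ratios
#'   are supplied, the fixed-effect IVW estimate is used.
#' @return Data.frame with `rsid`, `theta`, `inverse_se`; the pooled
#'   reference is the `"theta_ivw"` attribute and `theta_ivw` column.
#' @export
funnel_data <- function(ratios, theta_ivw = NULL) {
  stopifnot(is.data.frame(ratios), nrow(ratios) >= 1L)
  if (is.null(theta_ivw)) {
    theta_ivw <- sum(ratios$weight * ratios$theta) / sum(ratios$weight)
  }
  out <- data.frame(rsid = ratios$rsid,
                    theta = ratios$theta,
                    inverse_se = sqrt(ratios$weight),
                    theta_ivw = theta_ivw,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "theta_ivw") <- theta_ivw
  out
}

#' Sensitivity summary per group
#'
#' MR-Egger intercept test and Cochran's Q for each cancer grouping with
#' at least `min_snps` instruments — the columns of a standard
#' directional-pleiotropy summary table (intercept, its standard error and
#' p-value, Q, Q p-value).
#'
#' @param harmonized A `harmonized_instruments` data.frame.
#' @param min_snps Minimum instruments per group (Egger needs 3).
#' @return Data.frame with one row per group.
#' @export
sensitivity_table <- function(harmonized, min_snps = 3L) {
  groups <- c(group_subsets(harmonized, "per-cancer"),
              group_subsets(harmonized, "smoking"),
              group_subsets(harmonized, "non-smoking"),
              group_subsets(harmonized, "all"))
  rows <- list()
  for (label in names(groups)) {
    h <- groups[[label]]
    if (nrow(h) < min_snps) next
    eg <- egger_regression(h)
    q <- cochran_q(wald_ratios(h))
    rows[[label]] <- data.frame(
      group = label, n_snps = nrow(h),
      intercept = eg$intercept, intercept_se = eg$intercept_se,
      intercept_pvalue = eg$intercept_pvalue,
      q_statistic = q$q, q_pvalue = q$pvalue,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(group = character(0), n_snps = integer(0),
                      intercept = numeric(0), intercept_se = numeric(0),
                      intercept_pvalue = numeric(0), q_statistic = numeric(0),
                      q_pvalue = numeric(0))
  }
  rownames(out) <- NULL
  out
}
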