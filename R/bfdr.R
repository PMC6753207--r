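#' Prior variance of the alternative effect from an odds-ratio bound
#'
#' Convenience for choosing the spread `W` of the alternative-hypothesis
#' effect distribution in [bfdp()]: returns the variance of a zero-mean
#' normal prior on the log odds ratio such that 95% of alternative effects
#' fall within `1/or95` to `or95`. The default, OR 1.2, encodes the
#' modest per-unit effects expected of a liability-scale exposure.
#'
#' @param or95 Odds ratio bounding the central 95% of alternative effects.
#' @return The prior variance \eqn{(\log(or95)/1.959964)^2}.
#' @export
alt_prior_variance <- function(or95 = 1.2) {
  stopifnot(is.numeric(or95), or95 > 1)
  (log(or95) / 1.959964)^2
}

#' False-positive report probability (FPRP)
#'
#' Posterior probability that a reported association is a false positive,
#' combining the observed p-value with the study's power and a prior
#' probability that the null hypothesis is false:
#' \deqn{FPRP = \frac{\alpha \pi_0}{\alpha \pi_0 + (power) \pi_1}}
#' with \eqn{\pi_1} = `prior_true`, \eqn{\pi_0 = 1 - \pi_1}, and
#' \eqn{\alpha} the significance level attained — here the observed
#' p-value itself, so each result yields one value per prior. Power is
#' the probability of attaining \eqn{p \le \alpha} under the alternative
#' effect (by default the observed estimate), from two-sided normal tails.
#'
#' @param pvalue Observed two-sided p-value.
#' @param theta Point estimate (log odds ratio).
#' @param se Standard error of `theta` (> 0).
#' @param prior_true Prior probability that the null is false, strictly
#'   inside (0, 1); vectorized.
#' @param alpha_level Significance level \eqn{\alpha}; defaults to the
#'   observed p-value.
#' @param power Optional fixed power overriding the computed one.
#' @return FPRP value(s) in \eqn{[0, 1]}, one per prior.
#' @export
fprp <- function(pvalue, theta, se, prior_true, alpha_level = pvalue,
                 power = NULL) {
  stopifnot(is.numeric(pvalue), pvalue >= 0, pvalue <= 1,
            is.numeric(se), se > 0)
  if (any(prior_true <= 0) || any(prior_true >= 1)) {
    stop("prior_true must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (is.null(power)) {
    z_alpha <- stats::qnorm(1 - alpha_level / 2)
    mu <- theta / se
    power <- stats::pnorm(-z_alpha - mu) + stats::pnorm(mu - z_alpha)
  }
  pi1 <- prior_true
  pi0 <- 1 - prior_true
  alpha_level * pi0 / (alpha_level * pi0 + power * pi1)
}

#' Bayesian false-discovery probability (BFDP)
#'
#' Posterior probability of the null hypothesis from the approximate Bayes
#' factor of a normal estimate against a zero-mean normal alternative with
#' variance `W`:
#' \deqn{BF = \sqrt{\frac{V + W}{V}}
#'   \exp\left(-\frac{z^2}{2}\,\frac{W}{V + W}\right), \qquad
#'   BFDP = \frac{BF \cdot PO}{BF \cdot PO + 1}}
#' with \eqn{V = se^2}, \eqn{z = \theta/se}, and prior odds of the null
#' \eqn{PO = (1 - \pi_1)/\pi_1}. Null-consistent data (\eqn{z = 0}) raise
#' the null's posterior above its prior; as \eqn{W \to 0} the alternative
#' collapses onto the null and the posterior returns to the prior.
#'
#' @param theta Point estimate (log odds ratio).
#' @param se Standard error of `theta` (> 0).
#' @param prior_true Prior probability that the null is false, strictly
#'   inside (0, 1); vectorized.
#' @param W Variance of the effect under the alternative (> 0); see
#'   [alt_prior_variance()].
#' @return BFDP value(s) in \eqn{[0, 1]}, one per prior.
#' @export
bfdp <- function(theta, se, prior_true, W = alt_prior_variance()) {
  stopifnot(is.numeric(se), se > 0)
  if (any(W <= 0)) stop("W must be positive", call. = FALSE)
  if (any(prior_true <= 0) || any(prior_true >= 1)) {
    stop("prior_true must lie strictly inside (0, 1)", call. = FALSE)
  }
  V <- se^2
  z <- theta / se
  log_bf <- 0.5 * log((V + W) / V) - (z^2 / 2) * W / (V + W)
  po <- (1 - prior_true) / prior_true
  # work with log Bayes factor for numerical stability at large |z|
  odds <- exp(log_bf) * po
  odds / (odds + 1)
}

#' Bayesian false-discovery assessment for a table of MR results
#'
#' Computes, for every pooled MR result and irrespective of its
#' statistical significance, the posterior probability that the finding is
#' a false discovery at each prior in the grid (default 50%, 10%, 1%,
#' 0.1% prior probability that the null is false). Values are reported as
#' proportions in \eqn{[0, 1]}; percentage formatting belongs to the
#' reporting layer. For a fixed result the false-discovery probability
#' rises monotonically as the prior belief in a true effect weakens.
#'
#' @param results An `mr_result` data.frame (columns `theta_ivw`,
#'   `se_ivw`, `pvalue`, `group`).
#' @param priors Grid of prior probabilities that the null is false.
#' @param method `"bfdp"` (default) for the approximate-Bayes-factor
#'   posterior, or `"fprp"` for the power-based false-positive report
#'   probability.
#' @param W Alternative-effect variance for `method = "bfdp"`.
#' @return Data.frame with one row per result group and one `bfdr_*`
#'   column per prior, plus a `method` column.
#' @export
bfdr_table <- function(results, priors = c(0.5, 0.1, 0.01, 0.001),
                       method = c("bfdp", "fprp"), W = alt_prior_variance()) {
  method <- match.arg(method)
  stopifnot(is.data.frame(results), nrow(results) >= 1L)
  vals <- vapply(seq_len(nrow(results)), function(i) {
    switch(method,
      bfdp = bfdp(results$theta_ivw[i], results$se_ivw[i], priors, W),
      fprp = fprp(results$pvalue[i], results$theta_ivw[i], results$se_ivw[i],
                  priors))
  }, numeric(length(priors)))
  vals <- matrix(vals, ncol = length(priors), byrow = TRUE)
  colnames(vals) <- paste0("bfdr_", sub("\\.?0+$", "",
                                        formatC(100 * priors, format = "f",
                                                digits = 4)))
  out <- data.frame(group = results$group, method = method, vals,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}
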