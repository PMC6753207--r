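#' Define a synthetic two-sample MR scenario
#'
#' Bundles the generative parameters for [simulate_two_sample()]: the
#' number of instruments, the true causal log-odds effect, dispersion of
#' exposure effects, standard-error scales for the two studies, and the
#' horizontal-pleiotropy regime. Under the default NOME setting the
#' observed exposure betas equal their true values, mirroring the
#' assumption behind first-order IVW weights; switching it off adds
#' exposure-side sampling noise and demonstrates weak-instrument
#' attenuation towards the null.
#'
#' @param n_snps Number of instruments J (>= 1).
#' @param theta_true True causal effect on the log-odds scale.
#' @param beta_x_scale Standard deviation of true exposure log-odds
#'   effects (default 0.15, the scale of GWAS lead-SNP effects on cancer
#'   susceptibility).
#' @param beta_x_floor Minimum exposure-effect magnitude (default 0.01);
#'   Wald ratios require nonzero exposure betas.
#' @param se_x Exposure standard-error scale (default 0.015, a large
#'   exposure GWAS).
#' @param se_y Outcome standard-error scale (default 0.02, the order of
#'   the IGAP meta-analysis for common variants).
#' @param pleiotropy_mode `"none"`, `"balanced"` (zero-mean direct
#'   effects), or `"directional"` (nonzero mean).
#' @param pleiotropy_mean Mean of per-SNP direct effects on the outcome;
#'   must be 0 unless mode is `"directional"`.
#' @param pleiotropy_sd Spread of per-SNP direct effects (default 0.02).
#' @param nome Treat exposure betas as measured without error (default
#'   `TRUE`).
#' @param seed Integer seed making the scenario fully reproducible.
#' @param label Cancer-type label stamped on the generated instruments.
#' @param smoking_related Logical flag stamped on the instruments.
#' @param rsid_start First sequential rsID number; scenarios meant to
#'   share one outcome file should use disjoint ranges.
#' @return An `mr_scenario` list.
#' @export
mr_scenario <- function(n_snps, theta_true = 0, beta_x_scale = 0.15,
                        beta_x_floor = 0.01, se_x = 0.015, se_y = 0.02,
                        pleiotropy_mode = c("none", "balanced", "directional"),
                        pleiotropy_mean = 0, pleiotropy_sd = 0.02,
                        nome = TRUE, seed = 20190919,
                        label = "synthetic", smoking_related = FALSE,
                        rsid_start = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (!is.numeric(n_snps) || length(n_snps) != 1L || n_snps < 1) {
    stop("n_snps must be a single integer >= 1", call. = FALSE)
  }
  if (se_x <= 0 || se_y <= 0 || beta_x_scale <= 0 || beta_x_floor < 0) {
    stop("scale parameters must be positive", call. = FALSE)
  }
  if (pleiotropy_mode != "directional" && pleiotropy_mean != 0) {
    stop(sprintf("pleiotropy_mean must be 0 when mode is '%s'", pleiotropy_mode),
         call. = FALSE)
  }
  structure(list(
    n_snps = as.integer(n_snps), theta_true = theta_true,
    beta_x_scale = beta_x_scale, beta_x_floor = beta_x_floor,
    se_x = se_x, se_y = se_y,
    pleiotropy_mode = pleiotropy_mode, pleiotropy_mean = pleiotropy_mean,
    pleiotropy_sd = pleiotropy_sd, nome = nome,
    seed = as.integer(seed), label = label,
    smoking_related = isTRUE(smoking_related),
    rsid_start = as.integer(rsid_start)),
    class = "mr_scenario")
}

random_allele_pairs <- function(n) {
  bases <- c("A", "C", "G", "T")
  a1 <- sample(bases, n, replace = TRUE)
  shift <- sample(1:3, n, replace = TRUE)
  a2 <- bases[(match(a1, bases) - 1L + shift) %% 4L + 1L]
  cbind(a1, a2)
}

#' Simulate two-sample GWAS summary statistics with known causal structure
#'
#' Draws J true exposure effects (zero-centred, magnitude-floored),
#' observed exposure betas (exact under NOME, noisy otherwise), and
#' outcome betas \eqn{\beta_{Yj} = \theta \beta_{Xj}^{true} + \alpha_j +
#' \epsilon_j} where \eqn{\alpha_j} follows the scenario's pleiotropy
#' regime and \eqn{\epsilon_j \sim N(0, se_y^2)}. Pleiotropic intercepts
#' are defined in the exposure-increasing allele orientation — the frame
#' in which a directional (nonzero-mean) pleiotropy is identifiable at
#' all, since flipping an allele label flips the sign of a direct effect
#' — and are rotated into each variant's reported orientation. Variants get sequential
#' rsIDs and random distinct allele pairs, identically oriented in both
#' studies except for an optional fraction of outcome rows whose alleles
#' are deliberately swapped (beta negated) to exercise harmonization's
#' sign-flip path. Output is fully reproducible from the scenario seed.
#'
#' @param scn An [mr_scenario()].
#' @param flip_fraction Fraction of outcome rows emitted with swapped
#'   alleles and negated beta (default 0).
#' @return List with `exposure` (an `instrument_table`) and `outcome` (an
#'   `outcome_table`), plus `truth` (per-SNP true exposure effects and
#'   pleiotropic intercepts).
#' @export
simulate_two_sample <- function(scn, flip_fraction = 0) {
  stopifnot(inherits(scn, "mr_scenario"),
            flip_fraction >= 0, flip_fraction <= 1)
  set.seed(scn$seed)
  J <- scn$n_snps
  bx_true <- stats::rnorm(J, 0, scn$beta_x_scale)
  bx_true <- sign(bx_true + (bx_true == 0)) * pmax(abs(bx_true), scn$beta_x_floor)
  bx_obs <- if (scn$nome) bx_true else bx_true + stats::rnorm(J, 0, scn$se_x)
  alpha <- switch(scn$pleiotropy_mode,
    none = rep(0, J),
    balanced = stats::rnorm(J, 0, scn$pleiotropy_sd),
    directional = stats::rnorm(J, scn$pleiotropy_mean, scn$pleiotropy_sd))
  by <- scn$theta_true * bx_true + sign(bx_true) * alpha +
    stats::rnorm(J, 0, scn$se_y)

  alleles <- random_allele_pairs(J)
  rsid <- sprintf("rs%06d", scn$rsid_start + seq_len(J) - 1L)
  chromosome <- sample(1:22, J, replace = TRUE)
  position <- sample.int(2.4e8, J)

  exposure <- new_instrument_table(data.frame(
    rsid = rsid, chromosome = chromosome, position = position,
    effect_allele = alleles[, 1], other_allele = alleles[, 2],
    beta = bx_obs, se = scn$se_x,
    pvalue = 2 * stats::pnorm(-abs(bx_obs / scn$se_x)),
    stringsAsFactors = FALSE), scn$label, scn$smoking_related)

  flip <- rep(FALSE, J)
  if (flip_fraction > 0) {
    flip <- stats::runif(J) < flip_fraction
  }
  outcome <- data.frame(
    rsid = rsid, chromosome = chromosome, position = position,
    effect_allele = ifelse(flip, alleles[, 2], alleles[, 1]),
    other_allele = ifelse(flip, alleles[, 1], alleles[, 2]),
    beta = ifelse(flip, -by, by), se = scn$se_y,
    pvalue = 2 * stats::pnorm(-abs(by / scn$se_y)),
    stringsAsFactors = FALSE)
  class(outcome) <- c("outcome_table", "data.frame")

  list(exposure = exposure, outcome = outcome,
       truth = data.frame(rsid = rsid, beta_x_true = bx_true, alpha = alpha,
                          flipped = flip, stringsAsFactors = FALSE))
}

#' Simulate a block LD matrix with companion proxy fixtures
#'
#' Builds a block-diagonal squared-correlation matrix — `within_r2` inside
#' each locus, 0 across loci, unit diagonal — together with a proxy table
#' mapping one designated "missing" variant per locus (the last) to an
#' in-block partner (the first) at LD `proxy_r2`, with a consistent allele
#' bijection. An allele assignment for every variant is returned so
#' exposure and outcome fixtures built on top of the matrix stay
#' consistent with the proxy allele maps.
#'
#' @param n_loci Number of independent loci.
#' @param snps_per_locus Variants per locus (>= 2 for proxies to exist).
#' @param within_r2 Pairwise \eqn{r^2} within a locus, in \eqn{[0, 1]}.
#' @param proxy_r2 LD between each designated missing variant and its
#'   proxy.
#' @param seed Integer seed.
#' @return List with `ld` (an `ld_matrix`), `proxies` (a `proxy_table`),
#'   `alleles` (data.frame `rsid`, `a1`, `a2`), and `missing` (the
#'   designated per-locus missing rsIDs).
#' @export
simulate_ld_fixture <- function(n_loci = 3, snps_per_locus = 3,
                                within_r2 = 0.5, proxy_r2 = 0.95,
                                seed = 20190919) {
  stopifnot(within_r2 >= 0, within_r2 <= 1, proxy_r2 >= 0, proxy_r2 <= 1)
  set.seed(seed)
  n <- n_loci * snps_per_locus
  rsid <- sprintf("rsL%02dS%02d", rep(seq_len(n_loci), each = snps_per_locus),
                  rep(seq_len(snps_per_locus), n_loci))
  locus <- rep(seq_len(n_loci), each = snps_per_locus)
  m <- outer(locus, locus, function(a, b) ifelse(a == b, within_r2, 0))
  diag(m) <- 1
  dimnames(m) <- list(rsid, rsid)
  alleles <- random_allele_pairs(n)
  allele_df <- data.frame(rsid = rsid, a1 = alleles[, 1], a2 = alleles[, 2],
                          stringsAsFactors = FALSE)
  proxies <- NULL
  missing <- character(0)
  if (snps_per_locus >= 2) {
    rows <- list()
    for (l in seq_len(n_loci)) {
      tgt <- rsid[locus == l][snps_per_locus]
      prx <- rsid[locus == l][1]
      missing <- c(missing, tgt)
      ti <- match(tgt, rsid); pi <- match(prx, rsid)
      rows[[l]] <- data.frame(
        target_rsid = tgt, proxy_rsid = prx, r2 = proxy_r2,
        target_allele = c(alleles[ti, 1], alleles[ti, 2]),
        proxy_allele = c(alleles[pi, 1], alleles[pi, 2]),
        stringsAsFactors = FALSE)
    }
    proxies <- validate_proxy_table(do.call(rbind, rows))
  }
  list(ld = validate_ld_matrix(m), proxies = proxies,
       alleles = allele_df, missing = missing)
}

#' Preset scenarios sized like a multi-cancer MR study
#'
#' Six labelled scenarios matching the instrument counts of a
#' representative multi-cancer analysis — lung (18 SNPs), leukemia (38),
#' breast (109), all smoking-related cancers (68), all non-smoking-related
#' cancers (246), and all cancers (314) — with true causal effects set to
#' the log of each group's protective odds ratio (0.91, 0.98, 0.94, 0.95,
#' 0.98, 0.98). Intended for end-to-end smoke tests and calibration runs
#' at realistic problem sizes.
#'
#' @param seed Base seed; each preset derives its own offset seed.
#' @return Named list of six [mr_scenario()] objects.
#' @export
paper_scale_scenarios <- function(seed = 20190919) {
  spec <- data.frame(
    label = c("lung", "leukemia", "breast", "smoking_related",
              "non_smoking_related", "all_cancers"),
    n_snps = c(18L, 38L, 109L, 68L, 246L, 314L),
    odds_ratio = c(0.91, 0.98, 0.94, 0.95, 0.98, 0.98),
    smoking_related = c(TRUE, FALSE, FALSE, TRUE, FALSE, NA),
    stringsAsFactors = FALSE)
  starts <- cumsum(c(1L, spec$n_snps[-nrow(spec)]))
  out <- lapply(seq_len(nrow(spec)), function(i) {
    mr_scenario(n_snps = spec$n_snps[i], theta_true = log(spec$odds_ratio[i]),
                seed = seed + i, label = spec$label[i],
                smoking_related = isTRUE(spec$smoking_related[i]),
                rsid_start = starts[i])
  })
  names(out) <- spec$label
  out
}
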