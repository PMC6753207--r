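# Shared fixture builders: everything is generated in code at test time.

# A harmonized-instruments data.frame drawn directly on the harmonized
# scale (used for estimator-level oracles where the I/O layer is not
# under test).
make_harmonized <- function(J, theta = 0, seed = 1, se_y = 0.02,
                            intercept = 0) {
  set.seed(seed)
  bx <- sign(stats::rnorm(J)) * stats::runif(J, 0.05, 0.4)
  se_out <- stats::runif(J, 0.5, 1.5) * se_y
  by <- intercept * sign(bx) + theta * bx + stats::rnorm(J, 0, se_out)
  alleles <- matrix(c("A", "G"), J, 2, byrow = TRUE)
  h <- data.frame(
    rsid = sprintf("rs%06d", seq_len(J)),
    effect_allele = alleles[, 1], other_allele = alleles[, 2],
    beta_exposure = bx, se_exposure = 0.015,
    pvalue_exposure = 2 * stats::pnorm(-abs(bx / 0.015)),
    beta_outcome = by, se_outcome = se_out,
    cancer_type = "synthetic", smoking_related = FALSE,
    flipped = FALSE, proxy_used = FALSE, palindromic = FALSE,
    stringsAsFactors = FALSE)
  class(h) <- c("harmonized_instruments", "data.frame")
  h
}

# One simulate -> harmonize -> IVW replicate under a scenario.
run_ivw_rep <- function(scn, flip_fraction = 0) {
  sim <- simulate_two_sample(scn, flip_fraction = flip_fraction)
  h <- suppressWarnings(harmonize(sim$exposure, sim$outcome))
  ivw_pool(wald_ratios(h))
}

# A tiny instrument table built in memory.
make_instruments <- function(rsid, beta, se, pvalue,
                             effect_allele = NULL, other_allele = NULL,
                             cancer_type = "test", smoking_related = FALSE) {
  n <- length(rsid)
  if (is.null(effect_allele)) effect_allele <- rep("A", n)
  if (is.null(other_allele)) other_allele <- rep("G", n)
  df <- data.frame(rsid = rsid, effect_allele = effect_allele,
                   other_allele = other_allele, beta = beta, se = se,
                   pvalue = pvalue, stringsAsFactors = FALSE)
  mrivw:::new_instrument_table(df, cancer_type, smoking_related)
}

extdata <- function(name) system.file("extdata", name, package = "mrivw")
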