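is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure instruments with outcome summary statistics
#'
#' Joins exposure and outcome records on rsID and aligns both studies to
#' the exposure's effect allele. When the outcome study reports its effect
#' for the same allele the outcome beta is kept as-is; when the outcome's
#' effect/other alleles are swapped relative to the exposure, the outcome
#' beta is negated and the instrument flagged `flipped` (its magnitude and
#' standard error are untouched). Allele comparison is case-insensitive.
#' Palindromic variants (A/T or C/G pairs), whose strand cannot be resolved
#' from alleles alone, are retained with a warning by default since no
#' strand inference from allele frequency is attempted; set
#' `drop_palindromic = TRUE` to exclude them. Instruments absent from the
#' outcome data or with irreconcilable allele pairs are dropped, with the
#' reason recorded in the `"dropped"` attribute.
#'
#' @param exposure An `instrument_table` (after selection/proxy
#'   substitution, so rsIDs should resolve in `outcome`).
#' @param outcome An `outcome_table` (or data.frame with fields `rsid`,
#'   `effect_allele`, `other_allele`, `beta`, `se`).
#' @param drop_palindromic Drop A/T and C/G variants instead of flagging
#'   them. Default `FALSE`.
#' @return A `harmonized_instruments` data.frame with one row per aligned
#'   instrument: alleles, `beta_exposure`/`se_exposure`,
#'   `beta_outcome`/`se_outcome`, group labels, and logical flags
#'   `flipped`, `proxy_used`, `palindromic`. Attribute `"dropped"` is a
#'   data.frame of `(rsid, reason)` with reasons `"absent"`,
#'   `"incompatible"`, or `"palindromic"`.
#' @export
harmonize <- function(exposure, outcome, drop_palindromic = FALSE) {
  stopifnot(is.data.frame(exposure), is.data.frame(outcome))
  idx <- match(exposure$rsid, outcome$rsid)
  ea_x <- toupper(exposure$effect_allele)
  oa_x <- toupper(exposure$other_allele)
  ea_y <- toupper(outcome$effect_allele[idx])
  oa_y <- toupper(outcome$other_allele[idx])

  absent <- is.na(idx)
  same <- !absent & ea_x == ea_y & oa_x == oa_y
  swapped <- !absent & ea_x == oa_y & oa_x == ea_y
  incompatible <- !absent & !same & !swapped
  palindromic <- is_palindromic(ea_x, oa_x)

  keep <- (same | swapped) & !(drop_palindromic & palindromic)
  reason <- rep(NA_character_, nrow(exposure))
  reason[absent] <- "absent"
  reason[incompatible] <- "incompatible"
  reason[(same | swapped) & drop_palindromic & palindromic] <- "palindromic"

  n_pal <- sum(palindromic & keep)
  if (n_pal > 0 && !drop_palindromic) {
    warning(sprintf(
      "%d palindromic (A/T or C/G) instrument%s retained; strand cannot be verified from alleles",
      n_pal, if (n_pal > 1) "s" else ""), call. = FALSE)
  }

  h <- data.frame(
    rsid = exposure$rsid[keep],
    effect_allele = ea_x[keep],
    other_allele = oa_x[keep],
    beta_exposure = exposure$beta[keep],
    se_exposure = exposure$se[keep],
    pvalue_exposure = exposure$pvalue[keep],
    beta_outcome = ifelse(swapped[keep], -outcome$beta[idx[keep]],
                          outcome$beta[idx[keep]]),
    se_outcome = outcome$se[idx[keep]],
    cancer_type = if (is.null(exposure$cancer_type)) NA_character_ else
      exposure$cancer_type[keep],
    smoking_related = if (is.null(exposure$smoking_related)) NA else
      exposure$smoking_related[keep],
    flipped = swapped[keep],
    proxy_used = if (is.null(exposure$proxy_used)) rep(FALSE, sum(keep)) else
      exposure$proxy_used[keep],
    palindromic = palindromic[keep],
    stringsAsFactors = FALSE)
  if (any(h$se_exposure <= 0) || any(h$se_outcome <= 0)) {
    stop("standard errors must be positive after harmonization", call. = FALSE)
  }
  rownames(h) <- NULL
  class(h) <- c("harmonized_instruments", "data.frame")
  attr(h, "dropped") <- data.frame(rsid = exposure$rsid[!keep],
                                   reason = reason[!keep],
                                   stringsAsFactors = FALSE)
  h
}

#' Export harmonized instruments as the pipeline's canonical TSV
#'
#' @param h A `harmonized_instruments` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(h, path) {
  utils::write.table(h, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
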