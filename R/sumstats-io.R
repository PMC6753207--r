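#' @keywords internal
"_PACKAGE"

# Exposure-table column aliases, matched case-insensitively. The outcome
# layout is fixed by igap_columns(); the exposure layout varies by source,
# so a generous alias list is accepted.
.exposure_aliases <- list(
  rsid          = c("rsid", "snp", "markername", "rs_id", "variant", "variant_id"),
  chromosome    = c("chromosome", "chr"),
  position      = c("position", "pos", "bp", "base_pair_location"),
  effect_allele = c("effect_allele", "ea", "a1", "allele1"),
  other_allele  = c("other_allele", "non_effect_allele", "oa", "a2", "allele2"),
  beta          = c("beta", "b", "log_odds", "beta_coefficient"),
  se            = c("se", "stderr", "standard_error"),
  pvalue        = c("pvalue", "p", "p_value", "pval"),
  eaf           = c("eaf", "effect_allele_frequency", "freq")
)

#' Default outcome-table column mapping
#'
#' Column names of the Alzheimer's disease outcome datafile layout used by
#' the IGAP (International Genomics of Alzheimer's Project) meta-analysis:
#' one row per variant with `MarkerName` (rsID, or `chromosome:position`
#' where no rsID exists), the effect and non-effect alleles, the per-allele
#' log-odds effect size, its standard error, and the association p-value.
#'
#' @return Named character vector mapping internal field names to file
#'   column names; pass a modified copy to [read_outcome_table()] for files
#'   using different headers.
#' @export
igap_columns <- function() {
  c(rsid = "MarkerName", chromosome = "Chromosome", position = "Position",
    effect_allele = "Effect_allele", other_allele = "Non_Effect_allele",
    beta = "Beta", se = "SE", pvalue = "P")
}

# Validate one table of SNP associations. `lines` are the 1-based file line
# numbers of each row (header = line 1) for error reporting; NULL for
# in-memory tables.
validate_snp_rows <- function(df, lines = NULL, context = "table") {
  if (is.null(lines)) lines <- seq_len(nrow(df)) + 1L
  bad <- function(rows, what) {
    if (length(rows)) {
      stop(sprintf("%s: %s (line %s)", context, what,
                   paste(lines[rows], collapse = ", ")), call. = FALSE)
    }
  }
  df$effect_allele <- toupper(df$effect_allele)
  df$other_allele <- toupper(df$other_allele)
  bad(which(is.na(df$rsid) | !nzchar(df$rsid)), "empty rsid")
  snp_allele <- function(a) !is.na(a) & a %in% c("A", "C", "G", "T")
  bad(which(!snp_allele(df$effect_allele)),
      "effect_allele is not a single A/C/G/T base")
  bad(which(!snp_allele(df$other_allele)),
      "other_allele is not a single A/C/G/T base")
  bad(which(df$effect_allele == df$other_allele),
      "effect_allele equals other_allele")
  bad(which(!is.finite(df$beta)), "non-numeric beta")
  bad(which(!is.finite(df$se)), "non-numeric se")
  bad(which(is.finite(df$se) & df$se <= 0), "se must be > 0")
  bad(which(!is.finite(df$pvalue) | df$pvalue < 0 | df$pvalue > 1),
      "pvalue must lie in [0, 1]")
  if (!is.null(df$eaf)) {
    bad(which(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1)),
        "eaf must lie in [0, 1]")
  }
  df
}

# Map file headers onto canonical field names (case-insensitive, first
# alias wins). Returns the renamed data.frame.
map_exposure_columns <- function(df, path) {
  hdr <- tolower(names(df))
  out <- list()
  for (field in names(.exposure_aliases)) {
    hit <- which(hdr %in% .exposure_aliases[[field]])
    if (length(hit)) out[[field]] <- df[[hit[1]]]
  }
  required <- c("rsid", "effect_allele", "other_allele", "beta", "se", "pvalue")
  missing <- setdiff(required, names(out))
  if (length(missing)) {
    stop(sprintf("'%s': missing required column '%s'", path, missing[1]),
         call. = FALSE)
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

coerce_numeric <- function(x, col, path) {
  if (is.numeric(x)) return(x)
  y <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(y) & !is.na(x) & nzchar(trimws(x)))
  if (length(bad)) {
    stop(sprintf("'%s': non-numeric %s (line %s)", path, col,
                 paste(bad + 1L, collapse = ", ")), call. = FALSE)
  }
  y
}

new_instrument_table <- function(df, cancer_type, smoking_related) {
  df$cancer_type <- cancer_type
  df$smoking_related <- smoking_related
  keep <- intersect(c("rsid", "chromosome", "position", "effect_allele",
                      "other_allele", "beta", "se", "pvalue", "eaf",
                      "cancer_type", "smoking_related",
                      "proxy_used", "proxy_for"), names(df))
  df <- df[, keep, drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("instrument_table", "data.frame")
  df
}

#' Read an exposure instrument table
#'
#' Reads a tab-separated table of SNP-cancer associations (one row per
#' variant: rsID, alleles, per-allele log-odds `beta`, standard error,
#' p-value; chromosome/position/eaf optional) and validates every row.
#' Column headers are matched case-insensitively against common aliases
#' (`SNP`/`rsid`, `P`/`pvalue`, `A1`/`effect_allele`, ...). Alleles are
#' upper-cased; indels and multi-character alleles are rejected — the
#' instruments handled here are SNPs.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param cancer_type Label attached to every record (e.g. `"lung"`).
#' @param smoking_related Logical flag attached to every record.
#' @return An `instrument_table`: a data.frame with one validated row per
#'   variant, row order as in the file.
#' @seealso [read_outcome_table()], [write_instrument_table()]
#' @export
read_instrument_table <- function(path, cancer_type, smoking_related) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  df <- map_exposure_columns(raw, path)
  for (col in c("beta", "se", "pvalue")) {
    df[[col]] <- coerce_numeric(df[[col]], col, path)
  }
  if (!is.null(df$eaf)) df$eaf <- coerce_numeric(df$eaf, "eaf", path)
  if (!is.null(df$position)) df$position <- coerce_numeric(df$position, "position", path)
  df <- validate_snp_rows(df, context = sprintf("'%s'", path))
  if (anyDuplicated(df$rsid)) {
    stop(sprintf("'%s': duplicated rsid '%s'", path,
                 df$rsid[duplicated(df$rsid)][1]), call. = FALSE)
  }
  new_instrument_table(df, cancer_type, isTRUE(smoking_related))
}

#' Write an exposure instrument table
#'
#' Inverse of [read_instrument_table()]; numeric fields are written at full
#' double precision so a write/read round trip is lossless well beyond 12
#' significant digits.
#'
#' @param x An `instrument_table`.
#' @param path Output path (tab-separated, with header).
#' @return `path`, invisibly.
#' @export
write_instrument_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read outcome summary statistics (IGAP datafile layout)
#'
#' Reads a tab-separated outcome GWAS summary-statistics file keyed by
#' `MarkerName` and validates every record. The default header names follow
#' the IGAP Alzheimer's disease datafile ([igap_columns()]); supply a
#' modified mapping for files with other headers. `MarkerName` values are
#' treated as opaque keys — rsIDs and `chromosome:position` identifiers are
#' both accepted — and must be unique.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param columns Named character vector mapping internal field names to
#'   file column names; see [igap_columns()]. `chromosome`/`position` are
#'   optional in the file.
#' @return An `outcome_table`: a data.frame of validated records, one per
#'   variant, supporting lookup by `rsid`.
#' @export
read_outcome_table <- function(path, columns = igap_columns()) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  hdr <- tolower(names(raw))
  required <- c("rsid", "effect_allele", "other_allele", "beta", "se", "pvalue")
  df <- list()
  for (field in names(columns)) {
    hit <- which(hdr == tolower(columns[[field]]))
    if (length(hit)) {
      df[[field]] <- raw[[hit[1]]]
    } else if (field %in% required) {
      stop(sprintf("'%s': missing required column '%s'", path, columns[[field]]),
           call. = FALSE)
    }
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("beta", "se", "pvalue")) {
    df[[col]] <- coerce_numeric(df[[col]], col, path)
  }
  if (!is.null(df$position)) df$position <- coerce_numeric(df$position, "position", path)
  df <- validate_snp_rows(df, context = sprintf("'%s'", path))
  if (anyDuplicated(df$rsid)) {
    stop(sprintf("'%s': duplicated MarkerName '%s'", path,
                 df$rsid[duplicated(df$rsid)][1]), call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("outcome_table", "data.frame")
  df
}

#' Write outcome summary statistics in the IGAP datafile layout
#'
#' @param x An `outcome_table` (or data.frame with the same fields).
#' @param path Output path.
#' @param columns Field-to-header mapping, as in [read_outcome_table()].
#' @return `path`, invisibly.
#' @export
write_outcome_table <- function(x, path, columns = igap_columns()) {
  fields <- intersect(names(columns), names(x))
  out <- x[, fields, drop = FALSE]
  names(out) <- columns[fields]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pairwise LD r-squared matrix
#'
#' Reads a square tab-separated matrix of squared allelic correlations with
#' rsID row and column labels (the layout exported by LD lookup tools) and
#' checks symmetry, a unit diagonal, and the \eqn{[0, 1]} range.
#'
#' @param path Path to a tab-separated file: header of rsIDs, one labelled
#'   row per rsID.
#' @return A numeric matrix with rsID dimnames, class `ld_matrix`.
#' @export
read_ld_matrix <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- raw[[1]]
  storage.mode(m) <- "double"
  validate_ld_matrix(m, context = sprintf("'%s'", path))
}

validate_ld_matrix <- function(m, context = "ld matrix") {
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m))) {
    stop(sprintf("%s: not square with matching rsid labels", context), call. = FALSE)
  }
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1)) {
    stop(sprintf("%s: r2 entries must lie in [0, 1]", context), call. = FALSE)
  }
  if (max(abs(m - t(m))) > 1e-8) {
    stop(sprintf("%s: not symmetric", context), call. = FALSE)
  }
  if (max(abs(diag(m) - 1)) > 1e-8) {
    stop(sprintf("%s: diagonal must equal 1", context), call. = FALSE)
  }
  class(m) <- c("ld_matrix", class(m))
  m
}

#' Write an LD r-squared matrix
#'
#' @param m Square numeric matrix with rsID dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(m, path) {
  df <- data.frame(rsid = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a proxy SNP table
#'
#' Reads a long-format tab-separated table of proxy candidates: one row per
#' (target, proxy, allele) triple with columns `target_rsid`, `proxy_rsid`,
#' `r2`, `target_allele`, `proxy_allele`. The two rows of each
#' target/proxy pair define the allele correspondence used to re-assign
#' effect alleles when a proxy stands in for an instrument missing from the
#' outcome data; the correspondence must be a bijection over the target's
#' two alleles.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A `proxy_table` data.frame.
#' @export
read_proxy_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("target_rsid", "proxy_rsid", "r2", "target_allele", "proxy_allele")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("'%s': missing required column '%s'", path, missing[1]),
         call. = FALSE)
  }
  df$r2 <- coerce_numeric(df$r2, "r2", path)
  if (any(!is.finite(df$r2) | df$r2 < 0 | df$r2 > 1)) {
    stop(sprintf("'%s': r2 must lie in [0, 1]", path), call. = FALSE)
  }
  df$target_allele <- toupper(df$target_allele)
  df$proxy_allele <- toupper(df$proxy_allele)
  validate_proxy_table(df, context = sprintf("'%s'", path))
}

validate_proxy_table <- function(df, context = "proxy table") {
  key <- paste(df$target_rsid, df$proxy_rsid)
  for (k in unique(key)) {
    rows <- df[key == k, ]
    if (nrow(rows) != 2L ||
        anyDuplicated(rows$target_allele) || anyDuplicated(rows$proxy_allele)) {
      stop(sprintf("%s: allele map for %s -> %s is not a bijection over two alleles",
                   context, rows$target_rsid[1], rows$proxy_rsid[1]), call. = FALSE)
    }
  }
  rownames(df) <- NULL
  class(df) <- c("proxy_table", "data.frame")
  df
}

#' Write a proxy SNP table
#'
#' @param x A `proxy_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proxy_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
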