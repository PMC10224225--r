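#' Prevalence / abundance feature filter
#'
#' Drops rare species before differential-abundance analysis. A feature is
#' retained when its prevalence (fraction of samples with a nonzero value)
#' is at least `min_prevalence` AND its mean relative abundance is at least
#' `min_mean_relative_abundance`. The defaults implement the common screen
#' that excludes species present in fewer than 20% of samples or below
#' 0.001% average relative abundance; both comparisons are inclusive at the
#' boundary (exclusion is strict).
#'
#' @param table A [count_table()]; counts are converted to per-sample
#'   relative abundances for the mean-abundance rule.
#' @param min_prevalence Fraction in \[0, 1\] (default 0.20).
#' @param min_mean_relative_abundance Fraction in \[0, 1\] (default 1e-5).
#' @return The filtered [count_table()] (same samples); an attribute
#'   `"retention"` records the number of features kept and dropped. An
#'   empty survivor set is returned with a warning, not an error.
#' @export
filter_features <- function(table, min_prevalence = 0.20,
                            min_mean_relative_abundance = 1e-5) {
  stopifnot(inherits(table, "count_table"))
  if (min_prevalence < 0 || min_prevalence > 1 ||
      min_mean_relative_abundance < 0 || min_mean_relative_abundance > 1) {
    stop("thresholds must lie in [0, 1]")
  }
  m <- table$values
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty table")
  prev <- colMeans(m > 0)
  rel <- m / rowSums(m)
  mean_rel <- colMeans(rel)
  keep <- prev >= min_prevalence & mean_rel >= min_mean_relative_abundance
  if (!any(keep)) warning("no features pass the prevalence/abundance filter")
  out <- count_table(m[, keep, drop = FALSE], feature_kind = table$feature_kind,
                     relative = table$relative,
                     taxonomy = if (!is.null(table$taxonomy)) table$taxonomy[keep])
  attr(out, "retention") <- c(kept = sum(keep), dropped = sum(!keep))
  out
}

#' Quality-control filter for continuous omics features
#'
#' Protein mode keeps markers detected (non-missing) in strictly more than
#' `detection` of samples. Metabolite mode keeps features whose coefficient
#' of variation (SD/mean over observed values) is below `max_cv` and whose
#' missing rate is below `max_missing`; both exclusions are inclusive at
#' the boundary (a CV of exactly 30% is dropped).
#'
#' @param matrix An [omics_matrix()].
#' @param kind `"protein"` or `"metabolite"`.
#' @param detection Detection-fraction threshold for proteins (default 0.75).
#' @param max_cv CV threshold for metabolites (default 0.30).
#' @param max_missing Missing-rate threshold for metabolites (default 0.20).
#' @return The filtered [omics_matrix()]; empty survivor sets warn.
#' @export
qc_filter <- function(matrix, kind = c("protein", "metabolite"),
                      detection = 0.75, max_cv = 0.30, max_missing = 0.20) {
  kind <- match.arg(kind)
  stopifnot(inherits(matrix, "omics_matrix"))
  m <- matrix$values
  if (ncol(m) == 0L) stop("empty matrix")
  if (kind == "protein") {
    keep <- colMeans(!is.na(m)) > detection
  } else {
    miss <- colMeans(is.na(m))
    cv <- apply(m, 2, function(x) {
      x <- x[!is.na(x)]
      stats::sd(x) / mean(x)
    })
    keep <- (cv < max_cv) & (miss < max_missing)
    keep[is.na(keep)] <- FALSE
  }
  if (!any(keep)) warning("no features pass the QC filter")
  omics_matrix(m[, keep, drop = FALSE], scale_tag = matrix$scale_tag)
}

#' Half-minimum imputation for below-detection values
#'
#' Replaces each missing entry of a feature with half the minimum observed
#' value of that feature, the convention for metabolites that fell under
#' the detection limit. Observed entries are untouched.
#'
#' @param matrix An [omics_matrix()] (every feature needs at least one
#'   observed value).
#' @return An [omics_matrix()] with no missing entries.
#' @export
impute_half_min <- function(matrix) {
  stopifnot(inherits(matrix, "omics_matrix"))
  m <- matrix$values
  all_missing <- which(colSums(!is.na(m)) == 0)
  if (length(all_missing)) {
    stop("feature(s) with no observed values: ",
         paste(colnames(m)[utils::head(all_missing, 5)], collapse = ", "))
  }
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    if (any(miss)) m[miss, j] <- 0.5 * min(m[!miss, j])
  }
  omics_matrix(m, scale_tag = matrix$scale_tag)
}
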