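#' Centered log-ratio (CLR) transform
#'
#' Converts each sample's composition to log-ratios about its geometric
#' mean, removing the unit-sum constraint of relative abundances. Zeros are
#' replaced before taking logs: by default with half the smallest nonzero
#' relative abundance observed anywhere in the table, mirroring the
#' half-minimum convention used for below-detection metabolites; a fixed
#' pseudocount can be supplied instead.
#'
#' @param table A [count_table()] or numeric matrix (samples x features).
#'   Counts are converted to relative abundances per sample first.
#' @param zero_replacement `"half_min_nonzero"` (default) or a positive
#'   number used as the replacement value delta on the relative-abundance
#'   scale.
#' @return A [transformed_matrix()] with tag `"CLR"`; each row sums to zero
#'   (within 1e-9) and the transform is invariant to per-sample scaling.
#' @examples
#' m <- matrix(c(1, 2, 4, 1, 1, 1), 2, 3, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("a", "b", "c")))
#' clr_transform(m)$values
#' @export
clr_transform <- function(table, zero_replacement = "half_min_nonzero") {
  m <- as_values(table)
  rs <- rowSums(m)
  zero_rows <- which(rs == 0)
  if (length(zero_rows)) {
    stop("all-zero sample(s): ",
         paste(rownames(m)[utils::head(zero_rows, 5)], collapse = ", "))
  }
  rel <- m / rs
  if (identical(zero_replacement, "half_min_nonzero")) {
    delta <- 0.5 * min(rel[rel > 0])
  } else {
    delta <- as.numeric(zero_replacement)
    if (!is.finite(delta) || delta <= 0) {
      stop("zero_replacement must be 'half_min_nonzero' or a positive number")
    }
  }
  rel[rel == 0] <- delta
  lg <- log(rel)
  out <- lg - rowMeans(lg)
  transformed_matrix(out, "CLR", parameters = list(delta = delta))
}

#' Rank-based inverse-normal transform (INT)
#'
#' Maps each column to normal quantiles through its ranks: a value with
#' rank r among n maps to `qnorm((r - c) / (n - 2c + 1))`. The default
#' offset c = 3/8 is the Blom convention common in epidemiology; ties
#' receive average ranks so the map is deterministic and symmetric.
#'
#' @param matrix A numeric matrix, [omics_matrix()] or
#'   [transformed_matrix()] (e.g. CLR output, giving INT-CLR abundances).
#' @param offset_c Rank offset c (default 3/8).
#' @return A [transformed_matrix()] tagged `"INT"`, or `"INT_CLR"` when the
#'   input was CLR-transformed.
#' @export
int_transform <- function(matrix, offset_c = 3 / 8) {
  was_clr <- inherits(matrix, "transformed_matrix") &&
    matrix$transform_tag == "CLR"
  m <- as_values(matrix)
  if (anyNA(m)) stop("int_transform requires a complete matrix; impute first")
  const <- which(apply(m, 2, function(x) length(unique(x)) < 2))
  if (length(const)) {
    stop("constant column(s): ",
         paste(colnames(m)[utils::head(const, 5)], collapse = ", "))
  }
  n <- nrow(m)
  out <- apply(m, 2, function(x) {
    r <- rank(x, ties.method = "average")
    stats::qnorm((r - offset_c) / (n - 2 * offset_c + 1))
  })
  dimnames(out) <- dimnames(m)
  transformed_matrix(out, if (was_clr) "INT_CLR" else "INT",
                     parameters = list(c = offset_c))
}

#' Column z-score standardization
#'
#' @param matrix Numeric matrix or container; columns centered to mean 0
#'   and scaled to unit SD.
#' @return A [transformed_matrix()] tagged `"zscore"`.
#' @export
zscore_transform <- function(matrix) {
  m <- as_values(matrix)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ",
         paste(colnames(m)[utils::head(which(sds == 0), 5)], collapse = ", "))
  }
  out <- scale(m)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  transformed_matrix(out, "zscore")
}
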