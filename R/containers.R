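#' Sample-by-feature abundance table
#'
#' Lightweight container for a microbiome abundance matrix (species counts,
#' relative abundances, or functional-enzyme abundances). Samples are rows,
#' features are columns. Row and column names carry the sample and feature
#' identifiers and must be unique.
#'
#' @param values Numeric matrix, samples as rows, features as columns.
#'   All entries must be non-negative; `NA` is not allowed.
#' @param feature_kind One of `"species"`, `"enzyme"`, `"gene"`.
#' @param relative Logical; `TRUE` when rows are relative abundances
#'   (each row must then sum to 1 within 1e-9).
#' @param taxonomy Optional character vector of per-feature lineage strings.
#'
#' @return An object of class `count_table`.
#' @export
count_table <- function(values, feature_kind = c("species", "enzyme", "gene"),
                        relative = FALSE, taxonomy = NULL) {
  feature_kind <- match.arg(feature_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (ncol(values) == 0L && is.null(colnames(values))) {
    colnames(values) <- character(0)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have sample row names and feature column names")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(values))) stop("duplicate feature ids")
  if (anyNA(values)) stop("count_table values may not contain NA")
  if (any(values < 0)) stop("count_table values must be non-negative")
  if (relative) {
    rs <- rowSums(values)
    bad <- which(abs(rs - 1) > 1e-9)
    if (length(bad)) {
      stop("relative-abundance rows must sum to 1: ",
           paste(rownames(values)[utils::head(bad, 5)], collapse = ", "))
    }
  }
  if (!is.null(taxonomy) && length(taxonomy) != ncol(values)) {
    stop("taxonomy length must match feature count")
  }
  structure(
    list(values = values, feature_kind = feature_kind,
         relative = relative, taxonomy = taxonomy),
    class = "count_table"
  )
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d samples x %d %s features (%s)\n",
              nrow(x$values), ncol(x$values), x$feature_kind,
              if (x$relative) "relative" else "counts/abundance"))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$values)

sample_ids <- function(x) rownames(x$values)
feature_ids <- function(x) colnames(x$values)

#' Continuous omics matrix (proteins or metabolites)
#'
#' Real-valued sample-by-feature matrix in which missing entries are allowed
#' (metabolites under the detection limit, undetected proteins).
#'
#' @param values Numeric matrix with sample row names and feature column
#'   names; `NA` marks a missing measurement.
#' @param scale_tag `"NPX_log2"` for Olink normalized protein expression or
#'   `"intensity"` for LC-MS intensities.
#' @return An object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, scale_tag = c("intensity", "NPX_log2")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (ncol(values) == 0L && is.null(colnames(values))) {
    colnames(values) <- character(0)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have sample row names and feature column names")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(values))) stop("duplicate feature ids")
  structure(list(values = values, scale_tag = scale_tag),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix:%s> %d samples x %d features, %.1f%% missing\n",
              x$scale_tag, nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Transformed real matrix with provenance
#'
#' Holds the output of a compositional or rank transform together with the
#' transform tag and the parameters used, so downstream models can record
#' exactly what scale an effect estimate refers to.
#'
#' @param values Numeric matrix (samples x features), no missing entries.
#' @param transform_tag One of `"CLR"`, `"INT"`, `"INT_CLR"`, `"zscore"`.
#' @param parameters Named list of transform parameters (e.g. the zero
#'   replacement value `delta`, the inverse-normal offset `c`).
#' @return An object of class `transformed_matrix`.
#' @export
transformed_matrix <- function(values,
                               transform_tag = c("CLR", "INT", "INT_CLR", "zscore"),
                               parameters = list()) {
  transform_tag <- match.arg(transform_tag)
  if (!is.matrix(values) || !is.numeric(values) || anyNA(values)) {
    stop("`values` must be a complete numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have sample row names and feature column names")
  }
  structure(list(values = values, transform_tag = transform_tag,
                 parameters = parameters),
            class = "transformed_matrix")
}

#' @export
print.transformed_matrix <- function(x, ...) {
  cat(sprintf("<transformed_matrix:%s> %d samples x %d features\n",
              x$transform_tag, nrow(x$values), ncol(x$values)))
  invisible(x)
}

# Accept either a bare matrix or one of the containers above and return the
# numeric matrix; used by the statistical layer so every op takes both.
as_values <- function(x) {
  if (is.matrix(x)) return(x)
  if (inherits(x, c("count_table", "omics_matrix", "transformed_matrix"))) {
    return(x$values)
  }
  stop("expected a matrix, count_table, omics_matrix or transformed_matrix")
}
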