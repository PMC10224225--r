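#' Read a sample-by-feature abundance table from TSV
#'
#' Canonical table format: tab-separated, header row of feature ids, first
#' column sample ids (`samples_as_rows`), or the transpose
#' (`features_as_rows`). Values must be numeric and non-negative.
#'
#' @param path Path to a TSV file.
#' @param orientation `"samples_as_rows"` (default) or `"features_as_rows"`.
#' @param feature_kind Passed to [count_table()].
#' @param relative Passed to [count_table()].
#' @return A [count_table()].
#' @export
read_feature_table <- function(path,
                               orientation = c("samples_as_rows", "features_as_rows"),
                               feature_kind = "species", relative = FALSE) {
  orientation <- match.arg(orientation)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("feature table needs an id column plus >= 1 feature")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate ids in first column of ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in ", path)
  if (anyNA(m)) stop("missing values not allowed in an abundance table: ", path)
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative entry at row %d (id %s), column %s in %s",
                 neg[1, 1], ids[neg[1, 1]], colnames(m)[neg[1, 2]], path))
  }
  rownames(m) <- ids
  if (orientation == "features_as_rows") m <- t(m)
  count_table(m, feature_kind = feature_kind, relative = relative)
}

#' Write a sample-by-feature table as TSV
#'
#' Inverse of [read_feature_table()] in `samples_as_rows` orientation:
#' header row of feature ids, first column `sample_id`.
#'
#' @param x A [count_table()], [omics_matrix()], [transformed_matrix()] or
#'   bare matrix with dimnames.
#' @param path Output path.
#' @export
write_feature_table <- function(x, path) {
  m <- as_values(x)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a continuous omics matrix from TSV
#'
#' Same layout as [read_feature_table()] (samples as rows) but empty cells
#' and `NA` are kept as missing measurements.
#'
#' @inheritParams read_feature_table
#' @param scale_tag Passed to [omics_matrix()].
#' @return An [omics_matrix()].
#' @export
read_omics_matrix <- function(path, scale_tag = "intensity") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in ", path)
  rownames(m) <- ids
  omics_matrix(m, scale_tag = scale_tag)
}

#' Read cohort metadata from TSV
#'
#' Validates that the named covariate columns and the binary outcome column
#' are present; the outcome must be coded 0/1.
#'
#' @param path Path to a TSV with a `sample_id` column.
#' @param outcome Name of the binary outcome column (default `"plaque"`).
#' @param required Character vector of covariate column names that must be
#'   present (checked by name; an informative error lists any missing).
#' @return A data.frame with `sample_id` as row names.
#' @export
read_metadata <- function(path, outcome = "plaque", required = character()) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("metadata must have a sample_id column")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  missing_cols <- setdiff(c(outcome, required), names(df))
  if (length(missing_cols)) {
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!all(df[[outcome]] %in% c(0, 1))) {
    stop("outcome column '", outcome, "' must be coded 0/1")
  }
  rownames(df) <- df$sample_id
  df
}

#' Serialize / reload the planted ground truth of a synthetic cohort
#'
#' @param truth A `synthetic_truth` object from [generate_cohort()].
#' @param path JSON output path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  obj <- unclass(truth)
  # named numeric vectors serialize as JSON objects, not bare arrays
  for (nm in c("species_plaque_effects", "producer_weights",
               "carrier_weights")) {
    obj[[nm]] <- as.list(obj[[nm]])
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("species_plaque_effects", "producer_weights",
               "carrier_weights")) {
    v <- unlist(x[[nm]])
    x[[nm]] <- stats::setNames(as.numeric(v), names(v))
  }
  x$mediator_loadings <- as.matrix(x$mediator_loadings)
  structure(x, class = "synthetic_truth")
}

#' Read an enzyme-to-EC-category map
#'
#' Two-column TSV: `enzyme_id`, `ec_level3` (the EC level-III class of the
#' enzyme, e.g. `"EC 6.3.4"` for carbon-nitrogen ligases).
#'
#' @param path Path to the map TSV.
#' @return Named character vector: category keyed by enzyme id.
#' @export
read_ec_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("enzyme_id", "ec_level3") %in% names(df))) {
    stop("EC map must have columns enzyme_id and ec_level3")
  }
  if (anyDuplicated(df$enzyme_id)) stop("duplicate enzyme ids in EC map")
  stats::setNames(as.character(df$ec_level3), df$enzyme_id)
}
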