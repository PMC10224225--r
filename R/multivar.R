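#' PLS-DA fit for a binary outcome (NIPALS PLS1)
#'
#' Partial least squares discriminant analysis of an omics panel against a
#' two-class outcome, the profiling step used for inflammatory-marker
#' panels. Deterministic single-response NIPALS: each component extracts
#' the unit-norm weight vector `w = X'y / ||X'y||`, scores `t = X w`,
#' x-loadings `p = X't / t't`, y-loading `q = t'y / t't`, then deflates
#' `X <- X - t p'` and `y <- y - t q`. Columns of `X` are standardized and
#' `y` is centered internally, so supplied matrices can be raw.
#'
#' @param X Numeric matrix or [omics_matrix()]/[transformed_matrix()]
#'   (samples x features; no missing values, no constant columns).
#' @param y Binary 0/1 outcome vector.
#' @param n_components Number of components to extract (default 8, must
#'   not exceed the rank of the centered `X`).
#' @return A `plsda_model`: `x_weights`, `x_loadings` (feature x
#'   component), `scores` (sample x component, mutually orthogonal),
#'   `y_loadings`, `explained_x_variance` (per-component fraction of the
#'   standardized X sum of squares).
#' @export
plsda_fit <- function(X, y, n_components = 8) {
  Xm <- as_values(X)
  if (anyNA(Xm)) stop("X must be complete; impute first")
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be coded 0/1")
  sds <- apply(Xm, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ",
         paste(colnames(Xm)[utils::head(which(sds == 0), 5)], collapse = ", "))
  }
  Xs <- scale(Xm)
  rank_x <- qr(Xs)$rank
  if (n_components > rank_x) {
    stop("n_components (", n_components, ") exceeds rank of X (", rank_x, ")")
  }
  yc <- y - mean(y)
  n <- nrow(Xs); p <- ncol(Xs)
  total_ss <- sum(Xs^2)
  W <- P <- matrix(0, p, n_components,
                   dimnames = list(colnames(Xm),
                                   paste0("PC", seq_len(n_components))))
  Tm <- matrix(0, n, n_components,
               dimnames = list(rownames(Xm), colnames(W)))
  q <- numeric(n_components)
  expvar <- numeric(n_components)
  Xd <- Xs
  yd <- yc
  for (h in seq_len(n_components)) {
    w <- drop(crossprod(Xd, yd))
    w <- w / sqrt(sum(w^2))
    tt <- drop(Xd %*% w)
    pl <- drop(crossprod(Xd, tt)) / sum(tt^2)
    qh <- sum(tt * yd) / sum(tt^2)
    Xd <- Xd - tcrossprod(tt, pl)
    yd <- yd - tt * qh
    W[, h] <- w; P[, h] <- pl; Tm[, h] <- tt; q[h] <- qh
    expvar[h] <- sum(tt^2) * sum(pl^2) / total_ss
  }
  structure(list(n_components = n_components, x_weights = W,
                 x_loadings = P, scores = Tm, y_loadings = q,
                 explained_x_variance = expvar),
            class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("<plsda_model> %d components over %d features (%d samples)\n",
              x$n_components, nrow(x$x_loadings), nrow(x$scores)))
  cat("explained X variance:",
      paste(sprintf("%.3f", x$explained_x_variance), collapse = " "), "\n")
  invisible(x)
}

#' Top contributors of each PLS-DA component
#'
#' The k features with the largest absolute x-loading per component,
#' reported with the signed loading. Ties in |loading| are broken
#' lexicographically by feature id so the ranking is deterministic.
#'
#' @param model A [plsda_fit()] model.
#' @param k Number of contributors per component (default 5).
#' @return data.frame: `component`, `rank`, `feature_id`, `loading`.
#' @export
top_contributors <- function(model, k = 5) {
  stopifnot(inherits(model, "plsda_model"))
  p <- nrow(model$x_loadings)
  if (k > p) stop("k exceeds the number of features (", p, ")")
  out <- lapply(seq_len(model$n_components), function(h) {
    lo <- model$x_loadings[, h]
    ord <- order(-abs(lo), names(lo))
    idx <- ord[seq_len(k)]
    data.frame(component = colnames(model$x_loadings)[h], rank = seq_len(k),
               feature_id = names(lo)[idx], loading = unname(lo[idx]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Covariate-adjusted outcome models per PLS-DA component
#'
#' One logistic fit of the outcome on each component score (standardized
#' to unit SD, so odds ratios read per SD of the component), adjusted for
#' the covariates. Delegates to [fit_logistic()].
#'
#' @param model A [plsda_fit()] model.
#' @param outcome 0/1 vector.
#' @param covariates Optional covariate data.frame/matrix.
#' @return data.frame of association records with BH q-values across
#'   components.
#' @export
pc_outcome_association <- function(model, outcome, covariates = NULL) {
  stopifnot(inherits(model, "plsda_model"))
  recs <- lapply(seq_len(model$n_components), function(h) {
    sc <- model$scores[, h]
    if (stats::sd(sc) == 0) stop("component ", h, " is constant")
    fit_logistic(outcome, sc, covariates = covariates,
                 feature_id = colnames(model$scores)[h],
                 model_tag = "plsda_pc")
  })
  out <- do.call(rbind, recs)
  out$q <- bh_fdr(out$p)
  out
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: pseudo-F and R^2 from
#' the Gower-centered partition of squared distances with an add-one
#' permutation p-value, `p = (1 + #[F_perm >= F_obs]) / (1 + n)`.
#' Delegates to [vegan::adonis2()]; the seed makes the permutation stream
#' reproducible.
#'
#' @param d Symmetric distance matrix (or `dist`).
#' @param groups Group labels; at least 2 groups of at least 2 samples.
#' @param n_permutations Number of permutations (default 999).
#' @param seed Integer seed.
#' @return List: `pseudo_F`, `R2`, `p`.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = 1L) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("singleton group(s) not allowed")
  dd <- stats::as.dist(d)
  set.seed(seed)
  fit <- vegan::adonis2(dd ~ groups, data = data.frame(groups = groups),
                        permutations = n_permutations)
  list(pseudo_F = fit$F[1], R2 = fit$R2[1], p = fit$`Pr(>F)`[1])
}

#' Serialize a PLS-DA model as JSON
#'
#' Weights, loadings, explained variance and top contributors in a plain
#' JSON document for downstream tooling.
#'
#' @param model A [plsda_fit()] model.
#' @param path Output path.
#' @param k Contributors per component to embed (default 5, capped at the
#'   feature count).
#' @export
write_plsda_model <- function(model, path, k = 5) {
  k <- min(k, nrow(model$x_loadings))
  obj <- list(
    n_components = model$n_components,
    x_weights = model$x_weights, x_loadings = model$x_loadings,
    y_loadings = model$y_loadings,
    explained_x_variance = model$explained_x_variance,
    top_contributors = top_contributors(model, k))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
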