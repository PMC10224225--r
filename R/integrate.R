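#' Cross-omics Spearman correlation screen
#'
#' All feature-by-target (partial) Spearman correlations between a
#' transformed feature matrix (e.g. species CLR abundances) and a set of
#' continuous targets (e.g. metabolites), with one BH adjustment across
#' the whole screen. The typical use is identifying the species correlated
#' with a microbial metabolite before mutual-adjustment selection.
#'
#' @param features [transformed_matrix()] or matrix (samples x features).
#' @param targets [omics_matrix()] or matrix (samples x targets, complete).
#' @param covariates Optional covariate data.frame/matrix; when supplied,
#'   partial Spearman correlations are computed.
#' @param fdr Significance cutoff on the BH q-value (default 0.10).
#' @return data.frame: `feature_id`, `target_id`, `rho`, `p`, `q`,
#'   `significant`.
#' @export
correlation_screen <- function(features, targets, covariates = NULL,
                               fdr = 0.10) {
  fm <- as_values(features)
  tm <- as_values(targets)
  shared <- intersect(rownames(fm), rownames(tm))
  if (length(shared) < 10) stop("need at least 10 shared samples")
  fm <- fm[shared, , drop = FALSE]
  tm <- tm[shared, , drop = FALSE]
  if (anyNA(tm)) stop("targets must be complete; impute first")
  grid <- expand.grid(feature_id = colnames(fm), target_id = colnames(tm),
                      stringsAsFactors = FALSE)
  res <- mapply(function(f, t) {
    ps <- partial_spearman(fm[, f], tm[, t], covariates)
    c(ps$rho, ps$p)
  }, grid$feature_id, grid$target_id)
  grid$rho <- res[1, ]
  grid$p <- res[2, ]
  grid$q <- bh_fdr(grid$p)
  grid$significant <- grid$q < fdr
  grid
}

#' Mutual-adjustment (conditional) species selection
#'
#' Joint least-squares fit of a continuous target on all candidate species
#' simultaneously plus covariates; species whose joint-model coefficient
#' has p < `alpha` are declared independently associated, and their betas
#' become the weights of the gut-microbiota score. Aliased candidates in a
#' rank-deficient design are dropped with a warning and reported.
#'
#' @param target Numeric vector (e.g. metabolite level).
#' @param candidate_species [transformed_matrix()] or matrix of candidate
#'   abundances (typically INT-CLR).
#' @param covariates Optional covariate data.frame/matrix.
#' @param alpha Joint-model significance level (default 0.05).
#' @return List: `selected` (ids), `weights` (named betas of the selected
#'   set), `records` (per-candidate beta/se/p), `dropped` (aliased ids).
#' @export
conditional_selection <- function(target, candidate_species,
                                  covariates = NULL, alpha = 0.05) {
  Cm <- as_values(candidate_species)
  n <- length(target)
  Z <- make_design(covariates, n = n)
  if (n <= ncol(Cm) + ncol(Z) + 1) {
    stop("need n > candidates + covariates + 1 (",
         n, " <= ", ncol(Cm) + ncol(Z) + 1, ")")
  }
  X <- cbind(`(Intercept)` = 1, Cm, Z)
  qrx <- qr(X)
  dropped <- character(0)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    dropped <- intersect(aliased, colnames(Cm))
    warning("dropping aliased candidate(s): ", paste(dropped, collapse = ", "))
    Cm <- Cm[, setdiff(colnames(Cm), dropped), drop = FALSE]
    X <- cbind(`(Intercept)` = 1, Cm, Z)
    qrx <- qr(X)
    if (qrx$rank < ncol(X)) stop("design still rank-deficient after drop")
  }
  fit <- stats::lm.fit(X, target)
  df <- n - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  V <- chol2inv(qr.R(qrx)) * sigma2
  se <- sqrt(diag(V))
  idx <- seq_len(ncol(Cm)) + 1
  beta <- fit$coefficients[idx]
  sei <- se[idx]
  pv <- 2 * stats::pt(-abs(beta / sei), df)
  records <- data.frame(feature_id = colnames(Cm), beta = unname(beta),
                        se = unname(sei), p = unname(pv),
                        stringsAsFactors = FALSE)
  sel <- records$feature_id[records$p < alpha]
  list(selected = sel,
       weights = stats::setNames(records$beta[records$p < alpha], sel),
       records = records, dropped = dropped)
}

#' Weighted gut-microbiota score
#'
#' Per-sample weighted sum of (typically INT-CLR transformed) abundances
#' of a selected species set, the weights being the mutual-adjustment
#' regression betas. Standardized to unit sample SD by default so outcome
#' associations read per SD of the score.
#'
#' @param weights Named numeric vector (beta per species id).
#' @param abundance [transformed_matrix()] or matrix containing every
#'   species in `weights`.
#' @param standardize Divide by the sample SD of the score (default
#'   `TRUE`; skipped with a warning when the score is constant).
#' @return A `microbiota_score`: `species_ids`, `weights`, `score` (named
#'   per-sample vector), `standardized`.
#' @export
build_gmb_score <- function(weights, abundance, standardize = TRUE) {
  m <- as_values(abundance)
  missing_sp <- setdiff(names(weights), colnames(m))
  if (length(missing_sp)) {
    stop("species missing from abundance matrix: ",
         paste(missing_sp, collapse = ", "))
  }
  score <- if (length(weights)) {
    drop(m[, names(weights), drop = FALSE] %*% weights)
  } else rep(0, nrow(m))
  names(score) <- rownames(m)
  standardized <- FALSE
  if (standardize) {
    s <- stats::sd(score)
    if (s > 0) {
      score <- score / s
      standardized <- TRUE
    } else {
      warning("score has zero variance; standardization skipped")
    }
  }
  structure(list(species_ids = names(weights), weights = weights,
                 score = score, standardized = standardized),
            class = "microbiota_score")
}

#' @export
print.microbiota_score <- function(x, ...) {
  cat(sprintf("<microbiota_score> %d species, %d samples%s\n",
              length(x$species_ids), length(x$score),
              if (x$standardized) ", unit SD" else ""))
  invisible(x)
}

#' Hypergeometric EC-category enrichment
#'
#' Over-representation test of significant enzymes within EC level-III
#' categories. The universe N is all tested enzymes, the significant set n
#' is those with p < `alpha_feature`, and for a category containing K
#' enzymes of which k are significant the upper-tail p-value is
#' `P(X >= k)` under the hypergeometric distribution; BH adjustment is
#' applied across categories. Depletion is not tested.
#'
#' @param enzyme_records data.frame with `feature_id` and `p` columns
#'   (e.g. output of [logistic_screen()] or per-enzyme [fit_linear()]).
#' @param ec_map Named character vector mapping every tested enzyme id to
#'   exactly one EC level-III category (see [read_ec_map()]).
#' @param alpha_feature Enzyme-level significance cutoff (default 0.05).
#' @param fdr Category-level BH cutoff (default 0.10).
#' @return data.frame: `category_id`, `category_size`, `hits`,
#'   `significant_total`, `universe`, `p`, `q`, `enriched`.
#' @export
ec_enrichment <- function(enzyme_records, ec_map, alpha_feature = 0.05,
                          fdr = 0.10) {
  ids <- enzyme_records$feature_id
  unmapped <- setdiff(ids, names(ec_map))
  if (length(unmapped)) {
    stop("unmapped enzyme(s): ", paste(utils::head(unmapped, 10), collapse = ", "))
  }
  cat_of <- ec_map[ids]
  sig <- enzyme_records$p < alpha_feature
  N <- length(ids)
  n_sig <- sum(sig)
  cats <- sort(unique(cat_of))
  out <- lapply(cats, function(cc) {
    K <- sum(cat_of == cc)
    k <- sum(sig & cat_of == cc)
    p <- if (n_sig == 0) 1 else
      stats::phyper(k - 1, K, N - K, n_sig, lower.tail = FALSE)
    data.frame(category_id = cc, category_size = K, hits = k,
               significant_total = n_sig, universe = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$q <- bh_fdr(out$p)
  out$enriched <- out$q < fdr
  out
}

#' Sequential-adjustment attenuation of a species-outcome association
#'
#' Fits the base covariate-adjusted logistic model for one exposure and
#' the model further adjusted for extra terms (inflammation-profile
#' component scores, a metabolite, or both), and reports the percent
#' attenuation of the log-odds magnitude,
#' `100 (|beta_base| - |beta_adj|) / |beta_base|`. An adjuster nearly
#' collinear with the exposure (|r| > 0.99) is flagged with a warning in
#' the report rather than an error.
#'
#' @inheritParams fit_logistic
#' @param extra_adjusters Numeric vector or matrix of additional
#'   adjustment terms measured on the same samples.
#' @param adjustment_tag Label recorded on the report (e.g. `"plus_PCs"`,
#'   `"plus_metabolite"`, `"plus_both"`).
#' @return List: `base`, `adjusted` (association records),
#'   `percent_attenuation`, `adjustment_tag`, `collinearity_warning`.
#' @export
attenuation_analysis <- function(outcome, exposure, covariates = NULL,
                                 extra_adjusters,
                                 adjustment_tag = "plus_adjusters",
                                 feature_id = "exposure") {
  A <- if (is.matrix(extra_adjusters)) extra_adjusters else
    matrix(extra_adjusters, ncol = 1,
           dimnames = list(NULL, "adjuster1"))
  if (is.null(colnames(A))) colnames(A) <- paste0("adjuster", seq_len(ncol(A)))
  collin <- apply(A, 2, function(a) abs(stats::cor(a, exposure)) > 0.99)
  if (any(collin)) {
    warning("adjuster(s) nearly collinear with exposure: ",
            paste(colnames(A)[collin], collapse = ", "))
  }
  Z <- make_design(covariates, n = length(outcome))
  base <- fit_logistic(outcome, exposure, covariates = Z,
                       feature_id = feature_id, model_tag = "base")
  adj <- fit_logistic(outcome, exposure, covariates = cbind(Z, A),
                      feature_id = feature_id, model_tag = adjustment_tag)
  pa <- 100 * (abs(base$beta) - abs(adj$beta)) / abs(base$beta)
  list(base = base, adjusted = adj, percent_attenuation = pa,
       adjustment_tag = adjustment_tag,
       collinearity_warning = any(collin))
}
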