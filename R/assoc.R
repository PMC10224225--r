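#' @title Covariate-adjusted association models
#' @description Thin, fast wrappers around iteratively reweighted least
#'   squares and ordinary least squares that return one standardized
#'   association record per exposure: effect per SD, Wald 95% CI, p-value
#'   and (after [bh_fdr()]) a BH q-value. Every screen in the pipeline is
#'   built from these.
#' @name assoc
NULL

# Build a numeric design matrix (no intercept column) from a covariate
# data.frame/matrix. Categorical columns are reference-coded with the most
# frequent level as reference so the expansion is deterministic.
make_design <- function(covariates, n = NULL) {
  if (is.null(covariates)) {
    return(matrix(numeric(0), nrow = n %||% 0, ncol = 0))
  }
  if (is.matrix(covariates)) {
    storage.mode(covariates) <- "double"
    return(covariates)
  }
  stopifnot(is.data.frame(covariates))
  df <- as.data.frame(covariates)
  for (nm in names(df)) {
    if (is.character(df[[nm]]) || is.factor(df[[nm]]) || is.logical(df[[nm]])) {
      f <- as.factor(df[[nm]])
      ref <- names(which.max(table(f)))
      df[[nm]] <- stats::relevel(f, ref = ref)
    }
  }
  mm <- stats::model.matrix(~ ., data = df)
  mm[, -1, drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assoc_record <- function(feature_id, model_tag, beta, se, p,
                         logistic = TRUE, converged = TRUE) {
  data.frame(
    feature_id = feature_id, model_tag = model_tag,
    beta = beta, se = se,
    or_value = if (logistic) exp(beta) else NA_real_,
    ci_low = if (logistic) exp(beta - 1.96 * se) else beta - 1.96 * se,
    ci_high = if (logistic) exp(beta + 1.96 * se) else beta + 1.96 * se,
    p = p, q = NA_real_, converged = converged,
    stringsAsFactors = FALSE
  )
}

#' Covariate-adjusted logistic regression for one exposure
#'
#' Maximum-likelihood logistic fit (IRLS) of a binary outcome on a single
#' exposure plus covariates. The exposure is standardized to unit SD by
#' default so the odds ratio reads "per SD increment"; the CI is the Wald
#' interval `exp(beta +/- 1.96 se)`. Quasi-separation or non-convergence is
#' flagged on the returned record rather than raised.
#'
#' @param outcome 0/1 vector containing both classes.
#' @param exposure Numeric vector (non-constant).
#' @param covariates Optional data.frame or numeric matrix of adjustment
#'   covariates; categorical columns are reference-coded automatically.
#' @param standardize Divide the exposure by its SD before fitting
#'   (default `TRUE`).
#' @param feature_id,model_tag Labels copied onto the record.
#' @return One-row data.frame: `feature_id`, `model_tag`, `beta`, `se`,
#'   `or_value`, `ci_low`, `ci_high`, `p`, `q` (NA until [bh_fdr()]),
#'   `converged`.
#' @examples
#' # classic 2x2 table: 20/10 exposed cases/controls, 10/20 unexposed
#' y <- rep(c(1, 0, 1, 0), c(20, 10, 10, 20))
#' x <- rep(c(1, 1, 0, 0), c(20, 10, 10, 20))
#' fit_logistic(y, x, standardize = FALSE)  # OR = 4
#' @export
fit_logistic <- function(outcome, exposure, covariates = NULL,
                         standardize = TRUE, feature_id = "exposure",
                         model_tag = "model1") {
  outcome <- as.numeric(outcome)
  if (!all(outcome %in% c(0, 1))) stop("outcome must be coded 0/1")
  if (length(unique(outcome)) < 2) stop("outcome must contain both classes")
  if (stats::sd(exposure) == 0) stop("constant exposure")
  if (standardize) exposure <- exposure / stats::sd(exposure)
  Z <- make_design(covariates, n = length(outcome))
  X <- cbind(`(Intercept)` = 1, exposure = exposure, Z)
  fit <- suppressWarnings(stats::glm.fit(X, outcome, family = stats::binomial()))
  beta <- fit$coefficients["exposure"]
  w <- fit$weights
  V <- tryCatch(solve(crossprod(X * sqrt(w))), error = function(e) NULL)
  separated <- any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8)
  ok <- fit$converged && !is.null(V) && abs(beta) < 15 && !separated
  se <- if (!is.null(V)) sqrt(diag(V))["exposure"] else NA_real_
  p <- if (is.finite(se)) 2 * stats::pnorm(-abs(beta / se)) else NA_real_
  assoc_record(feature_id, model_tag, unname(beta), unname(se), unname(p),
               logistic = TRUE, converged = ok)
}

#' Covariate-adjusted linear regression for one exposure
#'
#' OLS fit of a continuous response on one exposure plus covariates; the
#' CI columns hold `beta +/- 1.96 se` and `or_value` is `NA`. A
#' rank-deficient design is an error naming the aliased columns.
#'
#' @inheritParams fit_logistic
#' @param response Numeric response vector.
#' @param standardize Standardize the exposure to unit SD (default `TRUE`).
#' @return One-row association record (see [fit_logistic()]).
#' @export
fit_linear <- function(response, exposure, covariates = NULL,
                       standardize = TRUE, feature_id = "exposure",
                       model_tag = "model1") {
  if (stats::sd(exposure) == 0) stop("constant exposure")
  if (standardize) exposure <- exposure / stats::sd(exposure)
  Z <- make_design(covariates, n = length(response))
  X <- cbind(`(Intercept)` = 1, exposure = exposure, Z)
  if (nrow(X) <= ncol(X)) stop("n must exceed the number of parameters")
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("rank-deficient design; aliased: ", paste(aliased, collapse = ", "))
  }
  fit <- stats::lm.fit(X, response)
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  V <- chol2inv(qr.R(qrx)) * sigma2
  se <- sqrt(diag(V))[2]
  beta <- fit$coefficients["exposure"]
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  assoc_record(feature_id, model_tag, unname(beta), unname(se), unname(p),
               logistic = FALSE)
}

#' Per-feature covariate-adjusted logistic screen
#'
#' Runs [fit_logistic()] across every column of a transformed feature
#' matrix against the same outcome and covariates, then attaches BH
#' q-values across the screen. Shares one design matrix across features,
#' so it is the fast path for genome-wide-style screens.
#'
#' @param features [transformed_matrix()] or numeric matrix
#'   (samples x features), e.g. CLR abundances.
#' @param outcome 0/1 vector.
#' @param covariates Optional covariate data.frame/matrix.
#' @param model_tag Label for the records.
#' @return data.frame of association records, one row per feature, with
#'   `q` filled by [bh_fdr()].
#' @export
logistic_screen <- function(features, outcome, covariates = NULL,
                            model_tag = "model1") {
  m <- as_values(features)
  Z <- make_design(covariates, n = length(outcome))
  recs <- lapply(colnames(m), function(f) {
    fit_logistic(outcome, m[, f], covariates = Z, feature_id = f,
                 model_tag = model_tag)
  })
  out <- do.call(rbind, recs)
  out$q <- bh_fdr(out$p)
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH q-values: `q_(i) = min_{j >= i} p_(j) m / j`, capped at 1 and
#' mapped back to the input order. Monotone: a larger p never receives a
#' smaller q.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Partial Spearman correlation
#'
#' Ranks `x` and `y` (average ranks on ties), residualizes both rank
#' vectors on the covariates by OLS, and returns the Pearson correlation
#' of the residuals with a t-based p-value on `n - 2 - k` degrees of
#' freedom (k = number of covariate columns). With no covariates this is
#' the ordinary Spearman rank correlation.
#'
#' @param x,y Numeric vectors (non-constant).
#' @param covariates Optional covariate data.frame/matrix.
#' @return List with elements `rho` and `p`.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input vector")
  n <- length(x)
  Z <- make_design(covariates, n = n)
  if (n < ncol(Z) + 3) stop("need n >= covariate count + 3")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (ncol(Z) > 0) {
    X <- cbind(1, Z)
    rx <- stats::lm.fit(X, rx)$residuals
    ry <- stats::lm.fit(X, ry)$residuals
  } else {
    rx <- rx - mean(rx)
    ry <- ry - mean(ry)
  }
  rho <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  df <- n - 2 - ncol(Z)
  tval <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  list(rho = rho, p = 2 * stats::pt(-abs(tval), df))
}

#' Effect-modification (interaction) test
#'
#' Fits the logistic model with an exposure-by-modifier product term and
#' returns the Wald p-value for the product together with per-stratum
#' association records, the standard check that an exposure-outcome
#' association is homogeneous across, e.g., serostatus strata.
#'
#' @inheritParams fit_logistic
#' @param modifier Binary 0/1 vector; both strata must contain both
#'   outcome classes.
#' @return List: `p_interaction`, `stratum_records` (data.frame with one
#'   record per modifier stratum, tagged `stratum0`/`stratum1`).
#' @export
interaction_test <- function(outcome, exposure, modifier, covariates = NULL) {
  modifier <- as.numeric(modifier)
  if (length(unique(modifier)) < 2) stop("modifier is constant")
  for (s in c(0, 1)) {
    if (length(unique(outcome[modifier == s])) < 2) {
      stop("stratum ", s, " lacks one outcome class")
    }
  }
  if (stats::sd(exposure) == 0) stop("constant exposure")
  exposure <- exposure / stats::sd(exposure)
  Z <- make_design(covariates, n = length(outcome))
  X <- cbind(`(Intercept)` = 1, exposure = exposure, modifier = modifier,
             `exposure:modifier` = exposure * modifier, Z)
  fit <- suppressWarnings(stats::glm.fit(X, outcome, family = stats::binomial()))
  V <- solve(crossprod(X * sqrt(fit$weights)))
  z <- fit$coefficients["exposure:modifier"] /
    sqrt(diag(V))["exposure:modifier"]
  strata <- do.call(rbind, lapply(c(0, 1), function(s) {
    idx <- modifier == s
    cv <- if (ncol(Z)) Z[idx, , drop = FALSE] else NULL
    fit_logistic(outcome[idx], exposure[idx], covariates = cv,
                 standardize = FALSE, feature_id = "exposure",
                 model_tag = paste0("stratum", s))
  }))
  list(p_interaction = unname(2 * stats::pnorm(-abs(z))),
       stratum_records = strata)
}

#' Quartile grouping of a continuous variable
#'
#' Splits a vector at its empirical quartiles into `low` (quartile 1),
#' `medium` (quartiles 2-3) and `high` (quartile 4); values tied with a
#' boundary quartile fall into the lower group.
#'
#' @param values Numeric vector with at least 4 distinct values.
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
quartile_groups <- function(values) {
  if (length(unique(values)) < 4) stop("need at least 4 distinct values")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE)
  factor(ifelse(values <= q[1], "low",
                ifelse(values <= q[2], "medium", "high")),
         levels = c("low", "medium", "high"))
}

#' Covariate-adjusted group means
#'
#' Linear model of the response on group indicators plus covariates; the
#' adjusted mean of each group is the model prediction at the covariate
#' means, with a 95% CI from the prediction standard error. With no
#' covariates the adjusted means equal the raw group means.
#'
#' @param response Numeric vector.
#' @param groups Factor or character group labels (every group non-empty).
#' @param covariates Optional covariate data.frame/matrix.
#' @return data.frame: `group`, `n`, `mean`, `ci_low`, `ci_high`.
#' @export
adjusted_group_means <- function(response, groups, covariates = NULL) {
  groups <- as.factor(groups)
  if (any(table(groups) == 0)) stop("every group must be non-empty")
  Z <- make_design(covariates, n = length(response))
  G <- stats::model.matrix(~ 0 + groups)
  colnames(G) <- levels(groups)
  X <- cbind(G, Z)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) stop("group indicators aliased with covariates")
  fit <- stats::lm.fit(X, response)
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  V <- chol2inv(qr.R(qrx)) * sigma2
  zbar <- if (ncol(Z)) colMeans(Z) else numeric(0)
  out <- lapply(levels(groups), function(g) {
    cvec <- stats::setNames(numeric(ncol(X)), colnames(X))
    cvec[g] <- 1
    if (length(zbar)) cvec[names(zbar)] <- zbar
    mu <- sum(cvec * fit$coefficients)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    data.frame(group = g, n = sum(groups == g), mean = mu,
               ci_low = mu - 1.96 * se, ci_high = mu + 1.96 * se,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write association records as TSV
#'
#' Fixed column order: feature, model, beta, se, or, ci_low, ci_high, p, q.
#'
#' @param records data.frame of association records.
#' @param path Output path.
#' @export
write_association_records <- function(records, path) {
  cols <- c("feature_id", "model_tag", "beta", "se", "or_value",
            "ci_low", "ci_high", "p", "q")
  utils::write.table(records[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
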