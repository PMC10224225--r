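#' Kruskal-Wallis rank test
#'
#' Chi-square approximation with tie correction (delegates to
#' [stats::kruskal.test()]); the nonparametric prefilter of the LDA
#' effect-size screen.
#'
#' @param values Numeric vector.
#' @param classes Group labels (at least 2 non-empty classes).
#' @return p-value.
#' @export
kruskal_wallis <- function(values, classes) {
  classes <- factor(classes)
  if (nlevels(classes) < 2) stop("need at least 2 classes")
  # identical distributions in every class: H = 0, p = 1 (kruskal.test
  # returns NaN when all values are tied, so short-circuit)
  if (length(unique(values)) == 1) return(1)
  stats::kruskal.test(values, classes)$p.value
}

#' Two-class LDA effect-size (LefSe-style) differential-abundance screen
#'
#' A documented, reproducible variant of the LDA effect-size procedure for
#' a two-class design without subclasses:
#' \enumerate{
#'   \item per-feature Kruskal-Wallis prefilter at `alpha`;
#'   \item relative abundances rescaled so the table maximum maps to 1e6;
#'   \item `n_bootstrap` class-stratified subsamples of 2/3 of the
#'     samples; on each, a ridge-regularized two-class linear discriminant
#'     (pooled within-class covariance plus `1e-3 * trace / m` on the
#'     diagonal) over the surviving features; the per-feature effect is
#'     `|(w_f + dmu_f) / 2|` where `w_f` is the discriminant coefficient
#'     and `dmu_f` the class-mean difference on the scaled data;
#'   \item `lda_score = log10(1 + mean bootstrap effect)`, signed positive
#'     for features enriched in class 1 (cases).
#' }
#' A feature passes when `|lda_score| > threshold` (strict) and its
#' Kruskal-Wallis p is below `alpha`. Deterministic given `seed` and
#' invariant to sample order.
#'
#' @param table [count_table()] of relative abundances or counts (rows are
#'   renormalized to proportions).
#' @param classes Binary labels; coerced to factor, the second level is
#'   treated as the case class.
#' @param alpha Kruskal-Wallis prefilter level (default 0.05).
#' @param n_bootstrap Number of subsamples (default 30).
#' @param threshold log10 effect-size cutoff (default 3.0).
#' @param seed Integer seed for the subsampling.
#' @return data.frame: `feature_id`, `kw_p`, `lda_score`,
#'   `enriched_class`, `passes_threshold`; empty when no feature passes
#'   the prefilter.
#' @export
lefse_lda_scores <- function(table, classes, alpha = 0.05, n_bootstrap = 30,
                             threshold = 3.0, seed = 1L) {
  m <- as_values(table)
  classes <- factor(classes)
  if (nlevels(classes) != 2) stop("unsupported design: need exactly 2 classes")
  rel <- m / rowSums(m)
  # sample-order invariance: fix a canonical ordering before subsampling
  ord <- order(rownames(rel))
  rel <- rel[ord, , drop = FALSE]
  classes <- classes[ord]

  kw_p <- apply(rel, 2, kruskal_wallis, classes = classes)
  surv <- names(kw_p)[kw_p < alpha]
  if (!length(surv)) {
    return(data.frame(feature_id = character(), kw_p = numeric(),
                      lda_score = numeric(), enriched_class = character(),
                      passes_threshold = logical(), stringsAsFactors = FALSE))
  }
  scaled <- rel[, surv, drop = FALSE] * (1e6 / max(rel))
  case <- levels(classes)[2]
  idx0 <- which(classes != case)
  idx1 <- which(classes == case)
  mfeat <- length(surv)

  set.seed(seed)
  eff <- matrix(0, n_bootstrap, mfeat, dimnames = list(NULL, surv))
  for (b in seq_len(n_bootstrap)) {
    s0 <- sample(idx0, max(2, floor(2 / 3 * length(idx0))))
    s1 <- sample(idx1, max(2, floor(2 / 3 * length(idx1))))
    X0 <- scaled[s0, , drop = FALSE]
    X1 <- scaled[s1, , drop = FALSE]
    mu0 <- colMeans(X0)
    mu1 <- colMeans(X1)
    S <- ((nrow(X0) - 1) * stats::cov(X0) + (nrow(X1) - 1) * stats::cov(X1)) /
      (nrow(X0) + nrow(X1) - 2)
    lambda <- 1e-3 * sum(diag(S)) / mfeat
    w <- solve(S + diag(lambda, mfeat), mu1 - mu0)
    eff[b, ] <- abs((w + (mu1 - mu0)) / 2)
  }
  mean_eff <- colMeans(eff)
  dmu_full <- colMeans(scaled[idx1, , drop = FALSE]) -
    colMeans(scaled[idx0, , drop = FALSE])
  score <- log10(1 + mean_eff) * ifelse(dmu_full >= 0, 1, -1)
  out <- data.frame(
    feature_id = surv, kw_p = unname(kw_p[surv]), lda_score = unname(score),
    enriched_class = ifelse(dmu_full >= 0, case, levels(classes)[1]),
    stringsAsFactors = FALSE)
  out$passes_threshold <- abs(out$lda_score) > threshold & out$kw_p < alpha
  rownames(out) <- NULL
  out
}

#' Covariate-adjusted pairwise log-ratio W statistic (ANCOM-style)
#'
#' For every feature pair (i, j) a linear model
#' `ln(x_i / x_j) ~ outcome + covariates` is fitted and the outcome
#' p-value collected; within feature i, its m - 1 pairwise p-values are
#' BH-adjusted and `W_i` counts those below `alpha`. A feature is
#' "detected" at cutoff f when `W_i / (m - 1) >= f`. All pairwise fits
#' share one design matrix, so the whole screen is a single multi-response
#' least-squares solve. W values are invariant to per-sample scaling of
#' the composition (a log-ratio identity).
#'
#' @param table [count_table()] of strictly positive abundances (apply
#'   zero replacement first, e.g. the CLR convention of half the smallest
#'   nonzero value).
#' @param outcome 0/1 vector.
#' @param covariates Optional covariate data.frame/matrix.
#' @param alpha Per-pair significance level (default 0.05).
#' @param detection_levels Cutoffs reported in `detected_at`
#'   (default 0.6, 0.7, 0.8, 0.9).
#' @return data.frame: `feature_id`, `W`, `detected_at` (comma-separated
#'   cutoffs reached, `""` when none).
#' @export
ancom_w <- function(table, outcome, covariates = NULL, alpha = 0.05,
                    detection_levels = c(0.6, 0.7, 0.8, 0.9)) {
  m <- as_values(table)
  if (ncol(m) < 3) stop("need at least 3 features")
  if (any(m <= 0)) stop("abundances must be strictly positive; replace zeros first")
  L <- log(m)
  n <- nrow(L)
  p <- ncol(L)
  Z <- make_design(covariates, n = n)
  X <- cbind(1, outcome = as.numeric(outcome), Z)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) stop("rank-deficient covariate design")
  df <- n - ncol(X)
  XtXinv_oo <- chol2inv(qr.R(qrx))[2, 2]

  pairs <- utils::combn(p, 2)
  Y <- L[, pairs[1, ], drop = FALSE] - L[, pairs[2, ], drop = FALSE]
  B <- qr.coef(qrx, Y)
  R <- Y - X %*% B
  sigma2 <- colSums(R^2) / df
  se <- sqrt(sigma2 * XtXinv_oo)
  tstat <- B[2, ] / se
  pv <- 2 * stats::pt(-abs(tstat), df)

  W <- integer(p)
  for (i in seq_len(p)) {
    sel <- pairs[1, ] == i | pairs[2, ] == i
    W[i] <- sum(bh_fdr(pv[sel]) < alpha)
  }
  frac <- W / (p - 1)
  detected <- vapply(frac, function(f) {
    paste(detection_levels[f >= detection_levels], collapse = ",")
  }, character(1))
  data.frame(feature_id = colnames(m), W = W, detected_at = detected,
             stringsAsFactors = FALSE)
}
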