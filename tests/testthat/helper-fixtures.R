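# Shared fixtures and independent oracles used across test files.

# small named abundance matrix
toy_matrix <- function(n = 6, p = 4, seed = 42, counts = TRUE) {
  set.seed(seed)
  m <- matrix(if (counts) rpois(n * p, 20) + 1 else runif(n * p), n, p,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("f%02d", seq_len(p))))
  m
}

# a cohort config scaled for unit tests; moderate fixed sparsity so every
# planted species stays observable at small n
test_config <- function(seed = 1, n_samples = 120, n_species = 40, ...) {
  cohort_config(n_samples = n_samples, n_species = n_species,
                n_enzymes = 10, n_proteins = 8, n_metabolites = 10,
                sparsity = rep(0.3, n_species), seed = seed, ...)
}

no_effect <- function(n_species = 40) {
  list(species_plaque_effects = stats::setNames(numeric(0), character(0)),
       covariate_effects = rep(0, 4),
       producer_weights = stats::setNames(numeric(0), character(0)),
       carrier_weights = stats::setNames(numeric(0), character(0)))
}

# independent partial-Spearman oracle: explicit ranks, lm() residuals,
# cor() of residuals; written against base model-fitting, not lm.fit paths
oracle_partial_spearman <- function(x, y, Z = NULL) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (is.null(Z)) return(stats::cor(rx, ry))
  ex <- stats::residuals(stats::lm(rx ~ Z))
  ey <- stats::residuals(stats::lm(ry ~ Z))
  stats::cor(ex, ey)
}

# hand step-up BH: q_(i) = min_{j>=i} p_(j) * m / j, mapped to input order
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(1, q_sorted)[order(o)]
}

# exhaustive hypergeometric upper tail via binomial coefficients
oracle_hyper_upper <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
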