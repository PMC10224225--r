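test_that("logistic fit reproduces the closed-form 2x2 odds ratio and Woolf SE", {
  y <- rep(c(1, 0, 1, 0), c(20, 10, 10, 20))
  x <- rep(c(1, 1, 0, 0), c(20, 10, 10, 20))
  rec <- fit_logistic(y, x, standardize = FALSE)
  expect_equal(rec$or_value, 4.0, tolerance = 1e-6)
  expect_equal(rec$beta, log(4), tolerance = 1e-6)
  expect_equal(rec$se, sqrt(1 / 20 + 1 / 10 + 1 / 10 + 1 / 20),
               tolerance = 1e-6)
  expect_equal(rec$ci_low, exp(rec$beta - 1.96 * rec$se))
  expect_true(rec$converged)
})

test_that("logistic fit guards degenerate inputs and flags separation", {
  y <- rep(0:1, each = 10)
  expect_error(fit_logistic(y, rep(1, 20)), "constant")
  expect_error(fit_logistic(rep(1, 20), rnorm(20)), "both classes")
  # perfect separation: flagged, not an error
  rec <- fit_logistic(y, c(rnorm(10, -5), rnorm(10, 5)))
  expect_false(rec$converged)
})

test_that("linear fit matches the normal-equations oracle on a small dataset", {
  set.seed(8)
  n <- 8
  x <- rnorm(n); z <- rnorm(n)
  y <- 1 + 0.5 * x - 0.3 * z + rnorm(n, 0, 0.2)
  rec <- fit_linear(y, x, covariates = cbind(z = z), standardize = FALSE)
  X <- cbind(1, x, z)
  beta_hat <- solve(t(X) %*% X, t(X) %*% y)  # explicit normal equations
  expect_equal(rec$beta, as.numeric(beta_hat[2, 1]), tolerance = 1e-8)
  expect_true(is.na(rec$or_value))

  # exact fit: beta = 2, zero residual variance
  rec2 <- fit_linear(2 * x, x, standardize = FALSE)
  expect_equal(rec2$beta, 2, tolerance = 1e-10)
  expect_lt(rec2$se, 1e-8)
})

test_that("linear fit names aliased columns in a rank-deficient design", {
  x <- rnorm(20)
  expect_error(fit_linear(rnorm(20), x, covariates = cbind(dup = x)), "dup")
})

test_that("partial Spearman reduces to Spearman and matches the brute-force oracle", {
  set.seed(12)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(partial_spearman(x, y)$rho,
               cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_equal(partial_spearman(x, exp(x))$rho, 1)

  # n = 12 with one covariate and ties, against the explicit oracle
  x12 <- c(rnorm(10), 1.5, 1.5)
  z12 <- rnorm(12)
  y12 <- 0.4 * x12 + 0.8 * z12 + rnorm(12)
  got <- partial_spearman(x12, y12, covariates = cbind(z = z12))
  expect_equal(got$rho, oracle_partial_spearman(x12, y12, cbind(z12)),
               tolerance = 1e-10)
})

test_that("partial Spearman is invariant to strictly monotone transforms", {
  set.seed(13)
  x <- rexp(25); y <- rnorm(25); z <- rnorm(25)
  base <- partial_spearman(x, y, cbind(z))$rho
  expect_equal(partial_spearman(log(x), y, cbind(z))$rho, base,
               tolerance = 1e-12)
  expect_equal(partial_spearman(x, y^3, cbind(z))$rho, base,
               tolerance = 1e-12)
  expect_error(partial_spearman(rep(1, 25), y), "constant")
})

test_that("BH adjustment matches hand enumeration and its properties", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(14)
  for (rep in 1:5) {
    p <- runif(50)
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone
  }
})

test_that("interaction test detects opposite-sign effects and guards strata", {
  set.seed(15)
  hits <- 0
  for (rep in 1:10) {
    n <- 1000
    g <- rbinom(n, 1, 0.5)
    x <- rnorm(n)
    eta <- -1 + log(2) * x * (2 * g - 1)     # +/- ln 2 by stratum
    y <- rbinom(n, 1, plogis(eta))
    res <- interaction_test(y, x, g)
    if (res$p_interaction < 0.05) hits <- hits + 1
    expect_identical(res$stratum_records$model_tag, c("stratum0", "stratum1"))
  }
  expect_gte(hits, 8)
  expect_error(interaction_test(rbinom(50, 1, 0.5), rnorm(50), rep(1, 50)),
               "constant")
})

test_that("quartile groups split low / medium / high with ties to the lower group", {
  expect_equal(as.vector(table(quartile_groups(1:8))), c(2, 4, 2))
  expect_equal(as.vector(table(quartile_groups(sample(1:100)))), c(25, 50, 25))
  expect_error(quartile_groups(c(1, 1, 2, 2, 3)), "4 distinct")

  # ties straddling the first quartile: brute-force rule application
  v <- c(1, 2, 2, 2, 5, 6, 7, 8, 9, 10, 11, 12)
  q1 <- quantile(v, 0.25, names = FALSE)
  q3 <- quantile(v, 0.75, names = FALSE)
  expected <- ifelse(v <= q1, "low", ifelse(v <= q3, "medium", "high"))
  expect_identical(as.character(quartile_groups(v)), expected)
})

test_that("adjusted group means reduce to raw means and respect balance", {
  set.seed(16)
  g <- rep(c("low", "medium", "high"), each = 20)
  y <- rnorm(60, mean = rep(c(1, 2, 3), each = 20))
  out <- adjusted_group_means(y, g)
  raw <- tapply(y, g, mean)
  expect_equal(out$mean, as.numeric(raw[out$group]), tolerance = 1e-10)

  # balanced covariate: adjusted means stay within MC error of raw means
  z <- rep(rnorm(20), 3)   # identical covariate distribution per group
  y2 <- y + 0.8 * z
  out2 <- adjusted_group_means(y2, g, covariates = cbind(z = z))
  raw2 <- tapply(y2, g, mean)
  expect_equal(out2$mean, as.numeric(raw2[out2$group]), tolerance = 0.2)
  expect_true(all(out2$ci_low < out2$mean & out2$mean < out2$ci_high))

  expect_error(adjusted_group_means(y, factor(g, levels = c(unique(g), "empty"))),
               "non-empty")
})
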