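test_that("correlation screen matches elementwise partial Spearman calls", {
  set.seed(60)
  n <- 40
  fm <- matrix(rnorm(n * 5), n, 5,
               dimnames = list(sprintf("s%02d", 1:n), paste0("sp", 1:5)))
  tm <- matrix(rnorm(n * 3), n, 3,
               dimnames = list(sprintf("s%02d", 1:n), paste0("met", 1:3)))
  z <- data.frame(age = rnorm(n))
  out <- correlation_screen(fm, tm, covariates = z)
  expect_equal(nrow(out), 15)
  for (i in seq_len(nrow(out))) {
    ps <- partial_spearman(fm[, out$feature_id[i]], tm[, out$target_id[i]], z)
    expect_equal(out$rho[i], ps$rho, tolerance = 1e-12)
    expect_equal(out$p[i], ps$p, tolerance = 1e-12)
  }
  expect_equal(out$q, bh_fdr(out$p))
})

test_that("a noise-free monotone pair dominates the screen", {
  set.seed(61)
  n <- 30
  fm <- matrix(rnorm(n * 4), n, 4,
               dimnames = list(sprintf("s%02d", 1:n), paste0("sp", 1:4)))
  tm <- cbind(target = exp(fm[, "sp2"]))
  rownames(tm) <- rownames(fm)
  out <- correlation_screen(fm, tm)
  hit <- out[out$feature_id == "sp2", ]
  expect_equal(hit$rho, 1)
  expect_equal(which.min(out$q), which(out$feature_id == "sp2"))
  expect_true(hit$significant)

  rownames(tm) <- sprintf("x%02d", 1:n)
  expect_error(correlation_screen(fm, tm), "shared samples")
})

test_that("conditional selection reduces to the marginal model for one candidate", {
  set.seed(62)
  n <- 100
  x <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "sp1"))
  y <- 0.4 * x[, 1] + rnorm(n)
  sel <- conditional_selection(y, x)
  marg <- fit_linear(y, x[, 1], standardize = FALSE)
  expect_equal(sel$records$beta, marg$beta, tolerance = 1e-10)
  expect_equal(sel$records$p, marg$p, tolerance = 1e-10)
  expect_identical(sel$selected, "sp1")
})

test_that("conditional selection separates a collinear pair and guards dimensions", {
  set.seed(63)
  correct <- 0
  for (rep in 1:10) {
    n <- 1000
    causal <- rnorm(n)
    shadow <- 0.8 * causal + sqrt(1 - 0.64) * rnorm(n)   # r = 0.8
    y <- 0.5 * causal + rnorm(n)
    X <- cbind(causal = causal, shadow = shadow)
    sel <- conditional_selection(y, X)
    if ("causal" %in% sel$selected && !("shadow" %in% sel$selected)) {
      correct <- correct + 1
    }
  }
  expect_gte(correct, 8)

  Xs <- matrix(rnorm(20 * 19), 20, 19,
               dimnames = list(NULL, paste0("c", 1:19)))
  expect_error(conditional_selection(rnorm(20), Xs), "candidates")
})

test_that("orthogonal candidates reproduce the marginally significant set", {
  set.seed(64)
  n <- 200
  Q <- qr.Q(qr(matrix(rnorm(n * 6), n, 6)))   # exactly orthogonal columns
  colnames(Q) <- paste0("sp", 1:6)
  y <- drop(Q %*% c(3, 0, 2.5, 0, 0, 0)) + rnorm(n, 0, 0.5)
  joint <- conditional_selection(y, Q)
  marginal <- vapply(colnames(Q), function(f) {
    fit_linear(y, Q[, f], standardize = FALSE)$p < 0.05
  }, logical(1))
  expect_setequal(joint$selected, names(which(marginal)))
})

test_that("aliased candidates are dropped with a warning and reported", {
  set.seed(65)
  n <- 50
  a <- rnorm(n)
  X <- cbind(a = a, b = rnorm(n), dup = a)
  expect_warning(sel <- conditional_selection(rnorm(n), X), "dup")
  expect_identical(sel$dropped, "dup")
  expect_setequal(sel$records$feature_id, c("a", "b"))
})

test_that("the microbiota score is a weighted sum with expected identities", {
  set.seed(66)
  m <- matrix(rnorm(50 * 4), 50, 4,
              dimnames = list(sprintf("s%02d", 1:50), paste0("sp", 1:4)))
  zero <- build_gmb_score(setNames(numeric(2), c("sp1", "sp2")), m,
                          standardize = FALSE)
  expect_true(all(zero$score == 0))

  single <- build_gmb_score(c(sp3 = 1), m, standardize = FALSE)
  expect_equal(unname(single$score), unname(m[, "sp3"]))

  # linearity in the weights
  w1 <- c(sp1 = 0.5, sp2 = -1)
  w2 <- c(sp1 = 0.2, sp2 = 0.4)
  s12 <- build_gmb_score(w1 + w2, m, standardize = FALSE)$score
  expect_equal(s12, build_gmb_score(w1, m, standardize = FALSE)$score +
                 build_gmb_score(w2, m, standardize = FALSE)$score,
               tolerance = 1e-12)

  std <- build_gmb_score(w1, m, standardize = TRUE)
  expect_equal(sd(std$score), 1, tolerance = 1e-12)
  expect_error(build_gmb_score(c(zz = 1), m), "zz")
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  # worked example: N=20, K=5, n=8, k=5
  recs <- data.frame(feature_id = sprintf("e%02d", 1:20),
                     p = c(rep(0.001, 8), rep(0.5, 12)))
  ec_map <- setNames(c(rep("EC A", 5), rep("EC B", 15)), recs$feature_id)
  # the 5 EC A enzymes are all inside the significant 8
  out <- ec_enrichment(recs, ec_map)
  pa <- out$p[out$category_id == "EC A"]
  expect_equal(pa, 455 / 125970, tolerance = 1e-10)
  expect_equal(pa, oracle_hyper_upper(5, 5, 20, 8), tolerance = 1e-12)

  # exhaustive agreement for all universes N <= 25
  set.seed(67)
  for (N in c(5, 10, 17, 25)) {
    for (rep in 1:5) {
      K <- sample(1:(N - 1), 1)
      nsig <- sample(0:N, 1)
      ids <- sprintf("z%02d", 1:N)
      map <- setNames(ifelse(seq_len(N) <= K, "in", "out"), ids)
      pvals <- rep(0.9, N)
      pvals[sample(N, nsig)] <- 0.001
      rr <- data.frame(feature_id = ids, p = pvals)
      got <- ec_enrichment(rr, map)
      k <- sum(pvals[seq_len(K)] < 0.05)
      expected <- if (nsig == 0) 1 else oracle_hyper_upper(k, K, N, nsig)
      expect_equal(got$p[got$category_id == "in"], expected,
                   tolerance = 1e-12)
    }
  }
})

test_that("enrichment edge cases: no significant enzymes, unmapped ids", {
  recs <- data.frame(feature_id = c("a", "b", "c"), p = c(0.5, 0.9, 0.7))
  map <- setNames(rep("EC X", 3), recs$feature_id)
  out <- ec_enrichment(recs, map)
  expect_equal(out$p, 1)
  expect_false(out$enriched)
  expect_error(ec_enrichment(recs, map[1:2]), "unmapped")
})

test_that("attenuation follows its formula and detects full mediation", {
  set.seed(68)
  n <- 4000
  x <- rnorm(n)
  mediator <- x + rnorm(n, 0, 0.2)       # exposure -> mediator -> outcome
  y <- rbinom(n, 1, plogis(-1 + 1.2 * mediator))
  res <- attenuation_analysis(y, x, extra_adjusters = cbind(med = mediator),
                              adjustment_tag = "plus_metabolite")
  expect_gt(res$percent_attenuation, 70)

  noise <- rnorm(n)
  res0 <- attenuation_analysis(y, x, extra_adjusters = cbind(noise = noise))
  expect_lt(abs(res0$percent_attenuation), 15)

  expect_warning(
    attenuation_analysis(y, x, extra_adjusters = cbind(same = x + rnorm(n, 0, 1e-4))),
    "collinear")
})

test_that("percent attenuation hits its closed-form anchors", {
  # formula check: 0.4 -> 0.3 is 25% attenuation
  expect_equal(100 * (abs(0.4) - abs(0.3)) / abs(0.4), 25)
  set.seed(69)
  n <- 500
  x <- rnorm(n); y <- rbinom(n, 1, plogis(-1 + 0.5 * x))
  same <- attenuation_analysis(y, x, extra_adjusters = cbind(z = rep(c(0, 1), n / 2)))
  expect_equal(same$base$beta, same$adjusted$beta, tolerance = 0.2)
})
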