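test_that("Kruskal-Wallis handles identical, separated and enumerated cases", {
  expect_equal(kruskal_wallis(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3)), 1)
  expect_equal(kruskal_wallis(rep(5, 10), rep(c("a", "b"), each = 5)), 1)
  expect_lt(kruskal_wallis(c(rnorm(10), rnorm(10) + 50),
                           rep(c("a", "b"), each = 10)), 0.001)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "2 classes")

  # small-n agreement with the explicit rank-statistic formula (with tie
  # correction), computed independently in the test
  set.seed(30)
  for (rep in 1:5) {
    v <- sample(1:6, 8, replace = TRUE)
    g <- rep(c("a", "b"), each = 4)
    r <- rank(v)
    n <- length(v)
    h <- (12 / (n * (n + 1))) *
      sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
    ties <- table(v)
    h <- h / (1 - sum(ties^3 - ties) / (n^3 - n))
    p_oracle <- pchisq(h, df = 1, lower.tail = FALSE)
    expect_equal(kruskal_wallis(v, g), p_oracle, tolerance = 1e-12)
  }
})

make_lefse_table <- function(n_per_class = 20, seed = 33, delta = 0.1) {
  set.seed(seed)
  n <- 2 * n_per_class
  base <- matrix(runif(n * 4, 0.05, 0.15), n, 4)
  sig <- c(rep(0.2, n_per_class), rep(0.2 + delta, n_per_class)) +
    rnorm(n, 0, 0.005)
  m <- cbind(sig = sig, base)
  colnames(m) <- c("sig", paste0("bg", 1:4))
  rownames(m) <- sprintf("s%02d", 1:n)
  m <- m / rowSums(m)
  list(table = count_table(m, "species", relative = TRUE),
       classes = rep(c(0, 1), each = n_per_class))
}

test_that("LDA effect-size screen scores a planted feature at the expected magnitude", {
  fx <- make_lefse_table()
  res <- lefse_lda_scores(fx$table, fx$classes, seed = 7)
  sig <- res[res$feature_id == "sig", ]
  expect_equal(nrow(sig), 1)
  # class-mean difference on the 1e6 scale is ~1e5, so log10(1 + effect)
  # should land near 5
  expect_gt(sig$lda_score, 4.5)
  expect_lt(sig$lda_score, 5.5)
  expect_true(sig$passes_threshold)
  expect_equal(sig$enriched_class, "1")
})

test_that("LDA screen returns empty on exchangeable classes and respects the strict cutoff", {
  set.seed(34)
  m <- matrix(runif(40 * 5), 40, 5,
              dimnames = list(sprintf("s%02d", 1:40), paste0("f", 1:5)))
  m <- m / rowSums(m)
  res <- lefse_lda_scores(count_table(m, "species", relative = TRUE),
                          rep(c(0, 1), 20), seed = 2)
  expect_equal(nrow(res), 0)

  # strict inequality: a score exactly at the cutoff does not pass
  fx <- make_lefse_table()
  base <- lefse_lda_scores(fx$table, fx$classes, seed = 7)
  s <- abs(base$lda_score[base$feature_id == "sig"])
  at <- lefse_lda_scores(fx$table, fx$classes, seed = 7, threshold = s)
  below <- lefse_lda_scores(fx$table, fx$classes, seed = 7,
                            threshold = s - 1e-6)
  expect_false(at$passes_threshold[at$feature_id == "sig"])
  expect_true(below$passes_threshold[below$feature_id == "sig"])
})

test_that("LDA screen is reproducible and invariant to sample order", {
  fx <- make_lefse_table()
  a <- lefse_lda_scores(fx$table, fx$classes, seed = 11)
  b <- lefse_lda_scores(fx$table, fx$classes, seed = 11)
  expect_identical(a, b)

  perm <- sample(nrow(fx$table$values))
  shuffled <- count_table(fx$table$values[perm, ], "species", relative = TRUE)
  c2 <- lefse_lda_scores(shuffled, fx$classes[perm], seed = 11)
  expect_equal(a, c2, tolerance = 1e-12)

  expect_error(lefse_lda_scores(fx$table, rep(c(0, 1, 2), length.out = 40)),
               "2 classes")
})

test_that("pairwise log-ratio W statistic flags a strongly shifted feature", {
  set.seed(36)
  n <- 200; m <- 30
  y <- rbinom(n, 1, 0.4)
  lx <- matrix(rnorm(n * m), n, m)
  lx[, 1] <- lx[, 1] + 2 * y          # 2 SD shift on the log scale
  x <- exp(lx)
  dimnames(x) <- list(sprintf("s%03d", 1:n), sprintf("f%02d", 1:m))
  res <- ancom_w(count_table(x, "species"), y)
  expect_gte(res$W[res$feature_id == "f01"], 0.6 * (m - 1))
  expect_true(grepl("0.6", res$detected_at[res$feature_id == "f01"]))
  # the rest of the features should sit well below the detection level
  expect_lt(median(res$W[-1]), 0.6 * (m - 1))
})

test_that("W values are invariant to per-sample scaling of the composition", {
  set.seed(37)
  n <- 60; m <- 8
  x <- exp(matrix(rnorm(n * m), n, m))
  dimnames(x) <- list(sprintf("s%02d", 1:n), sprintf("f%d", 1:m))
  y <- rbinom(n, 1, 0.5)
  z <- data.frame(age = rnorm(n))
  a <- ancom_w(count_table(x, "species"), y, z)
  scaled <- x * runif(n, 0.1, 10)     # arbitrary per-sample scale factors
  b <- ancom_w(count_table(scaled, "species"), y, z)
  expect_equal(a$W, b$W)
  expect_error(ancom_w(count_table(x[, 1:2], "species"), y), "3 features")
  x0 <- x; x0[1, 1] <- 0
  expect_error(ancom_w(count_table(x0, "species"), y), "positive")
})

test_that("the three screens agree on a strongly planted species", {
  co <- generate_cohort(test_config(
    seed = 41, n_samples = 300,
    species_plaque_effects = c(sp007 = log(3))))
  covs <- co$metadata[, c("age", "hiv", "site")]
  filt <- filter_features(co$species)
  cl <- clr_transform(filt)

  logi <- logistic_screen(cl, co$metadata$plaque, covs)
  top_logi <- logi$feature_id[which.min(logi$p)]

  lef <- lefse_lda_scores(filt, co$metadata$plaque, seed = 1)
  top_lef <- lef$feature_id[which.max(abs(lef$lda_score))]

  rel <- filt$values / rowSums(filt$values)
  rel[rel == 0] <- 0.5 * min(rel[rel > 0])
  anc <- ancom_w(count_table(rel, "species"), co$metadata$plaque, covs)
  top_anc <- anc$feature_id[which.max(anc$W)]

  expect_equal(top_logi, "sp007")
  expect_equal(top_lef, "sp007")
  expect_equal(top_anc, "sp007")
})
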