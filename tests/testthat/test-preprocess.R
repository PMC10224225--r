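test_that("prevalence/abundance filter applies both rules with inclusive boundaries", {
  # 100 samples so prevalence boundaries 19% vs 20% are constructible
  n <- 100
  m <- matrix(0, n, 4, dimnames = list(sprintf("s%03d", 1:n),
                                       c("p19", "p20", "common", "rare")))
  m[1:19, "p19"] <- 1000
  m[1:20, "p20"] <- 1000
  m[, "common"] <- 100
  m[1:50, "rare"] <- 1e-4          # present in half, but tiny mean share
  ct <- count_table(m, "species")
  kept <- colnames(filter_features(ct)$values)
  expect_false("p19" %in% kept)    # below 20% prevalence: excluded
  expect_true("p20" %in% kept)     # exactly 20%: retained
  expect_true("common" %in% kept)
  expect_false("rare" %in% kept)   # mean relative abundance < 1e-5
})

test_that("filter survivors match brute-force rule application on a toy table", {
  set.seed(3)
  n <- 10
  m <- matrix(rpois(n * 6, 5), n, 6,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("f%d", 1:6)))
  m[sample(length(m), 25)] <- 0
  ct <- count_table(m, "species")
  for (prev_cut in c(0.1, 0.2, 0.5)) {
    for (ab_cut in c(1e-6, 1e-3, 1e-1)) {
      rel <- m / rowSums(m)
      expected <- colnames(m)[
        colMeans(m > 0) >= prev_cut & colMeans(rel) >= ab_cut]
      got <- suppressWarnings(
        filter_features(ct, prev_cut, ab_cut))
      expect_identical(colnames(got$values), expected)
    }
  }
})

test_that("filter_features is idempotent", {
  co <- generate_cohort(test_config(seed = 5))
  once <- filter_features(co$species)
  twice <- filter_features(once)
  expect_identical(once$values, twice$values)
})

test_that("CLR transform matches hand computation and its identities", {
  m <- matrix(c(1, 2, 4, 1, 1, 1), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  out <- clr_transform(m)$values
  expect_equal(unname(out[1, ]), c(-log(2), 0, log(2)), tolerance = 1e-12)
  expect_equal(unname(out[2, ]), c(0, 0, 0))

  # scale invariance: clr(c x) = clr(x)
  expect_equal(clr_transform(m * 17)$values, out, tolerance = 1e-12)

  # zero row-sums on a generated sparse table
  co <- generate_cohort(test_config(seed = 2))
  cl <- clr_transform(co$species)
  expect_lt(max(abs(rowSums(cl$values))), 1e-9)
  expect_equal(clr_transform(co$species$values * 3)$values, cl$values,
               tolerance = 1e-12)
})

test_that("CLR rejects all-zero samples by name and bad pseudocounts", {
  m <- toy_matrix()
  m["s03", ] <- 0
  expect_error(clr_transform(m), "s03")
  expect_error(clr_transform(toy_matrix(), zero_replacement = -1), "positive")
})

test_that("inverse-normal transform follows the Blom rank map", {
  x <- matrix(c(5, 1, 9), 3, 1, dimnames = list(c("a", "b", "c"), "v"))
  out <- int_transform(x)$values
  expect_equal(out["a", 1], 0)  # middle of 3: (2 - 3/8) / 3.25 = 0.5

  # largest of 5 maps to the (4.625 / 5.25) normal quantile; verify the
  # quantile against an independent root-finding oracle on pnorm
  x5 <- matrix(c(3, 1, 4, 1.5, 9), 5, 1,
               dimnames = list(letters[1:5], "v"))
  out5 <- int_transform(x5)$values
  target <- (5 - 3 / 8) / (5 - 2 * 3 / 8 + 1)
  oracle_q <- uniroot(function(z) pnorm(z) - target, c(-10, 10),
                      tol = 1e-12)$root
  expect_equal(out5["e", 1], oracle_q, tolerance = 1e-9)
  expect_equal(target, 0.88095, tolerance = 1e-5)

  # antisymmetry: reversing the order of values negates every output
  xr <- matrix(-x5, 5, 1, dimnames = dimnames(x5))
  expect_equal(int_transform(xr)$values, -out5, tolerance = 1e-12)
})

test_that("inverse-normal output is standard-normal-like for large n", {
  set.seed(9)
  m <- matrix(rexp(1000), 1000, 1, dimnames = list(NULL, "v"))
  rownames(m) <- sprintf("s%04d", 1:1000)
  out <- int_transform(m)$values
  expect_lt(abs(mean(out)), 1e-9)
  expect_gt(var(out[, 1]), 0.9)
  expect_lt(var(out[, 1]), 1.1)
})

test_that("inverse-normal transform rejects constant columns by name", {
  m <- cbind(toy_matrix(), bad = 1)
  expect_error(int_transform(m), "bad")
})

test_that("protein QC keeps markers detected in strictly more than 75%", {
  m <- matrix(rnorm(100 * 3), 100, 3,
              dimnames = list(sprintf("s%03d", 1:100),
                              c("det75", "det76", "det100")))
  m[1:25, "det75"] <- NA   # detection exactly 75%: dropped
  m[1:24, "det76"] <- NA   # detection 76%: kept
  om <- omics_matrix(m, "NPX_log2")
  kept <- colnames(qc_filter(om, "protein")$values)
  expect_identical(kept, c("det76", "det100"))
})

test_that("metabolite QC matches exhaustive rule application on a CV/missing grid", {
  set.seed(11)
  n <- 50
  cvs <- c(0.05, 0.2, 0.29, 0.3, 0.5)
  miss <- c(0, 0.1, 0.18, 0.2, 0.4)
  cols <- list()
  for (i in seq_along(cvs)) {
    for (j in seq_along(miss)) {
      x <- rnorm(n, mean = 10, sd = 10 * cvs[i])
      # rescale to the exact CV so boundary cases are sharp
      x <- 10 + (x - mean(x)) * (10 * cvs[i] / sd(x))
      x[seq_len(round(miss[j] * n))] <- NA
      cols[[paste0("cv", i, "m", j)]] <- x
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- sprintf("s%02d", 1:n)
  om <- omics_matrix(m, "intensity")
  got <- colnames(suppressWarnings(qc_filter(om, "metabolite"))$values)
  expected <- names(cols)[vapply(cols, function(x) {
    obs <- x[!is.na(x)]
    (sd(obs) / mean(obs) < 0.30) && (mean(is.na(x)) < 0.20)
  }, logical(1))]
  expect_identical(got, expected)

  # zero missing, CV 10%: retained
  expect_true("cv2m1" %in% got)
})

test_that("half-minimum imputation fills only missing cells", {
  m <- cbind(a = c(2, NA, 6), b = c(1, 2, 3), c = c(0.4, NA, NA))
  rownames(m) <- c("s1", "s2", "s3")
  om <- omics_matrix(m, "intensity")
  out <- impute_half_min(om)$values
  expect_equal(out[, "a"], c(s1 = 2, s2 = 1, s3 = 6))    # 0.5 * min(2, 6)
  expect_equal(out[, "b"], c(s1 = 1, s2 = 2, s3 = 3))    # untouched
  expect_equal(unname(out[2:3, "c"]), c(0.2, 0.2))       # single observed value

  expect_identical(impute_half_min(omics_matrix(m[, 2, drop = FALSE]))$values,
                   m[, 2, drop = FALSE])
  m[, "a"] <- NA
  expect_error(impute_half_min(omics_matrix(m)), "a")
})
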