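#' Alpha diversity indices
#'
#' Shannon index (natural log), Simpson's index (1 - sum p^2), or the
#' Chao-1 richness estimator. Chao-1 uses the classic form
#' `S_obs + F1^2 / (2 F2)` when doubletons are present and the
#' bias-corrected `S_obs + F1 (F1 - 1) / 2` when `F2 = 0`; it requires
#' integer counts because singleton/doubleton tallies are meaningless on
#' relative abundances.
#'
#' @param table A [count_table()].
#' @param metric `"shannon"`, `"chao1"` or `"simpson"`.
#' @return Named numeric vector, one value per sample.
#' @export
alpha_diversity <- function(table, metric = c("shannon", "chao1", "simpson")) {
  metric <- match.arg(metric)
  m <- as_values(table)
  if (metric == "chao1") {
    if (any(abs(m - round(m)) > 1e-8)) {
      stop("chao1 requires integer counts, not relative abundances")
    }
    return(apply(m, 1, function(x) {
      s_obs <- sum(x > 0)
      f1 <- sum(x == 1)
      f2 <- sum(x == 2)
      if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
    }))
  }
  apply(m, 1, function(x) {
    p <- x / sum(x)
    p <- p[p > 0]
    if (metric == "shannon") -sum(p * log(p)) else 1 - sum(p^2)
  })
}

#' Between-sample distance matrix
#'
#' Bray-Curtis dissimilarity (via \pkg{vegan}) or normalized weighted
#' UniFrac. Weighted UniFrac for samples A and B is
#' `sum_b l_b |pA(b) - pB(b)| / sum_b l_b (pA(b) + pB(b))` over the
#' branches b of a rooted tree, where `pX(b)` is the fraction of sample
#' X's abundance descending through branch b; the normalization makes it 1
#' for samples with disjoint support.
#'
#' @param table A [count_table()] (counts or relative abundances; rows are
#'   converted to proportions).
#' @param method `"bray_curtis"` or `"weighted_unifrac"`.
#' @param tree Rooted `ape::phylo` tree with positive branch lengths whose
#'   tips cover all features (required for weighted UniFrac).
#' @return A symmetric `dist`-convertible matrix with zero diagonal.
#' @export
distance_matrix <- function(table, method = c("bray_curtis", "weighted_unifrac"),
                            tree = NULL) {
  method <- match.arg(method)
  m <- as_values(table)
  rel <- m / rowSums(m)
  if (method == "bray_curtis") {
    d <- as.matrix(vegan::vegdist(rel, method = "bray"))
    dimnames(d) <- list(rownames(m), rownames(m))
    return(d)
  }
  if (is.null(tree)) stop("weighted_unifrac requires a rooted tree")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  missing_tips <- setdiff(colnames(m), tree$tip.label)
  if (length(missing_tips)) {
    stop("tree is missing features: ", paste(missing_tips, collapse = ", "))
  }
  if (any(tree$edge.length <= 0)) stop("branch lengths must be positive")
  # branch proportions: P[i, e] = fraction of sample i descending edge e
  bm <- branch_membership(tree)
  # tree tips absent from the table get zero abundance
  full <- matrix(0, nrow(rel), length(tree$tip.label),
                 dimnames = list(rownames(rel), tree$tip.label))
  full[, colnames(rel)] <- rel
  P <- full %*% bm                      # samples x edges
  l <- tree$edge.length
  n <- nrow(P)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num <- sum(l * abs(P[i, ] - P[j, ]))
      den <- sum(l * (P[i, ] + P[j, ]))
      d[i, j] <- d[j, i] <- if (den > 0) num / den else 0
    }
  }
  d
}

# Tip-by-edge indicator: bm[tip, e] = 1 iff tip descends through edge e.
branch_membership <- function(tree) {
  ntip <- length(tree$tip.label)
  nedge <- nrow(tree$edge)
  # accumulate descendant tip sets in postorder
  tips_below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) tips_below[[i]] <- i
  ord <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nedge)) {
    parent <- ord$edge[k, 1]
    child <- ord$edge[k, 2]
    tips_below[[parent]] <- c(tips_below[[parent]], tips_below[[child]])
  }
  bm <- matrix(0, ntip, nedge,
               dimnames = list(tree$tip.label, NULL))
  for (k in seq_len(nedge)) {
    child <- tree$edge[k, 2]
    bm[tips_below[[child]], k] <- 1
  }
  bm
}
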