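# Independent oracles used across the suite. Each reimplements a quantity
# by a route deliberately different from the package code it checks.

# Isotope envelope by brute-force enumeration over all 2^n heavy/light
# assignments of the individual halogen atoms (vs the package's polynomial
# convolution).
brute_envelope <- function(n_cl, n_br,
                           cl = c(0.7576, 0.2424), br = c(0.5069, 0.4931)) {
  n <- n_cl + n_br
  probs <- c(rep(list(cl), n_cl), rep(list(br), n_br))
  acc <- numeric(n + 1L)
  if (n == 0L) return(1)
  for (mask in 0:(2^n - 1L)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    p <- 1
    for (a in seq_len(n)) p <- p * probs[[a]][bits[a] + 1L]
    heavy <- sum(bits)
    acc[heavy + 1L] <- acc[heavy + 1L] + p
  }
  acc / acc[1L]
}

# UPGMA merge heights recomputed from the original matrix at every step:
# clusters kept as explicit leaf sets, between-cluster distance re-averaged
# from scratch (vs the package's Lance-Williams update). Same tie-break.
brute_upgma_heights <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- NULL; bv <- Inf; bk <- c(Inf, Inf)
    for (i in seq_len(length(clusters) - 1L))
      for (j in (i + 1L):length(clusters)) {
        v <- mean(dm[clusters[[i]], clusters[[j]]])
        key <- range(c(min(clusters[[i]]), min(clusters[[j]])))
        if (v < bv || (v == bv && (key[1] < bk[1] ||
                                   (key[1] == bk[1] && key[2] < bk[2])))) {
          bv <- v; bk <- key; best <- c(i, j)
        }
      }
    heights <- c(heights, bv)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Random unrooted additive tree and its exact leaf-to-leaf path distances.
random_additive_tree <- function(n, min_bl = 0.5, max_bl = 2) {
  tr <- ape::rtree(n, rooted = FALSE,
                   br = function(k) stats::runif(k, min_bl, max_bl))
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  D <- ape::cophenetic.phylo(tr)
  D <- D[tr$tip.label, tr$tip.label]
  list(tree = tr, D = D)
}

# Leaf-to-leaf path distances of any phylo tree, ordered by label.
tree_distances <- function(tree, labels) {
  D <- ape::cophenetic.phylo(tree)
  D[labels, labels]
}

# Adjusted Rand by direct O(n^2) iteration over sample pairs.
pair_count_ari <- function(a, b) {
  ids <- intersect(names(a), names(b))
  a <- a[ids]; b <- b[ids]
  n <- length(ids)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (!sa && !sb) n00 <- n00 + 1
    else if (sa) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  tot <- n11 + n00 + n10 + n01
  exp11 <- (n11 + n10) * (n11 + n01) / tot
  denom <- ((n11 + n10) + (n11 + n01)) / 2 - exp11
  if (denom == 0) return(if (n10 + n01 == 0) 1 else 0)
  (n11 - exp11) / denom
}

# Ground-truth partitions of a synthetic bundle as named vectors.
bundle_truth <- function(bundle) {
  gt <- bundle$ground_truth$samples
  out <- list(chemogroup = stats::setNames(gt$chemogroup, gt$sample_id))
  for (col in grep("^phylogroup_", names(gt), value = TRUE))
    out[[col]] <- stats::setNames(gt[[col]], gt$sample_id)
  out
}
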