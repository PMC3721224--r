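#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|x - y|) / sum(x + y)`; similarity is reported as `100 * (1 - d)`
#' percent. Undefined when both vectors are all zero.
#'
#' @param x,y Equal-length non-negative abundance vectors.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("abundance vectors must have equal length", call. = FALSE)
  if (any(x < 0) || any(y < 0))
    stop("abundances must be non-negative", call. = FALSE)
  tot <- sum(x) + sum(y)
  if (tot == 0)
    stop("Bray-Curtis is undefined for two all-zero vectors", call. = FALSE)
  sum(abs(x - y)) / tot
}

#' Bray-Curtis resemblance matrix of a feature table
#'
#' @param ft A `feature_table` (or a samples x features numeric matrix).
#' @return A `dist` object of Bray-Curtis dissimilarities in `[0, 1]`.
#' @seealso [similarity_matrix] for the percent-similarity view.
#' @export
resemblance_matrix <- function(ft) {
  vals <- if (inherits(ft, "feature_table")) ft$values else as.matrix(ft)
  n <- nrow(vals)
  if (n < 2L) stop("need at least two samples", call. = FALSE)
  dm <- matrix(0, n, n, dimnames = list(rownames(vals), rownames(vals)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dm[i, j] <- dm[j, i] <- bray_curtis(vals[i, ], vals[j, ])
  }
  stats::as.dist(dm)
}

#' Percent-similarity view of a dissimilarity
#'
#' @param d A `dist` object or square dissimilarity matrix in `[0, 1]`.
#' @return Square matrix of `100 * (1 - d)` (%).
#' @export
similarity_matrix <- function(d) {
  100 * (1 - as.matrix(d))
}

#' Group-average (UPGMA) hierarchical clustering
#'
#' Agglomerative clustering with unweighted average linkage: the distance
#' between two clusters is the mean dissimilarity over all cross pairs
#' (maintained by the size-weighted Lance-Williams update). Ties are broken
#' deterministically by merging the candidate pair whose
#' (smallest leaf index, then largest smallest-leaf index) is
#' lexicographically least, so the result does not depend on input order.
#'
#' @param d A `dist` object (or square symmetric matrix) of dissimilarities.
#' @return An object of class `hclust` (method `"average"`), usable with
#'   [stats::cophenetic], [cut_dendrogram] and [dendrogram_newick].
#' @export
upgma <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < 2L) stop("need at least two leaves to cluster", call. = FALSE)
  labels <- rownames(dm)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (any(abs(dm - t(dm)) > 1e-12))
    stop("dissimilarity matrix must be symmetric", call. = FALSE)

  nmax <- 2L * n - 1L
  D <- matrix(NA_real_, nmax, nmax)
  D[1:n, 1:n] <- dm
  alive <- c(rep(TRUE, n), rep(FALSE, n - 1L))
  size <- c(rep(1L, n), rep(0L, n - 1L))
  minleaf <- c(seq_len(n), rep(NA_integer_, n - 1L))
  node <- c(-seq_len(n), rep(NA_integer_, n - 1L))  # hclust merge codes

  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (s in seq_len(n - 1L)) {
    idx <- which(alive)
    # locate minimum inter-cluster distance, then resolve ties
    best_i <- best_j <- NA_integer_
    best_val <- Inf
    best_key <- c(Inf, Inf)
    for (a in seq_len(length(idx) - 1L)) for (b in (a + 1L):length(idx)) {
      i <- idx[a]; j <- idx[b]
      v <- D[i, j]
      key <- c(min(minleaf[i], minleaf[j]), max(minleaf[i], minleaf[j]))
      better <- v < best_val ||
        (v == best_val && (key[1L] < best_key[1L] ||
                           (key[1L] == best_key[1L] && key[2L] < best_key[2L])))
      if (better) {
        best_val <- v; best_key <- key; best_i <- i; best_j <- j
      }
    }
    i <- best_i; j <- best_j
    if (minleaf[j] < minleaf[i]) { tmp <- i; i <- j; j <- tmp }
    merge[s, ] <- c(node[i], node[j])
    height[s] <- best_val
    new <- n + s
    for (k in idx) {
      if (k == i || k == j) next
      D[new, k] <- D[k, new] <-
        (size[i] * D[i, k] + size[j] * D[j, k]) / (size[i] + size[j])
    }
    alive[c(i, j)] <- FALSE
    alive[new] <- TRUE
    size[new] <- size[i] + size[j]
    minleaf[new] <- min(minleaf[i], minleaf[j])
    node[new] <- s
  }

  order_of <- function(m) {
    if (m < 0L) return(-m)
    c(order_of(merge[m, 1L]), order_of(merge[m, 2L]))
  }
  structure(
    list(merge = merge, height = height,
         order = order_of(n - 1L), labels = labels,
         method = "average", call = match.call(),
         dist.method = "bray-curtis"),
    class = "hclust"
  )
}

#' Cut a dendrogram at a similarity threshold
#'
#' Clusters are the maximal subtrees whose internal merge heights are all
#' strictly below `1 - similarity_pct/100`, i.e. groups of samples whose
#' cophenetic similarity exceeds the threshold. Singletons are allowed.
#' Group labels are numbered by order of first appearance along the
#' dendrogram leaf order.
#'
#' @param hc An `hclust` tree over dissimilarities in `[0, 1]` (e.g. from
#'   [upgma]).
#' @param similarity_pct Similarity threshold in percent, `[0, 100]`.
#' @param prefix Label prefix (default `"CG"` for chemogroups).
#' @return A partition data frame (`sample_id`, `group`) with attributes
#'   `cut_similarity` and `type`.
#' @export
cut_dendrogram <- function(hc, similarity_pct = 50, prefix = "CG") {
  if (similarity_pct < 0 || similarity_pct > 100)
    stop("similarity_pct must lie in [0, 100]", call. = FALSE)
  h_cut <- 1 - similarity_pct / 100
  n <- length(hc$labels)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  members <- vector("list", n - 1L)
  leaf_set <- function(m) if (m < 0L) -m else members[[m]]
  for (s in seq_along(hc$height)) {
    a <- leaf_set(hc$merge[s, 1L])
    b <- leaf_set(hc$merge[s, 2L])
    members[[s]] <- c(a, b)
    if (hc$height[s] < h_cut) parent[find(b[1L])] <- find(a[1L])
  }
  comp <- vapply(seq_len(n), find, integer(1))
  seen <- integer(0)
  for (leaf in hc$order) {
    r <- comp[leaf]
    if (!r %in% seen) seen <- c(seen, r)
  }
  lab <- paste0(prefix, match(comp, seen))
  partition(hc$labels, lab, type = tolower(prefix),
            cut_similarity = similarity_pct)
}

#' Construct a partition assignment
#'
#' @param sample_id Character vector of sample ids.
#' @param group Group label per sample.
#' @param type What the partition represents (e.g. `"chemogroup"`).
#' @param cut_similarity Optional similarity threshold used to obtain it.
#' @return Data frame `sample_id`, `group` with class `partition`.
#' @export
partition <- function(sample_id, group, type = "group",
                      cut_similarity = NA_real_) {
  stopifnot(length(sample_id) == length(group),
            !anyDuplicated(sample_id))
  structure(
    data.frame(sample_id = as.character(sample_id),
               group = as.character(group), stringsAsFactors = FALSE),
    type = type, cut_similarity = cut_similarity,
    class = c("partition", "data.frame")
  )
}

# Named character vector view of a partition (names = sample ids).
as_partition_vector <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("sample_id", "group") %in% names(x)) &&
        ncol(x) >= 2L) names(x)[1:2] <- c("sample_id", "group")
    stats::setNames(as.character(x$group), as.character(x$sample_id))
  } else if (!is.null(names(x))) {
    stats::setNames(as.character(x), names(x))
  } else stop("cannot interpret partition input", call. = FALSE)
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths are height differences between a node and its parent;
#' following the usual ultrametric convention each internal node sits at
#' half its merge height, so leaf-to-leaf path lengths in the tree equal
#' the cophenetic dissimilarities.
#'
#' @param hc An `hclust` object.
#' @param path Optional file to write the tree to.
#' @return The Newick string, invisibly when `path` is given.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  build <- function(m, parent_h) {
    if (m < 0L) {
      sprintf("%s:%.10g", hc$labels[-m], parent_h)
    } else {
      h <- hc$height[m] / 2
      sprintf("(%s,%s):%.10g",
              build(hc$merge[m, 1L], h), build(hc$merge[m, 2L], h),
              parent_h - h)
    }
  }
  root <- length(hc$height)
  root_h <- hc$height[root] / 2
  txt <- sprintf("(%s,%s);",
                 build(hc$merge[root, 1L], root_h),
                 build(hc$merge[root, 2L], root_h))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
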