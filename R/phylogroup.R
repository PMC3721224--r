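#' Read a pre-aligned FASTA file
#'
#' The pipeline consumes alignments (equal-length sequences per marker);
#' alignment itself is out of scope, and a length mismatch is a loud error,
#' never silent trimming. IUPAC ambiguity codes other than N are treated as
#' N (excluded pairwise) downstream.
#'
#' @param path Path to a FASTA file; record ids should match sample ids.
#' @param marker Optional marker name (`"cox1"`, `"rbcL"`, ...), stored as
#'   an attribute.
#' @return Character matrix (samples x alignment columns) of upper-case
#'   bases, with attribute `marker`.
#' @export
read_alignment <- function(path, marker = NULL) {
  seqs <- ape::read.FASTA(path)
  chars <- lapply(as.character(seqs), toupper)
  lens <- lengths(chars)
  if (length(unique(lens)) > 1L)
    stop("sequences in ", path, " are not aligned: lengths ",
         paste(sort(unique(lens)), collapse = ", "),
         " (provide a pre-aligned FASTA)", call. = FALSE)
  if (anyDuplicated(names(chars)))
    stop("duplicate sequence ids in ", path, call. = FALSE)
  aln <- do.call(rbind, chars)
  rownames(aln) <- names(chars)
  attr(aln, "marker") <- marker
  aln
}

BASES <- c("A", "C", "G", "T")

as_site_vector <- function(s) {
  if (is.character(s) && length(s) == 1L)
    s <- strsplit(s, "", fixed = TRUE)[[1L]]
  toupper(as.character(s))
}

#' Uncorrected pairwise distance between two aligned sequences
#'
#' Proportion of mismatching sites with pairwise deletion: any site where
#' either sequence has a gap, an N, or any other non-ACGT symbol is excluded
#' from the comparison.
#'
#' @param seq1,seq2 Aligned sequences (single strings or character vectors
#'   of equal length).
#' @return p-distance (proportion in `[0, 1]`).
#' @export
p_distance <- function(seq1, seq2) {
  a <- as_site_vector(seq1)
  b <- as_site_vector(seq2)
  if (length(a) != length(b))
    stop("sequences must be aligned to equal length", call. = FALSE)
  ok <- a %in% BASES & b %in% BASES
  m <- sum(ok)
  if (m == 0L)
    stop("no comparable sites between the two sequences", call. = FALSE)
  sum(a[ok] != b[ok]) / m
}

#' Pairwise p-distance matrix of an alignment
#'
#' @param aln Alignment matrix from [read_alignment].
#' @return `dist` object of p-distances.
#' @export
p_distance_matrix <- function(aln) {
  n <- nrow(aln)
  dm <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dm[i, j] <- dm[j, i] <- p_distance(aln[i, ], aln[j, ])
  }
  stats::as.dist(dm)
}

#' Jukes-Cantor distance from a p-distance
#'
#' `-(3/4) * log(1 - 4p/3)` substitutions per site; saturates at p = 0.75.
#'
#' @param p p-distance(s), each `< 0.75`.
#' @return Corrected distance(s).
#' @export
jc_distance <- function(p) {
  if (any(p < 0) || any(p >= 0.75))
    stop("Jukes-Cantor correction requires 0 <= p < 0.75 (saturation)",
         call. = FALSE)
  -0.75 * log(1 - 4 * p / 3)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining: at each step the pair minimizing the
#' Q-criterion is joined (ties broken by the smallest index pair), branch
#' lengths follow the usual formulas, and any negative branch length is
#' clamped to zero with the deficit transferred to its sibling edge so path
#' lengths through the new node are preserved.
#'
#' @param d `dist` object or square symmetric matrix, `n >= 3` taxa.
#' @return An unrooted `phylo` tree (class from \pkg{ape}).
#' @export
neighbor_joining <- function(d) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  frag <- labels

  join_pair <- function(i, j, vi, vj) {
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    sprintf("(%s:%.15g,%s:%.15g)", frag[i], max(vi, 0), frag[j], max(vj, 0))
  }

  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    best <- c(NA_integer_, NA_integer_); bq <- Inf
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      if (Q[i, j] < bq) { bq <- Q[i, j]; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    newfrag <- join_pair(i, j, vi, vj)
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    D <- D2
  }
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 frag[1], max(v1, 0), frag[2], max(v2, 0),
                 frag[3], max(v3, 0))
  ape::read.tree(text = txt)
}

#' Assign phylogroups by removing the longest internal edges
#'
#' Deletes the `k - 1` longest internal edges of the tree (for `k = 2`, the
#' single deepest split) and labels the resulting leaf sets `A`, `B`, ... by
#' decreasing group size, ties by smallest leaf id.
#'
#' @param tree A `phylo` tree (e.g. from [neighbor_joining]).
#' @param k Number of phylogroups (default 2).
#' @return A [partition] (`sample_id`, `group`) of the tips.
#' @export
assign_phylogroups <- function(tree, k = 2L) {
  tips <- tree$tip.label
  nt <- length(tips)
  if (k < 1L || k > nt) stop("k must lie in [1, n tips]", call. = FALSE)
  if (k == 1L) return(partition(tips, rep("A", nt), type = "phylogroup"))
  internal <- which(tree$edge[, 1L] > nt & tree$edge[, 2L] > nt)
  if (length(internal) < k - 1L)
    stop("tree has too few internal edges to split into ", k,
         " phylogroups (star-like tree)", call. = FALSE)
  drop <- internal[order(-tree$edge.length[internal], internal)][seq_len(k - 1L)]
  keep <- tree$edge[setdiff(seq_len(nrow(tree$edge)), drop), , drop = FALSE]
  nn <- max(tree$edge)
  parent <- seq_len(nn)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (e in seq_len(nrow(keep)))
    parent[find(keep[e, 1L])] <- find(keep[e, 2L])
  comp <- vapply(seq_len(nt), find, integer(1))
  groups <- split(tips, comp)
  ord <- order(-lengths(groups),
               vapply(groups, function(g) min(g), character(1)))
  groups <- groups[ord]
  lab <- stats::setNames(rep(LETTERS[seq_along(groups)], lengths(groups)),
                         unlist(groups))
  partition(tips, unname(lab[tips]), type = "phylogroup")
}

#' Divergence summary for a marker
#'
#' Reports per-marker sample coverage, the maximum overall pairwise
#' p-distance, the maximum within each phylogroup, and whether the overall
#' maximum stays within the conspecificity threshold for that marker.
#'
#' @param d p-distance `dist` object.
#' @param assignment Optional phylogroup [partition].
#' @param marker Marker name; selects the default threshold
#'   (cox1: 2.1%, rbcL: 1.1%).
#' @param conspecific_threshold Override threshold as a proportion.
#' @return List of class `divergence_report`.
#' @export
divergence_report <- function(d, assignment = NULL, marker = NULL,
                              conspecific_threshold = NULL) {
  defaults <- c(cox1 = 0.021, rbcL = 0.011)
  thr <- conspecific_threshold
  if (is.null(thr))
    thr <- if (!is.null(marker) && marker %in% names(defaults))
      defaults[[marker]] else NA_real_
  dm <- as.matrix(d)
  ids <- rownames(dm)
  max_overall <- if (nrow(dm) > 1L) max(dm[upper.tri(dm)]) else 0
  within <- NULL
  if (!is.null(assignment)) {
    pv <- as_partition_vector(assignment)
    pv <- pv[intersect(names(pv), ids)]
    within <- vapply(split(names(pv), pv), function(g) {
      if (length(g) < 2L) return(0)
      sub <- dm[g, g, drop = FALSE]
      max(sub[upper.tri(sub)])
    }, numeric(1))
  }
  structure(
    list(marker = marker, n_samples = nrow(dm),
         max_overall_pct = 100 * max_overall,
         max_within_pct = if (is.null(within)) NULL else 100 * within,
         threshold_pct = 100 * thr,
         conspecific = if (is.na(thr)) NA else max_overall <= thr),
    class = "divergence_report"
  )
}

#' @export
print.divergence_report <- function(x, ...) {
  cat("<divergence_report>",
      if (!is.null(x$marker)) paste0(" marker ", x$marker) else "",
      "\n  samples: ", x$n_samples,
      "\n  max pairwise divergence: ",
      formatC(x$max_overall_pct, format = "f", digits = 2), "%\n", sep = "")
  if (!is.null(x$max_within_pct)) {
    for (g in names(x$max_within_pct))
      cat("  max within ", g, ": ",
          formatC(x$max_within_pct[[g]], format = "f", digits = 2),
          "%\n", sep = "")
  }
  if (!is.na(x$conspecific))
    cat("  conspecific at ", x$threshold_pct, "% threshold: ",
        x$conspecific, "\n", sep = "")
  invisible(x)
}
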