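#' Cross-tabulate two or three partitions of the same samples
#'
#' Counts samples in each combination of group labels over the shared
#' sample ids; samples missing from any partition are dropped (with a
#' message) so marginals always equal the shared-sample count.
#'
#' @param ... Two or three partitions ([partition] data frames or named
#'   character vectors). Name the arguments to name the table dimensions.
#' @return A contingency `table` with deterministically sorted margins.
#' @export
crosstab <- function(...) {
  parts <- lapply(list(...), as_partition_vector)
  if (length(parts) < 2L || length(parts) > 3L)
    stop("crosstab takes 2 or 3 partitions", call. = FALSE)
  ids <- Reduce(intersect, lapply(parts, names))
  if (!length(ids))
    stop("partitions share no sample ids", call. = FALSE)
  dropped <- setdiff(unique(unlist(lapply(parts, names))), ids)
  if (length(dropped))
    message("crosstab: dropping ", length(dropped),
            " sample(s) absent from some partition: ",
            paste(sort(dropped), collapse = ", "))
  ids <- sort(ids)
  fx <- lapply(parts, function(p) factor(p[ids], levels = sort(unique(p[ids]))))
  nm <- names(list(...))
  if (is.null(nm) || any(!nzchar(nm)))
    nm <- paste0("partition", seq_along(parts))
  names(fx) <- nm
  table(fx)
}

#' Per-site chemogroup purity
#'
#' Purity of a site is the fraction of its samples that belong to the
#' site's modal (most frequent) group; a singleton site has purity 1 by
#' definition.
#'
#' @param groups A [partition] (e.g. chemogroup assignment).
#' @param design Data frame with columns `sample_id` and `site`.
#' @return Data frame `site`, `n`, `modal_group`, `purity`, sorted by site.
#' @export
site_purity <- function(groups, design) {
  pv <- as_partition_vector(groups)
  ids <- intersect(names(pv), as.character(design$sample_id))
  site <- stats::setNames(as.character(design$site),
                          as.character(design$sample_id))[ids]
  rows <- lapply(split(ids, site), function(g) {
    tab <- sort(table(pv[g]), decreasing = TRUE)
    data.frame(n = length(g), modal_group = names(tab)[1L],
               purity = as.numeric(tab[1L]) / length(g),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- data.frame(site = names(rows), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(out$site), ]
}

#' Rand and adjusted Rand indices between two partitions
#'
#' Pair-counting agreement over the shared sample ids: the Rand index is
#' the fraction of sample pairs on which the partitions agree (together in
#' both or apart in both); the adjusted form subtracts the chance
#' expectation under fixed margins.
#'
#' @param p1,p2 Partitions over the same sample ids.
#' @return List with `rand`, `adjusted_rand`, and `n` (shared samples).
#' @export
partition_concordance <- function(p1, p2) {
  a <- as_partition_vector(p1)
  b <- as_partition_vector(p2)
  ids <- intersect(names(a), names(b))
  if (length(ids) < 2L)
    stop("need at least two shared sample ids", call. = FALSE)
  tab <- table(a[ids], b[ids])
  n <- length(ids)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  npairs <- choose(n, 2)
  rand <- 1 + (2 * sum_ij - sum_a - sum_b) / npairs
  expected <- sum_a * sum_b / npairs
  denom <- (sum_a + sum_b) / 2 - expected
  ari <- if (denom == 0) {
    if (sum_ij == sum_a && sum_ij == sum_b) 1 else 0
  } else (sum_ij - expected) / denom
  list(rand = rand, adjusted_rand = ari, n = n)
}

#' Flag chemogroups that span more than one phylogroup
#'
#' In a strictly nested metabogenomic structure every chemogroup lies
#' inside a single phylogroup; exceptions (e.g. a single sample whose
#' plastid marker places it in the other clade) are listed with their
#' member ids.
#'
#' @param chemogroups,phylogroups Partitions over the same sample ids.
#' @return List with `nested` (logical) and `exceptions`: one entry per
#'   offending chemogroup, each a list of member ids split by phylogroup.
#' @export
nesting_check <- function(chemogroups, phylogroups) {
  cg <- as_partition_vector(chemogroups)
  pg <- as_partition_vector(phylogroups)
  ids <- intersect(names(cg), names(pg))
  exceptions <- list()
  for (g in sort(unique(cg[ids]))) {
    members <- ids[cg[ids] == g]
    spanned <- sort(unique(pg[members]))
    if (length(spanned) > 1L)
      exceptions[[g]] <- lapply(split(members, pg[members]), sort)
  }
  list(nested = length(exceptions) == 0L, exceptions = exceptions)
}

#' Integrated chemogroup x phylogroup x site report
#'
#' Bundles the cross-tabulations, per-site purity, pairwise partition
#' concordances and nesting exceptions into one report, with per-partition
#' sample coverage made explicit (samples present chemically but not
#' genetically stay in chemogroup-only statistics and are excluded
#' pairwise elsewhere).
#'
#' @param chemogroups Chemogroup [partition].
#' @param phylogroups Named list of phylogroup partitions (one per marker),
#'   or a single partition.
#' @param design Data frame `sample_id`, `site`, and optionally `depth_m`,
#'   `site_name` (carried descriptively).
#' @return List of class `integration_report`.
#' @export
integration_report <- function(chemogroups, phylogroups, design) {
  if (inherits(phylogroups, "partition") || !is.list(phylogroups) ||
      is.data.frame(phylogroups))
    phylogroups <- list(marker = phylogroups)
  cg <- as_partition_vector(chemogroups)
  sites <- partition(design$sample_id, design$site, type = "site")
  rep <- list(
    coverage = c(list(chemogroup = length(cg)),
                 lapply(phylogroups, function(p)
                   length(as_partition_vector(p)))),
    site_purity = site_purity(chemogroups, design),
    chemo_by_site = crosstab(chemogroup = chemogroups, site = sites),
    chemo_site_concordance = partition_concordance(chemogroups, sites)
  )
  rep$markers <- lapply(phylogroups, function(p) {
    list(
      chemo_by_phylo = crosstab(chemogroup = chemogroups, phylogroup = p),
      concordance = partition_concordance(chemogroups, p),
      nesting = nesting_check(chemogroups, p)
    )
  })
  class(rep) <- "integration_report"
  rep
}

#' @export
print.integration_report <- function(x, ...) {
  cat("<integration_report>\n")
  cat("  coverage:",
      paste(names(x$coverage), unlist(x$coverage), sep = "=",
            collapse = ", "), "\n")
  cat("  mean site purity:",
      formatC(mean(x$site_purity$purity), format = "f", digits = 3), "\n")
  for (m in names(x$markers)) {
    mk <- x$markers[[m]]
    cat("  ", m, ": ARI(chemo, phylo) = ",
        formatC(mk$concordance$adjusted_rand, format = "f", digits = 3),
        "; nested = ", mk$nesting$nested, "\n", sep = "")
  }
  invisible(x)
}

#' Write an integration report (or any report list) as JSON
#'
#' @param report A list, e.g. from [integration_report].
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  clean <- rapply(unclass(report), function(x) {
    if (is.table(x)) as.data.frame(x, stringsAsFactors = FALSE) else x
  }, classes = "table", how = "replace")
  jsonlite::write_json(clean, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
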