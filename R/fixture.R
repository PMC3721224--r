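#' Palmer Station study design
#'
#' The field design of the 21-sample survey this package models: seven
#' dive sites within a ~10 km2 area near Palmer Station (Anvers Island,
#' Antarctica), three individual thalli (replicates A-C) per site, each
#' site sampled at a single depth.
#'
#' @return Data frame `sample_id` (site digit + replicate letter), `site`,
#'   `depth_m`, `site_name`.
#' @export
palmer_design <- function() {
  sites <- data.frame(
    site = as.character(1:7),
    depth_m = c(19, 10, 6, 4, 17, 6, 12),
    site_name = c("Hermit Island", "Norsel Point wall", "Norsel Point cove",
                  "Old Palmer Station", "Bahia Paraiso shipwreck",
                  "Hero Inlet", "Litchfield Island"),
    stringsAsFactors = FALSE
  )
  out <- merge(
    data.frame(site = rep(sites$site, each = 3),
               replicate = rep(c("A", "B", "C"), 7),
               stringsAsFactors = FALSE),
    sites, by = "site"
  )
  out$sample_id <- paste0(out$site, out$replicate)
  out[order(out$sample_id),
      c("sample_id", "site", "depth_m", "site_name")]
}

#' Reference chemogroup assignment of the 21-sample survey
#'
#' The five chemogroups as reported for the field study: each site's
#' replicates fall in one chemogroup except Hermit Island replicate 1B
#' (grouping with the Hero Inlet pair) and Hero Inlet replicate 6C
#' (grouping with the Old Palmer trio).
#'
#' @return A [partition] `sample_id` -> chemogroup (CG1-CG5).
#' @export
palmer_chemogroups <- function() {
  groups <- list(
    CG1 = c("1A", "1C", "2A", "2B", "2C"),
    CG2 = c("1B", "6A", "6B"),
    CG3 = c("3A", "3B", "3C", "7A", "7B", "7C"),
    CG4 = c("5A", "5B", "5C"),
    CG5 = c("4A", "4B", "4C", "6C")
  )
  ids <- unlist(groups, use.names = FALSE)
  lab <- rep(names(groups), lengths(groups))
  ord <- order(ids)
  partition(ids[ord], lab[ord], type = "chemogroup", cut_similarity = 50)
}

#' Reference phylogroup assignment of the 21-sample survey
#'
#' Two clades: phylogroup A holds chemogroups 1 and 5, phylogroup B holds
#' chemogroups 2-4. Under the plastid (rbcL) marker one Hero Inlet sample
#' (6A) switches to phylogroup A; the mitochondrial (cox1) view keeps it
#' in B. The cross-marker conflict is reported, not resolved.
#'
#' @param marker `"cox1"` or `"rbcL"`.
#' @return A [partition] `sample_id` -> phylogroup (A/B).
#' @export
palmer_phylogroups <- function(marker = c("cox1", "rbcL")) {
  marker <- match.arg(marker)
  cg <- as_partition_vector(palmer_chemogroups())
  nesting <- c(CG1 = "A", CG2 = "B", CG3 = "B", CG4 = "B", CG5 = "A")
  pg <- nesting[cg]
  names(pg) <- names(cg)
  if (marker == "rbcL") pg["6A"] <- "A"
  partition(names(pg), unname(pg), type = "phylogroup")
}

#' Reconstructed ultrametric similarity structure of the survey
#'
#' Rebuilds the group-average similarity structure of the 21-sample survey
#' from the reported merge levels: the three phylogroup-B chemogroups join
#' at 40% (CG2 with CG4) and 30% (with CG3); chemogroup 5 joins that
#' cluster at 30%; chemogroup 1 is most distinct, joining everything at
#' 10%. Within a chemogroup, same-site replicate pairs sit at
#' `within_site` similarity (the survey reports > 70% at the tight sites)
#' and cross-site pairs at `within_group` (above the 50% chemogroup
#' delineation).
#'
#' @param within_site Similarity (%) of same-site, same-chemogroup pairs
#'   (default 75).
#' @param within_group Similarity (%) of cross-site pairs inside one
#'   chemogroup (default 60).
#' @return `dist` object of Bray-Curtis dissimilarities over the 21
#'   samples (exactly ultrametric).
#' @export
palmer_similarity <- function(within_site = 75, within_group = 60) {
  cg <- as_partition_vector(palmer_chemogroups())
  ids <- sort(names(cg))
  site <- substr(ids, 1, 1)
  n <- length(ids)
  b_groups <- c("CG2", "CG3", "CG4")
  sim_pair <- function(i, j) {
    gi <- cg[[ids[i]]]; gj <- cg[[ids[j]]]
    if (gi == gj) {
      if (site[i] == site[j]) within_site else within_group
    } else if (gi == "CG1" || gj == "CG1") {
      10
    } else if (all(c(gi, gj) %in% c("CG2", "CG4"))) {
      40
    } else if (gi %in% b_groups && gj %in% b_groups) {
      30
    } else {
      30  # CG5 against the phylogroup-B cluster
    }
  }
  dm <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dm[i, j] <- dm[j, i] <- 1 - sim_pair(i, j) / 100
  }
  stats::as.dist(dm)
}
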