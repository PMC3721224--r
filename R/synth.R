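#' Configuration for a synthetic metabogenomic study
#'
#' Defaults mirror the field design the package models: 7 sites x 3
#' replicates (21 samples), 43 recurring GC/MS features in the 10-30 min
#' window, five chemogroups nested in two phylogroups, within-group
#' Bray-Curtis similarity targeted above 70% and between-group below 40%,
#' and two-clade sequence sets with maximum divergence 2.1% (cox1, 660 bp)
#' and 1.1% (rbcL, 890 bp). Two chemogroup exceptions ("1B", "6C") and one
#' plastid-marker phylogroup exception ("6A") reproduce the survey's
#' site-impurity signature.
#'
#' @param seed Integer RNG seed; every generator draw derives from it.
#' @param n_sites,replicates_per_site Study layout (default 7 x 3).
#' @param n_chemogroups Number of metabolite templates (default 5).
#' @param nesting Named map chemogroup -> phylogroup.
#' @param site_groups Named map site -> default chemogroup of its
#'   replicates.
#' @param chemo_exceptions Named map sample_id -> chemogroup override.
#' @param marker_exceptions Per-marker named maps sample_id -> phylogroup
#'   override (default: 6A -> A under rbcL).
#' @param feature_pool_size Total recurring features (default 43).
#' @param shared_features Features common to all chemogroup templates;
#'   the remainder is split evenly between groups and controls
#'   between-group similarity (default 3).
#' @param intensity_range Template relative intensities are drawn uniformly
#'   from this range (default `c(30, 100)`), keeping every feature above
#'   the 10% base-peak rule under noise.
#' @param noise_sigma Lognormal sigma of multiplicative replicate intensity
#'   noise (default 0.25).
#' @param rt_jitter_sd Gaussian retention-time jitter, minutes
#'   (default 0.02).
#' @param rt_window Retention-time window holding the feature pool
#'   (default `c(10, 30)`).
#' @param halogen_range Range of total halogen atoms per feature
#'   (default `c(2, 6)`, at most 8).
#' @param height_scale Detector counts of a 100%-intensity peak
#'   (default 1e4).
#' @param seq_length Alignment length per marker.
#' @param within_clade_p Maximum within-clade p-distance (default 0.005).
#' @param between_clade_p Maximum overall p-distance per marker
#'   (default 2.1% cox1, 1.1% rbcL).
#' @param target_within,target_between Bray-Curtis similarity targets (%)
#'   the templates must satisfy (default 70 and 40).
#' @return List of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_sites = 7L,
                         replicates_per_site = 3L,
                         n_chemogroups = 5L,
                         nesting = c(CG1 = "A", CG2 = "B", CG3 = "B",
                                     CG4 = "B", CG5 = "A"),
                         site_groups = c(`1` = "CG1", `2` = "CG1",
                                         `3` = "CG3", `4` = "CG5",
                                         `5` = "CG4", `6` = "CG2",
                                         `7` = "CG3"),
                         chemo_exceptions = c(`1B` = "CG2", `6C` = "CG5"),
                         marker_exceptions = list(cox1 = c(),
                                                  rbcL = c(`6A` = "A")),
                         feature_pool_size = 43L,
                         shared_features = 3L,
                         intensity_range = c(30, 100),
                         noise_sigma = 0.25,
                         rt_jitter_sd = 0.02,
                         rt_window = c(10, 30),
                         halogen_range = c(2L, 6L),
                         height_scale = 1e4,
                         seq_length = c(cox1 = 660L, rbcL = 890L),
                         within_clade_p = 0.005,
                         between_clade_p = c(cox1 = 0.021, rbcL = 0.011),
                         target_within = 70,
                         target_between = 40) {
  cfg <- list(seed = as.integer(seed), n_sites = n_sites,
              replicates_per_site = replicates_per_site,
              n_chemogroups = n_chemogroups, nesting = nesting,
              site_groups = site_groups,
              chemo_exceptions = chemo_exceptions,
              marker_exceptions = marker_exceptions,
              feature_pool_size = feature_pool_size,
              shared_features = shared_features,
              intensity_range = intensity_range,
              noise_sigma = noise_sigma, rt_jitter_sd = rt_jitter_sd,
              rt_window = rt_window, halogen_range = halogen_range,
              height_scale = height_scale, seq_length = seq_length,
              within_clade_p = within_clade_p,
              between_clade_p = between_clade_p,
              target_within = target_within,
              target_between = target_between)
  stopifnot(n_sites >= 1, replicates_per_site >= 1, n_chemogroups >= 1,
            feature_pool_size >= n_chemogroups,
            shared_features >= 0, shared_features < feature_pool_size,
            noise_sigma >= 0, rt_jitter_sd >= 0,
            all(between_clade_p >= 0), all(between_clade_p < 0.75),
            within_clade_p >= 0, within_clade_p < 0.75,
            halogen_range[2] <= 8)
  if (length(site_groups) != n_sites)
    stop("site_groups must name a chemogroup for each site", call. = FALSE)
  if (!all(site_groups %in% names(nesting)))
    stop("site_groups refers to chemogroups missing from nesting",
         call. = FALSE)
  class(cfg) <- "synth_config"
  cfg
}

synth_sample_ids <- function(config) {
  sites <- names(config$site_groups)
  reps <- LETTERS[seq_len(config$replicates_per_site)]
  paste0(rep(sites, each = length(reps)), rep(reps, length(sites)))
}

synth_chemogroup_of <- function(config) {
  ids <- synth_sample_ids(config)
  cg <- config$site_groups[substr(ids, 1, 1)]
  names(cg) <- ids
  ov <- config$chemo_exceptions
  cg[names(ov)] <- ov
  cg
}

synth_phylogroup_of <- function(config, marker) {
  cg <- synth_chemogroup_of(config)
  pg <- config$nesting[cg]
  names(pg) <- names(cg)
  ov <- config$marker_exceptions[[marker]]
  if (length(ov)) pg[names(ov)] <- ov
  pg
}

#' Simulate chemogroup template profiles
#'
#' Builds one intensity template per chemogroup over the feature pool:
#' `shared_features` features occur in every template at a common
#' intensity, and the remaining pool is split evenly between groups as
#' group-exclusive features. Intensities are drawn uniformly from
#' `intensity_range`. The realized between-template Bray-Curtis
#' similarities are checked against `target_between` (a config error when
#' violated) and attached, together with the expected within-group
#' similarity under the replicate noise model, as attributes.
#'
#' @param config A [synth_config].
#' @return Matrix (chemogroups x features) of template intensities, with
#'   attributes `features` (rt, base_mass, n_cl, n_br per feature),
#'   `realized_between` (similarity matrix, %), and `expected_within` (%).
#' @export
simulate_profiles <- function(config) {
  set.seed(config$seed)
  k <- config$n_chemogroups
  p <- config$feature_pool_size
  s <- config$shared_features
  excl <- p - s
  per_group <- excl %/% k
  if (per_group < 1L)
    stop("feature pool too small for ", k, " chemogroup templates",
         call. = FALSE)
  # feature pool: evenly spaced consensus rts, random masses + compositions
  margin <- 0.5
  rts <- seq(config$rt_window[1] + margin, config$rt_window[2] - margin,
             length.out = p)
  n_total <- sample(config$halogen_range[1]:config$halogen_range[2], p,
                    replace = TRUE)
  n_br <- vapply(n_total, function(t) sample(0:t, 1L), integer(1))
  n_cl <- n_total - n_br
  base_mass <- round(stats::runif(p, 150, 500))
  features <- data.frame(feature = seq_len(p), rt = rts,
                         base_mass = base_mass, n_cl = n_cl, n_br = n_br)

  groups <- paste0("CG", seq_len(k))
  templates <- matrix(0, k, p, dimnames = list(groups, NULL))
  shared_idx <- if (s > 0) seq_len(s) else integer(0)
  shared_int <- stats::runif(s, config$intensity_range[1],
                             config$intensity_range[2])
  pool <- setdiff(seq_len(p), shared_idx)
  leftover <- length(pool) - per_group * k
  sizes <- rep(per_group, k) + c(rep(1L, leftover), rep(0L, k - leftover))
  at <- 0L
  for (g in seq_len(k)) {
    own <- pool[at + seq_len(sizes[g])]
    at <- at + sizes[g]
    templates[g, own] <- stats::runif(length(own), config$intensity_range[1],
                                      config$intensity_range[2])
    templates[g, shared_idx] <- shared_int
  }

  between <- matrix(100, k, k, dimnames = list(groups, groups))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    between[i, j] <- between[j, i] <-
      100 * (1 - bray_curtis(templates[i, ], templates[j, ]))
  }
  off <- between[upper.tri(between)]
  if (length(off) && max(off) > config$target_between)
    stop("infeasible template targets: realized between-group similarity ",
         formatC(max(off), format = "f", digits = 1), "% exceeds target ",
         config$target_between, "%; lower shared_features", call. = FALSE)
  ew <- expected_within_similarity(config$noise_sigma)
  if (ew < config$target_within)
    stop("infeasible noise level: expected within-group similarity ",
         formatC(ew, format = "f", digits = 1), "% below target ",
         config$target_within, "%; lower noise_sigma", call. = FALSE)
  attr(templates, "features") <- features
  attr(templates, "realized_between") <- between
  attr(templates, "expected_within") <- ew
  templates
}

# Expected Bray-Curtis similarity (%) between two replicates of one
# template under lognormal(0, sigma) multiplicative noise: per feature the
# expected |a-b|/(a+b) equals E[tanh(|Z|/2)] with Z ~ N(0, sqrt(2) sigma).
expected_within_similarity <- function(sigma) {
  if (sigma == 0) return(100)
  sd <- sqrt(2) * sigma
  f <- function(z) tanh(abs(z) / 2) * stats::dnorm(z, sd = sd)
  d <- stats::integrate(f, -Inf, Inf)$value
  100 * (1 - d)
}

#' Simulate per-sample GC/MS peak tables
#'
#' Each sample draws its chemogroup's template, multiplies every intensity
#' by lognormal noise, jitters retention times, and attaches the
#' theoretical halogen isotope envelope of each feature's composition.
#'
#' @param config A [synth_config].
#' @param profiles Templates from [simulate_profiles].
#' @return Long peak data frame (`sample_id`, `rt_min`, `height`,
#'   `base_mass`, `envelope`) ready for [preprocess_peaks].
#' @export
simulate_peak_tables <- function(config, profiles) {
  set.seed(config$seed + 1L)
  features <- attr(profiles, "features")
  cg <- synth_chemogroup_of(config)
  env_str <- vapply(seq_len(nrow(features)), function(i) {
    format_envelope_string(
      theoretical_envelope(features$n_cl[i], features$n_br[i])$abundances)
  }, character(1))
  rows <- lapply(names(cg), function(id) {
    tmpl <- profiles[cg[[id]], ]
    present <- which(tmpl > 0)
    noise <- stats::rlnorm(length(present), 0, config$noise_sigma)
    data.frame(
      sample_id = id,
      rt_min = features$rt[present] +
        stats::rnorm(length(present), 0, config$rt_jitter_sd),
      height = tmpl[present] * noise * config$height_scale / 100,
      base_mass = features$base_mass[present],
      envelope = env_str[present],
      feature = present,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

mutate_sites <- function(seq, n_sub) {
  if (n_sub < 1L) return(seq)
  pos <- sample(length(seq), n_sub)
  for (p in pos) seq[p] <- sample(setdiff(BASES, seq[p]), 1L)
  seq
}

#' Simulate a two-clade aligned sequence set for one marker
#'
#' A random root sequence is split into two clade ancestors separated by a
#' fixed number of substitutions, then each leaf receives its own small set
#' of substitutions. Substitution counts are fixed (floor of length x
#' rate) so the configured divergence bounds hold as hard guarantees:
#' within-clade pairs differ by at most `2 * floor(L * within_clade_p / 2)`
#' sites and no pair exceeds `floor(L * between_clade_p)` differences.
#'
#' @param config A [synth_config].
#' @param marker Marker name (must index `config$seq_length`).
#' @return Alignment matrix as from [read_alignment], with attributes
#'   `marker` and `phylogroup` (the generating clade labels).
#' @export
simulate_sequences <- function(config, marker) {
  if (!marker %in% names(config$seq_length))
    stop("unknown marker: ", marker, call. = FALSE)
  offset <- match(marker, names(config$seq_length))
  set.seed(config$seed + 1L + offset)
  L <- config$seq_length[[marker]]
  pg <- synth_phylogroup_of(config, marker)
  m_leaf <- floor(L * config$within_clade_p / 2)
  m_between <- max(floor(L * config$between_clade_p[[marker]]) - 2L * m_leaf,
                   1L)
  root <- sample(BASES, L, replace = TRUE)
  anc <- list(A = root, B = mutate_sites(root, m_between))
  aln <- t(vapply(names(pg), function(id) {
    mutate_sites(anc[[pg[[id]]]], m_leaf)
  }, character(L)))
  attr(aln, "marker") <- marker
  attr(aln, "phylogroup") <- pg
  aln
}

#' Simulate a complete synthetic study bundle
#'
#' Orchestrates [simulate_profiles], [simulate_peak_tables] and
#' [simulate_sequences]; with the same config the output is reproducible
#' byte for byte. When `dir` is given the bundle is written in the exact
#' formats the pipeline consumes: `peaks.csv`, one FASTA per marker,
#' `design.csv` and `ground_truth.json`.
#'
#' @param config A [synth_config].
#' @param dir Optional output directory (created if needed).
#' @return List with `peaks`, `design`, `sequences` (per marker),
#'   `profiles`, and `ground_truth` (sample -> site/chemogroup/phylogroup
#'   plus per-feature halogen compositions and realized similarity
#'   summaries).
#' @export
simulate_study <- function(config = synth_config(), dir = NULL) {
  profiles <- simulate_profiles(config)
  peaks <- simulate_peak_tables(config, profiles)
  markers <- names(config$seq_length)
  sequences <- lapply(stats::setNames(markers, markers), function(m)
    simulate_sequences(config, m))
  ids <- synth_sample_ids(config)
  cg <- synth_chemogroup_of(config)
  design <- data.frame(sample_id = ids, site = substr(ids, 1, 1),
                       depth_m = NA_real_, site_name = NA_character_,
                       stringsAsFactors = FALSE)
  if (config$n_sites == 7L && config$replicates_per_site == 3L) {
    pd <- palmer_design()
    design <- pd[match(ids, pd$sample_id), ]
    rownames(design) <- NULL
  }
  ground_truth <- list(
    samples = data.frame(
      sample_id = ids, site = substr(ids, 1, 1),
      chemogroup = unname(cg[ids]),
      vapply(markers, function(m)
        unname(attr(sequences[[m]], "phylogroup")[ids]),
        character(length(ids))),
      stringsAsFactors = FALSE, check.names = FALSE
    ),
    features = attr(profiles, "features"),
    realized_between_similarity = attr(profiles, "realized_between"),
    expected_within_similarity = attr(profiles, "expected_within")
  )
  names(ground_truth$samples)[4:(3 + length(markers))] <-
    paste0("phylogroup_", markers)
  bundle <- list(peaks = peaks, design = design, sequences = sequences,
                 profiles = profiles, ground_truth = ground_truth,
                 config = config)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    pk <- peaks[, c("sample_id", "rt_min", "height", "base_mass", "envelope")]
    pk$rt_min <- sprintf("%.17g", pk$rt_min)
    pk$height <- sprintf("%.17g", pk$height)
    utils::write.csv(pk, file.path(dir, "peaks.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(design, file.path(dir, "design.csv"),
                     row.names = FALSE, quote = FALSE)
    for (m in markers) {
      con <- file(file.path(dir, paste0(m, ".fasta")), "w")
      aln <- sequences[[m]]
      for (id in rownames(aln))
        writeLines(c(paste0(">", id), paste(aln[id, ], collapse = "")), con)
      close(con)
    }
    gt <- ground_truth
    gt$realized_between_similarity <-
      as.data.frame(gt$realized_between_similarity)
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}
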