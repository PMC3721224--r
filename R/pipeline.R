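#' Pipeline configuration
#'
#' Collects every tunable of the analysis stages with its default. Unknown
#' keys are rejected so a typo cannot silently fall back to a default.
#'
#' @param ... Named overrides of the defaults: `threshold` (relative-height
#'   cutoff, %), `rt_window` (minutes), `rt_tol` (minutes), `mass_tol`
#'   (amu), `min_occurrence`, `cut_similarity` (%), `max_halogens`,
#'   `min_score`, `min_halogens`, `k_phylogroups`, `divergence_thresholds`
#'   (named proportions per marker), `seed`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    threshold = 10, rt_window = c(10, 30), rt_tol = 0.10, mass_tol = 1,
    min_occurrence = 1L, cut_similarity = 50, max_halogens = 8L,
    min_score = 0.95, min_halogens = 2L, k_phylogroups = 2L,
    divergence_thresholds = c(cox1 = 0.021, rbcL = 0.011), seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown pipeline_config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  class(cfg) <- "pipeline_config"
  cfg
}

#' Annotate matched features with halogen compositions
#'
#' Runs [classify_polyhalogenated] on the representative isotope envelope
#' of every feature in a table (features without a recorded envelope are
#' left unannotated).
#'
#' @param ft A `feature_table` whose `features` carry envelope strings.
#' @inheritParams classify_polyhalogenated
#' @return Data frame `feature_id`, `rt`, `base_mass`, `best_n_cl`,
#'   `best_n_br`, `score`, `polyhalogenated`.
#' @export
annotate_features <- function(ft, max_total = 8L, min_score = 0.95,
                              min_halogens = 2L) {
  feats <- ft$features
  rows <- lapply(seq_len(nrow(feats)), function(i) {
    out <- data.frame(feature_id = colnames(ft$values)[i],
                      rt = feats$rt[i], base_mass = feats$base_mass[i],
                      best_n_cl = NA_integer_, best_n_br = NA_integer_,
                      score = NA_real_, polyhalogenated = NA,
                      stringsAsFactors = FALSE)
    env <- parse_envelope_string(feats$envelope[i])
    if (!is.null(env)) {
      cl <- classify_polyhalogenated(env, min_halogens = min_halogens,
                                     min_score = min_score,
                                     max_total = max_total)
      out$best_n_cl <- cl$n_cl; out$best_n_br <- cl$n_br
      out$score <- cl$score; out$polyhalogenated <- cl$polyhalogenated
    }
    out
  })
  do.call(rbind, rows)
}

write_matrix_csv <- function(m, path, digits = 4) {
  df <- data.frame(id = rownames(m),
                   round(as.data.frame(m), digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Run the full metabogenomic pipeline
#'
#' Features -> chemotype -> phylo -> integrate, in order. Inputs may be
#' file paths (as written by [simulate_study]) or in-memory objects. When
#' a marker FASTA is missing the chemical stages still run and the genetic
#' and integration stages for that marker are skipped with a warning.
#' All intermediates are written under `out_dir` when given (matrices at 4
#' decimal places; full precision is kept in the returned objects).
#'
#' @param peaks Peak table: path to a CSV or a data frame
#'   (see [read_peak_table]).
#' @param fasta Named list/vector of per-marker FASTA paths (or alignment
#'   matrices); may be `NULL` or empty.
#' @param design Study design: path, or data frame with `sample_id`,
#'   `site`.
#' @param out_dir Optional output directory for intermediates.
#' @param config A [pipeline_config].
#' @return List of class `pipeline_result` with `feature_table`,
#'   `annotation`, `resemblance`, `dendrogram`, `chemogroups`, per-marker
#'   `phylo` (distances, tree, phylogroups, divergence) and `report`.
#' @export
run_pipeline <- function(peaks, fasta = NULL, design = NULL, out_dir = NULL,
                         config = pipeline_config()) {
  if (is.character(peaks)) peaks <- read_peak_table(peaks)
  if (is.character(design)) design <- utils::read.csv(design,
                                                      stringsAsFactors = FALSE)
  if (!is.null(design)) design$site <- as.character(design$site)
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  pk <- preprocess_peaks(peaks, threshold = config$threshold,
                         rt_window = config$rt_window)
  ft <- match_features(pk, rt_tol = config$rt_tol,
                       mass_tol = config$mass_tol,
                       min_occurrence = config$min_occurrence)
  annotation <- annotate_features(ft, max_total = config$max_halogens,
                                  min_score = config$min_score,
                                  min_halogens = config$min_halogens)
  d <- resemblance_matrix(ft)
  hc <- upgma(d)
  chemo <- cut_dendrogram(hc, config$cut_similarity, prefix = "CG")

  if (!is.null(out_dir)) {
    write_feature_table(ft, file.path(out_dir, "feature_table.csv"))
    utils::write.csv(annotation, file.path(out_dir, "annotation.csv"),
                     row.names = FALSE)
    write_matrix_csv(similarity_matrix(d),
                     file.path(out_dir, "similarity_pct.csv"))
    dendrogram_newick(hc, file.path(out_dir, "dendrogram.nwk"))
    utils::write.csv(chemo, file.path(out_dir, "chemogroups.csv"),
                     row.names = FALSE)
  }

  phylo <- list()
  if (length(fasta)) {
    for (m in names(fasta)) {
      src <- fasta[[m]]
      if (is.character(src) && length(src) == 1L) {
        if (!file.exists(src)) {
          warning("FASTA for marker ", m, " not found at ", src,
                  "; skipping the genetic stage for this marker",
                  call. = FALSE)
          next
        }
        aln <- read_alignment(src, marker = m)
      } else aln <- src
      pd <- p_distance_matrix(aln)
      tree <- neighbor_joining(pd)
      pg <- assign_phylogroups(tree, k = config$k_phylogroups)
      thr <- config$divergence_thresholds
      div <- divergence_report(pd, pg, marker = m,
                               conspecific_threshold =
                                 if (m %in% names(thr)) thr[[m]] else NULL)
      phylo[[m]] <- list(distances = pd, tree = tree, phylogroups = pg,
                         divergence = div)
      if (!is.null(out_dir)) {
        write_matrix_csv(100 * as.matrix(pd),
                         file.path(out_dir, paste0(m, "_pdist_pct.csv")))
        ape::write.tree(tree, file.path(out_dir, paste0(m, "_nj.nwk")))
        utils::write.csv(phylo[[m]]$phylogroups,
                         file.path(out_dir, paste0(m, "_phylogroups.csv")),
                         row.names = FALSE)
      }
    }
  } else if (!is.null(fasta)) {
    warning("no marker FASTA given; genetic stages skipped", call. = FALSE)
  }

  report <- NULL
  if (length(phylo) && !is.null(design)) {
    report <- integration_report(
      chemo, lapply(phylo, `[[`, "phylogroups"), design)
    if (!is.null(out_dir))
      write_report_json(report, file.path(out_dir, "report.json"))
  } else if (!is.null(design)) {
    report <- list(
      coverage = list(chemogroup = nrow(chemo)),
      site_purity = site_purity(chemo, design)
    )
  }

  structure(
    list(feature_table = ft, annotation = annotation, resemblance = d,
         dendrogram = hc, chemogroups = chemo, phylo = phylo,
         report = report, config = config),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", nrow(x$feature_table$values), " samples, ",
      ncol(x$feature_table$values), " features, ",
      length(unique(x$chemogroups$group)), " chemogroups",
      if (length(x$phylo)) paste0(", markers: ",
                                  paste(names(x$phylo), collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}
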