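#' Read a per-sample GC/MS peak table
#'
#' Expected columns: `sample_id`, `rt_min` (retention time, minutes),
#' `height` (detector counts, > 0), and optionally `base_mass` (nominal m/z
#' of the lightest isotopologue) and `envelope` (semicolon-joined relative
#' abundances).
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return Data frame of peaks, one row per peak.
#' @export
read_peak_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "rt_min", "height")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("peak table ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (col in c("rt_min", "height")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("peak table ", path, ": non-numeric ", col, " at data line ",
           bad[1L], call. = FALSE)
    df[[col]] <- v
  }
  if (any(is.na(df$rt_min) | df$rt_min <= 0))
    stop("peak table ", path, ": retention times must be positive",
         call. = FALSE)
  if (any(is.na(df$height) | df$height <= 0))
    stop("peak table ", path, ": heights must be positive", call. = FALSE)
  if (!"base_mass" %in% names(df)) df$base_mass <- NA_real_
  if (!"envelope" %in% names(df)) df$envelope <- NA_character_
  df$base_mass <- suppressWarnings(as.numeric(df$base_mass))
  df
}

#' Base-peak-relative heights within one chromatogram
#'
#' Divides every peak height by the height of the most abundant peak of the
#' same run and scales by 100, so the base peak maps to exactly 100%.
#'
#' @param heights Numeric vector of raw peak heights (> 0) from one run.
#' @return Relative heights in percent; the maximum is exactly 100.
#' @export
normalize_heights <- function(heights) {
  heights <- as.numeric(heights)
  if (length(heights) < 1L)
    stop("cannot normalize an empty run", call. = FALSE)
  if (any(!is.finite(heights)) || any(heights <= 0))
    stop("peak heights must be positive and finite", call. = FALSE)
  heights / max(heights) * 100
}

#' Retain peaks above the relative-height threshold inside the rt window
#'
#' Keeps peaks whose relative height is strictly greater than `threshold`
#' and whose retention time lies inside the closed window `rt_window`.
#'
#' @param peaks Data frame with columns `rt_min` and `rel_height`.
#' @param threshold Relative-height threshold in percent (default 10).
#' @param rt_window Closed retention-time window in minutes (default
#'   `c(10, 30)`).
#' @return The retained rows of `peaks`.
#' @export
filter_peaks <- function(peaks, threshold = 10, rt_window = c(10, 30)) {
  if (threshold <= 0 || threshold >= 100)
    stop("threshold must lie in (0, 100)", call. = FALSE)
  keep <- peaks$rel_height > threshold &
    peaks$rt_min >= rt_window[1L] & peaks$rt_min <= rt_window[2L]
  peaks[keep, , drop = FALSE]
}

#' Normalize and filter a multi-sample peak table
#'
#' Applies [normalize_heights] per sample (each chromatogram's base peak
#' defines its own 100%), then [filter_peaks]. Filtering precedes
#' cross-sample matching, so a feature below threshold in one sample stays
#' absent (0) there even when it recurs elsewhere.
#'
#' @param peaks Data frame as from [read_peak_table].
#' @inheritParams filter_peaks
#' @return Peak data frame with an added `rel_height` column, filtered.
#' @export
preprocess_peaks <- function(peaks, threshold = 10, rt_window = c(10, 30)) {
  if (nrow(peaks) < 1L) stop("empty peak table", call. = FALSE)
  parts <- split(peaks, peaks$sample_id)
  parts <- lapply(parts, function(p) {
    p$rel_height <- normalize_heights(p$height)
    p
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  filter_peaks(out, threshold = threshold, rt_window = rt_window)
}

#' Match peaks across samples into recurring features
#'
#' Greedy single-linkage binning in retention-time order: each peak joins an
#' existing feature bin when its rt lies within `rt_tol` of the bin's
#' consensus (running mean) rt and, when both masses are known, its base
#' mass lies within `mass_tol` of the bin's consensus mass. Each bin holds
#' at most one peak per sample; when a second peak of the same sample
#' matches a bin, the peak closer to the consensus rt stays and the other
#' seeds a new bin. Processing order (ascending rt, ties by sample id) makes
#' the result independent of input row order.
#'
#' @param peaks Preprocessed peaks from [preprocess_peaks] (columns
#'   `sample_id`, `rt_min`, `rel_height`, optionally `base_mass`,
#'   `envelope`).
#' @param rt_tol Retention-time tolerance in minutes (default 0.10).
#' @param mass_tol Base-mass tolerance in amu (default 1).
#' @param min_occurrence Minimum number of samples a feature must occur in
#'   to be kept (default 1).
#' @return A `feature_table`: list with `values` (samples x features matrix
#'   of relative heights, 0 = absent), `features` (data frame of consensus
#'   `rt`, `base_mass`, representative `envelope`), `samples`.
#' @export
match_features <- function(peaks, rt_tol = 0.10, mass_tol = 1,
                           min_occurrence = 1L) {
  if (nrow(peaks) < 1L) {
    return(feature_table(matrix(numeric(0), 0, 0),
                         data.frame(rt = numeric(0), base_mass = numeric(0),
                                    envelope = character(0),
                                    stringsAsFactors = FALSE)))
  }
  if (!"base_mass" %in% names(peaks)) peaks$base_mass <- NA_real_
  if (!"envelope" %in% names(peaks)) peaks$envelope <- NA_character_
  pk <- peaks[order(peaks$rt_min, peaks$sample_id), , drop = FALSE]

  # running-mean consensus per bin
  rt_sum <- numeric(0); rt_n <- integer(0)
  ms_sum <- numeric(0); ms_n <- integer(0)
  entries <- list()  # per bin: named list sample -> c(rt, rel)
  envs <- character(0)

  new_bin <- function(rt, ms, sm, rel, env) {
    rt_sum[length(rt_sum) + 1L] <<- rt
    rt_n[length(rt_n) + 1L] <<- 1L
    ms_sum[length(ms_sum) + 1L] <<- if (is.na(ms)) 0 else ms
    ms_n[length(ms_n) + 1L] <<- if (is.na(ms)) 0L else 1L
    e <- list(); e[[sm]] <- c(rt = rt, rel = rel)
    entries[[length(entries) + 1L]] <<- e
    envs[length(envs) + 1L] <<- env
  }
  add_to_bin <- function(b, rt, ms, sm, rel, env) {
    rt_sum[b] <<- rt_sum[b] + rt
    rt_n[b] <<- rt_n[b] + 1L
    if (!is.na(ms)) { ms_sum[b] <<- ms_sum[b] + ms; ms_n[b] <<- ms_n[b] + 1L }
    e <- entries[[b]]; e[[sm]] <- c(rt = rt, rel = rel)
    entries[[b]] <<- e
    if (is.na(envs[b]) && !is.na(env)) envs[b] <<- env
  }

  for (r in seq_len(nrow(pk))) {
    rt <- pk$rt_min[r]; sm <- as.character(pk$sample_id[r])
    ms <- pk$base_mass[r]; rel <- pk$rel_height[r]; env <- pk$envelope[r]
    if (length(rt_sum)) {
      brt <- rt_sum / rt_n
      bms <- ifelse(ms_n > 0, ms_sum / pmax(ms_n, 1L), NA_real_)
      ok <- abs(brt - rt) <= rt_tol &
        (is.na(ms) | is.na(bms) | abs(bms - ms) <= mass_tol)
      cand <- which(ok)
    } else cand <- integer(0)
    if (!length(cand)) { new_bin(rt, ms, sm, rel, env); next }
    b <- cand[which.min(abs(rt_sum[cand] / rt_n[cand] - rt))]
    held <- entries[[b]][[sm]]
    if (is.null(held)) {
      add_to_bin(b, rt, ms, sm, rel, env)
    } else {
      consensus <- rt_sum[b] / rt_n[b]
      if (abs(held["rt"] - consensus) <= abs(rt - consensus)) {
        new_bin(rt, ms, sm, rel, env)            # incoming loses, seeds new bin
      } else {                                   # incoming wins, displace holder
        rt_sum[b] <- rt_sum[b] - held["rt"] + rt
        e <- entries[[b]]; e[[sm]] <- c(rt = rt, rel = rel); entries[[b]] <- e
        new_bin(unname(held["rt"]), NA_real_, sm, unname(held["rel"]),
                NA_character_)
      }
    }
  }

  occ <- vapply(entries, length, integer(1))
  keep <- which(occ >= min_occurrence)
  keep <- keep[order(rt_sum[keep] / rt_n[keep])]
  samples <- sort(unique(as.character(pk$sample_id)))
  values <- matrix(0, length(samples), length(keep),
                   dimnames = list(samples, NULL))
  for (j in seq_along(keep)) {
    e <- entries[[keep[j]]]
    for (sm in names(e)) values[sm, j] <- e[[sm]]["rel"]
  }
  feats <- data.frame(
    rt = rt_sum[keep] / rt_n[keep],
    base_mass = ifelse(ms_n[keep] > 0, ms_sum[keep] / pmax(ms_n[keep], 1L),
                       NA_real_),
    envelope = envs[keep],
    stringsAsFactors = FALSE
  )
  feature_table(values, feats)
}

#' Construct a feature table
#'
#' @param values Samples x features numeric matrix of relative heights (%).
#' @param features Data frame with one row per feature (`rt`, `base_mass`,
#'   optionally `envelope`).
#' @return Object of class `feature_table`.
#' @export
feature_table <- function(values, features) {
  stopifnot(is.matrix(values), nrow(features) == ncol(values))
  colnames(values) <- feature_ids(features)
  structure(list(values = values, features = features,
                 samples = rownames(values)),
            class = "feature_table")
}

feature_ids <- function(features) {
  if (nrow(features) == 0L) return(character(0))
  m <- ifelse(is.na(features$base_mass), "NA",
              sprintf("%.17g", features$base_mass))
  sprintf("rt%s_m%s",
          sprintf("%.17g", features$rt), m)
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$values), " samples x ", ncol(x$values),
      " features\n", sep = "")
  invisible(x)
}

#' Write / read a feature table as CSV
#'
#' Samples are rows; feature columns are headed `rt<minutes>_m<mass>`.
#' Values are written at full double precision so the round trip is
#' lossless.
#'
#' @param ft A `feature_table`.
#' @param path Output / input CSV path.
#' @return `read_feature_table` returns a `feature_table`.
#' @export
write_feature_table <- function(ft, path) {
  vals <- ft$values
  if (nrow(vals) == 0L) {
    writeLines(paste(c("sample_id", colnames(vals)), collapse = ","), path)
    return(invisible(path))
  }
  body <- matrix(sprintf("%.17g", vals),
                 nrow = nrow(vals), dimnames = dimnames(vals))
  df <- data.frame(sample_id = rownames(vals), body, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop("feature table ", path, " lacks a sample_id column", call. = FALSE)
  cols <- setdiff(names(df), "sample_id")
  vals <- as.matrix(df[, cols, drop = FALSE])
  if (length(cols) && !is.numeric(vals))
    stop("feature table ", path, ": non-numeric cell values", call. = FALSE)
  if (!length(cols)) vals <- matrix(numeric(0), nrow(df), 0)
  rownames(vals) <- df$sample_id
  parse1 <- function(id) {
    m <- regmatches(id, regexec("^rt([0-9.eE+-]+)_m(.+)$", id))[[1L]]
    if (length(m) != 3L)
      stop("feature table ", path, ": malformed column header '", id, "'",
           call. = FALSE)
    c(rt = as.numeric(m[2L]),
      base_mass = if (m[3L] == "NA") NA_real_ else as.numeric(m[3L]))
  }
  if (length(cols)) {
    meta <- t(vapply(cols, parse1, numeric(2)))
    feats <- data.frame(rt = meta[, "rt"], base_mass = meta[, "base_mass"],
                        envelope = NA_character_, stringsAsFactors = FALSE)
  } else {
    feats <- data.frame(rt = numeric(0), base_mass = numeric(0),
                        envelope = character(0), stringsAsFactors = FALSE)
  }
  feature_table(vals, feats)
}
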