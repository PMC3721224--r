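#' Natural isotope abundances used throughout the package
#'
#' Fractional abundances of the two stable isotopes of chlorine and bromine.
#' Both elements have isotope pairs 2 amu apart, which is why polyhalogenated
#' ions show the characteristic clusters of peaks at 2 amu spacing that mark
#' halogenated monoterpenes in negative chemical ionization GC/MS spectra.
#'
#' @format Named numeric vectors of length 2 (light isotope first).
#' @name isotope_abundances
NULL

#' @rdname isotope_abundances
#' @export
CL_ISOTOPES <- c(cl35 = 0.7576, cl37 = 0.2424)

#' @rdname isotope_abundances
#' @export
BR_ISOTOPES <- c(br79 = 0.5069, br81 = 0.4931)

C13_ABUNDANCE <- 0.0107

#' Construct an isotopologue envelope
#'
#' An envelope is the ordered series of relative abundances of the
#' isotopologue peaks of one ion, read from the lightest peak upward.
#' For chlorine/bromine chemistry adjacent isotopologues sit 2 amu apart.
#'
#' @param abundances Numeric vector of relative abundances, lightest peak
#'   first. Must be non-negative, finite, with at least one positive entry.
#' @param base_mass Nominal m/z of the lightest isotopologue (optional).
#' @param spacing_amu Mass gap between adjacent isotopologues (default 2).
#' @param normalization How the abundances are scaled: `"as_given"` (no
#'   rescaling), `"first"` (lightest peak = 1) or `"max"` (tallest peak = 1).
#' @return An object of class `isotope_envelope`.
#' @export
isotope_envelope <- function(abundances, base_mass = NA_real_, spacing_amu = 2,
                             normalization = c("as_given", "first", "max")) {
  normalization <- match.arg(normalization)
  abundances <- as.numeric(abundances)
  if (length(abundances) < 1L)
    stop("an isotope envelope needs at least one peak", call. = FALSE)
  if (any(!is.finite(abundances)) || any(abundances < 0))
    stop("envelope abundances must be finite and non-negative", call. = FALSE)
  if (all(abundances == 0))
    stop("envelope abundances must not be all zero", call. = FALSE)
  if (normalization == "first") {
    if (abundances[1L] <= 0)
      stop("cannot normalize to a zero first peak", call. = FALSE)
    abundances <- abundances / abundances[1L]
  } else if (normalization == "max") {
    abundances <- abundances / max(abundances)
  }
  structure(
    list(abundances = abundances, base_mass = base_mass,
         spacing_amu = spacing_amu, normalization = normalization),
    class = "isotope_envelope"
  )
}

#' @export
print.isotope_envelope <- function(x, ...) {
  cat("<isotope_envelope> ", length(x$abundances), " peaks, ",
      x$spacing_amu, " amu apart", sep = "")
  if (!is.na(x$base_mass)) cat(", base m/z ", x$base_mass, sep = "")
  cat("\n  ", paste(signif(x$abundances, 4), collapse = " : "), "\n", sep = "")
  invisible(x)
}

# Coerce envelope-like input (numeric vector or isotope_envelope) to abundances.
as_abundances <- function(x) {
  if (inherits(x, "isotope_envelope")) return(x$abundances)
  a <- as.numeric(x)
  if (length(a) < 1L || any(!is.finite(a)) || any(a < 0))
    stop("envelope must be a non-empty vector of finite, non-negative abundances",
         call. = FALSE)
  a
}

# Convolve two discrete abundance distributions (polynomial product).
convolve_dist <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' Theoretical halogen isotopologue envelope
#'
#' Computes the isotopologue envelope of an ion carrying `n_cl` chlorine and
#' `n_br` bromine atoms by convolving the two-point isotope distributions of
#' each atom (a product of binomials). Peaks are 2 amu apart and the result
#' is normalized so the lightest peak equals 1. Contributions from other
#' polyisotopic elements are ignored by default; an optional carbon count
#' adds the 13C satellite peaks on a 1 amu grid.
#'
#' @param n_cl,n_br Non-negative integer counts of Cl and Br atoms.
#' @param base_mass Optional nominal m/z of the lightest isotopologue.
#' @param n_carbon Optional number of carbon atoms; when positive, 13C
#'   satellites are included and the returned envelope uses 1 amu spacing.
#' @param abundances List with elements `cl` and `br` giving the isotope
#'   abundance pairs; defaults to the natural values [CL_ISOTOPES] and
#'   [BR_ISOTOPES].
#' @return An [isotope_envelope] of length `n_cl + n_br + 1` (halogen-only
#'   model), lightest peak = 1.
#' @examples
#' theoretical_envelope(0, 2)  # the ~1:2:1 dibromo pattern
#' @export
theoretical_envelope <- function(n_cl, n_br, base_mass = NA_real_,
                                 n_carbon = 0L,
                                 abundances = list(cl = CL_ISOTOPES,
                                                   br = BR_ISOTOPES)) {
  if (length(n_cl) != 1L || length(n_br) != 1L ||
      is.na(n_cl) || is.na(n_br) || n_cl < 0 || n_br < 0 ||
      n_cl != floor(n_cl) || n_br != floor(n_br))
    stop("halogen counts must be single non-negative integers", call. = FALSE)
  env <- 1
  for (i in seq_len(n_cl)) env <- convolve_dist(env, abundances$cl)
  for (i in seq_len(n_br)) env <- convolve_dist(env, abundances$br)
  spacing <- 2
  if (n_carbon > 0) {
    # expand the 2 amu halogen grid to 1 amu, then fold in the 13C binomial
    fine <- numeric(2L * length(env) - 1L)
    fine[seq_along(env) * 2L - 1L] <- env
    carbon <- stats::dbinom(0:n_carbon, n_carbon, C13_ABUNDANCE)
    env <- convolve_dist(fine, carbon)
    spacing <- 1
  }
  isotope_envelope(env, base_mass = base_mass, spacing_amu = spacing,
                   normalization = "first")
}

#' Cosine similarity between two isotopologue envelopes
#'
#' Both abundance vectors are scaled to unit norm, so the score is invariant
#' to the overall intensity scale of either envelope; the shorter vector is
#' zero-padded to the longer one. The score is 1 exactly when the envelopes
#' are proportional and 0 when they share no peaks.
#'
#' @param observed,theoretical Envelopes ([isotope_envelope] or bare
#'   abundance vectors).
#' @return Similarity in `[0, 1]`.
#' @export
envelope_similarity <- function(observed, theoretical) {
  a <- as_abundances(observed)
  b <- as_abundances(theoretical)
  if (all(a == 0) || all(b == 0))
    stop("cannot score an all-zero envelope", call. = FALSE)
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  s <- sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  min(max(s, 0), 1)
}

#' Infer halogen composition from an observed envelope
#'
#' Enumerates every (n_cl, n_br) composition with at most `max_total`
#' halogens, scores the observed envelope against each theoretical envelope
#' with [envelope_similarity], and returns the full ranked hypothesis list.
#' The observed envelope is taken as complete: a composition of n halogens
#' predicts n + 1 isotopologue peaks, so compositions predicting more peaks
#' than were observed are not candidates, while compositions predicting
#' fewer are scored zero-padded (and can never outrank an exact-length
#' proportional match). Ties are broken deterministically: fewer total
#' halogens first, then more chlorines.
#'
#' @param observed Observed envelope (any intensity scale).
#' @param max_total Search bound on n_cl + n_br (default 8).
#' @inheritParams theoretical_envelope
#' @return A data frame with columns `n_cl`, `n_br`, `score`, `rank`,
#'   ordered by rank.
#' @export
infer_halogens <- function(observed, max_total = 8L,
                           abundances = list(cl = CL_ISOTOPES,
                                             br = BR_ISOTOPES)) {
  obs <- as_abundances(observed)
  if (all(obs == 0)) stop("observed envelope is all zero", call. = FALSE)
  if (max_total < 1L) stop("max_total must be at least 1", call. = FALSE)
  bound <- min(max_total, length(obs) - 1L)
  comps <- expand.grid(n_cl = 0:bound, n_br = 0:bound)
  comps <- comps[comps$n_cl + comps$n_br <= bound, , drop = FALSE]
  comps$score <- vapply(seq_len(nrow(comps)), function(i) {
    theo <- theoretical_envelope(comps$n_cl[i], comps$n_br[i],
                                 abundances = abundances)
    envelope_similarity(obs, theo)
  }, numeric(1))
  total <- comps$n_cl + comps$n_br
  ord <- order(-comps$score, total, -comps$n_cl)
  comps <- comps[ord, , drop = FALSE]
  comps$rank <- seq_len(nrow(comps))
  rownames(comps) <- NULL
  comps
}

#' Classify an observed envelope as polyhalogenated
#'
#' An ion is called polyhalogenated when the best-ranked halogen hypothesis
#' carries at least `min_halogens` halogen atoms and its envelope similarity
#' reaches `min_score`.
#'
#' @inheritParams infer_halogens
#' @param min_halogens Minimum total halogens for a positive call (default 2).
#' @param min_score Minimum envelope similarity for a positive call
#'   (default 0.95).
#' @return List with `polyhalogenated` (logical), `n_cl`, `n_br`, `score`.
#' @export
classify_polyhalogenated <- function(observed, min_halogens = 2L,
                                     min_score = 0.95, max_total = 8L) {
  hyp <- infer_halogens(observed, max_total = max_total)
  best <- hyp[1L, ]
  list(
    polyhalogenated = (best$n_cl + best$n_br) >= min_halogens &&
      best$score >= min_score,
    n_cl = best$n_cl, n_br = best$n_br, score = best$score
  )
}

# Parse "a0;a1;...;an" envelope strings (used in peak tables and envelope CSVs).
parse_envelope_string <- function(x) {
  if (is.na(x) || !nzchar(x)) return(NULL)
  as.numeric(strsplit(x, ";", fixed = TRUE)[[1L]])
}

format_envelope_string <- function(abundances, digits = 6) {
  paste(signif(abundances, digits), collapse = ";")
}

#' Read an envelope CSV
#'
#' Expected columns: `base_mass`, `spacing`, `abundances` (semicolon-joined),
#' and optionally `feature_id`.
#'
#' @param path Path to the CSV file.
#' @return Data frame with a list-column `abundances`.
#' @export
read_envelope_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("base_mass", "spacing", "abundances")
  if (!all(need %in% names(df)))
    stop("envelope CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"feature_id" %in% names(df))
    df$feature_id <- sprintf("env%02d", seq_len(nrow(df)))
  df$abundances <- lapply(df$abundances, parse_envelope_string)
  df
}

#' Annotate a set of observed envelopes with halogen compositions
#'
#' @param envelopes Data frame from [read_envelope_csv], or any data frame
#'   with columns `feature_id` and a list-column `abundances`.
#' @inheritParams classify_polyhalogenated
#' @return Data frame `feature_id`, `best_n_cl`, `best_n_br`, `score`,
#'   `polyhalogenated`.
#' @export
annotate_envelopes <- function(envelopes, max_total = 8L, min_score = 0.95,
                               min_halogens = 2L) {
  rows <- lapply(seq_len(nrow(envelopes)), function(i) {
    cl <- classify_polyhalogenated(envelopes$abundances[[i]],
                                   min_halogens = min_halogens,
                                   min_score = min_score,
                                   max_total = max_total)
    data.frame(feature_id = envelopes$feature_id[i],
               best_n_cl = cl$n_cl, best_n_br = cl$n_br,
               score = cl$score, polyhalogenated = cl$polyhalogenated,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
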