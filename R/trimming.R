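#' Parameters of the three-step map-driven trimming algorithm
#'
#' Defaults reproduce the procedure's printed typical values: smoothing
#' window = minimum domain length of ten residues, step-1 cutoff at the
#' top-half mean minus three standard deviations, step-2 end cutoff at
#' mean minus two standard deviations, and the step-3 segment cutoff at
#' the higher of 0.64 (= `reasonable_cc_ratio`^2) times and 0.3
#' (= 2 * `reasonable_cc_diff`) below the top-half mean segment
#' correlation.
#'
#' @param minimum_domain_length smoothing window and shortest surviving
#'   segment, in residues (default 10).
#' @param cc_sd_ratio step-1 multiplier k in cutoff = mean - k sd
#'   (default 3).
#' @param cc_sd_ratio_end step-2 end-trimming multiplier (default 2).
#' @param reasonable_cc_ratio step-3 ratio; its square scales the
#'   top-half mean (default 0.8, scale 0.64).
#' @param reasonable_cc_diff step-3 difference; twice it is subtracted
#'   from the top-half mean (default 0.15, offset 0.3).
#' @param use_plddt also require low pLDDT for step-1 removal on
#'   predicted models (default TRUE).
#' @param require_both with `use_plddt`, remove only when BOTH tracks are
#'   below cutoff (default TRUE; FALSE = either).
#' @param mask_radius per-residue correlation mask radius in Angstrom.
#' @param resolution map resolution for the model-derived map.
#' @return list of class `trim_params`.
#' @export
trim_params <- function(minimum_domain_length = 10,
                        cc_sd_ratio = 3,
                        cc_sd_ratio_end = 2,
                        reasonable_cc_ratio = 0.8,
                        reasonable_cc_diff = 0.15,
                        use_plddt = TRUE,
                        require_both = TRUE,
                        mask_radius = 2.5,
                        resolution = 3.0) {
  .assert(cc_sd_ratio > 0 && cc_sd_ratio_end > 0, "sd multipliers must be > 0")
  .assert(reasonable_cc_ratio > 0 && reasonable_cc_ratio <= 1,
          "reasonable_cc_ratio must be in (0, 1]")
  .assert(minimum_domain_length >= 1, "minimum_domain_length must be >= 1")
  structure(list(minimum_domain_length = as.integer(minimum_domain_length),
                 cc_sd_ratio = cc_sd_ratio,
                 cc_sd_ratio_end = cc_sd_ratio_end,
                 reasonable_cc_ratio = reasonable_cc_ratio,
                 reasonable_cc_diff = reasonable_cc_diff,
                 use_plddt = use_plddt,
                 require_both = require_both,
                 mask_radius = mask_radius,
                 resolution = resolution),
            class = "trim_params")
}

# Numerical tolerance on strict below-cutoff tests, so that a track that
# is constant up to floating-point noise (e.g. a model scored against its
# own map, cc == 1 everywhere) is not trimmed by an sd of ~1e-16.
.trim_eps <- 1e-9

#' Cutoff from the highest half of a set of values
#'
#' Sorts descending, keeps the top ceiling(n/2) values and returns their
#' mean minus `k` times their sample standard deviation (ddof 1; sd taken
#' as 0 when fewer than two values survive).
#'
#' @param values numeric vector (non-empty).
#' @param k multiplier on the standard deviation.
#' @return scalar cutoff.
#' @export
top_half_cutoff <- function(values, k) {
  .assert(length(values) >= 1, "top_half_cutoff needs at least one value")
  top <- sort(values, decreasing = TRUE)[seq_len(ceiling(length(values) / 2))]
  s <- if (length(top) < 2) 0 else stats::sd(top)
  mean(top) - k * s
}

#' Step 1: remove low-correlation (and low-confidence) residues
#'
#' A residue is removed when its smoothed local correlation is strictly
#' below the top-half cutoff (mean minus `cc_sd_ratio` standard
#' deviations) and, for predicted models with `use_plddt`, its smoothed
#' pLDDT is also below the corresponding pLDDT cutoff.
#'
#' @param smoothed_cc smoothed per-residue correlation track.
#' @param smoothed_plddt smoothed per-residue pLDDT track or NULL.
#' @param params a [trim_params()].
#' @return logical keep-mask, one entry per residue.
#' @export
step1_remove_low <- function(smoothed_cc, smoothed_plddt = NULL,
                             params = trim_params()) {
  cut_cc <- top_half_cutoff(smoothed_cc, params$cc_sd_ratio)
  low_cc <- smoothed_cc < cut_cc - .trim_eps
  if (params$use_plddt && !is.null(smoothed_plddt)) {
    cut_p <- top_half_cutoff(smoothed_plddt, params$cc_sd_ratio)
    low_p <- smoothed_plddt < cut_p - .trim_eps
    remove <- if (params$require_both) low_cc & low_p else low_cc | low_p
  } else {
    remove <- low_cc
  }
  !remove
}

#' Step 2: trim weak segment ends, drop short segments
#'
#' Segments are rebuilt from the residues surviving step 1. From each
#' segment end inward, residues are stripped while both the raw and the
#' smoothed correlation are strictly below the end cutoff (top-half mean
#' minus `cc_sd_ratio_end` standard deviations of the raw correlations of
#' surviving residues). Segments shorter than the smoothing window
#' (`minimum_domain_length`) are then removed entirely.
#'
#' @param keep step-1 keep-mask.
#' @param raw_cc raw per-residue correlation track (full length).
#' @param smoothed_cc smoothed track (full length).
#' @param starts segment-start flags for the full-length model.
#' @param params a [trim_params()].
#' @return logical keep-mask (full length).
#' @export
step2_trim_ends <- function(keep, raw_cc, smoothed_cc, starts,
                            params = trim_params()) {
  n <- length(keep)
  if (!any(keep)) return(keep)
  cut_end <- top_half_cutoff(raw_cc[keep], params$cc_sd_ratio_end)
  segs <- .kept_segments(keep, starts)
  out <- rep(FALSE, n)
  ce <- cut_end - .trim_eps
  for (seg in segs) {
    lo <- 1L; hi <- length(seg)
    while (lo <= hi && raw_cc[seg[lo]] < ce && smoothed_cc[seg[lo]] < ce)
      lo <- lo + 1L
    while (hi >= lo && raw_cc[seg[hi]] < ce && smoothed_cc[seg[hi]] < ce)
      hi <- hi - 1L
    if (hi - lo + 1L >= params$minimum_domain_length)
      out[seg[lo:hi]] <- TRUE
  }
  out
}

# Contiguous runs of kept residues, never crossing segment starts.
.kept_segments <- function(keep, starts) {
  n <- length(keep)
  segs <- list()
  cur <- integer(0)
  for (i in seq_len(n)) {
    if (!keep[i] || (length(cur) && starts[i])) {
      if (length(cur)) segs[[length(segs) + 1L]] <- cur
      cur <- integer(0)
    }
    if (keep[i]) cur <- c(cur, i)
  }
  if (length(cur)) segs[[length(segs) + 1L]] <- cur
  segs
}

#' Step 3: drop segments with much lower mean correlation
#'
#' Computes the mean of the top half of the segment mean correlations,
#' m, and the cutoff max(`reasonable_cc_ratio`^2 * m,
#' m - 2 * `reasonable_cc_diff`); keeps segments whose mean correlation
#' is at or above the cutoff.
#'
#' @param mean_ccs per-segment mean correlation values (non-empty).
#' @param params a [trim_params()].
#' @return logical keep flags, one per segment.
#' @export
step3_drop_weak_segments <- function(mean_ccs, params = trim_params()) {
  .assert(length(mean_ccs) >= 1, "no segments")
  top <- sort(mean_ccs, decreasing = TRUE)[seq_len(ceiling(length(mean_ccs) / 2))]
  m <- mean(top)
  cutoff <- max(params$reasonable_cc_ratio^2 * m,
                m - 2 * params$reasonable_cc_diff)
  mean_ccs >= cutoff
}

#' Trim a model to match a density map
#'
#' The full three-step procedure: per-residue local map-model
#' correlations are smoothed over `minimum_domain_length` residues;
#' step 1 removes residues below the top-half mean minus
#' `cc_sd_ratio` standard deviations (for predicted models jointly with
#' a smoothed-pLDDT cutoff); step 2 strips weak segment ends at the
#' mean-minus-two-sd cutoff and deletes segments shorter than the
#' smoothing window; step 3 removes whole segments whose mean
#' correlation falls below max(0.64 m, m - 0.3) where m is the top-half
#' mean segment correlation. A new model is assembled from the surviving
#' segments.
#'
#' @param model an [atomic_model()]; pLDDT is taken from the B column
#'   when the model's provenance is "predicted" and `use_plddt` is set.
#' @param map a [density_map()] overlapping the model.
#' @param params a [trim_params()].
#' @return list with `model` (trimmed) and `report` (per-step removal
#'   counts, cutoffs, and the surviving-residue keys).
#' @export
trim_to_map <- function(model, map, params = trim_params()) {
  prof <- local_cc(model, map, mask_radius = params$mask_radius,
                   resolution = params$resolution)
  starts <- segment_starts(model)
  plddt <- NULL
  if (params$use_plddt && identical(model$provenance, "predicted")) {
    plddt <- .residue_plddt(model, confidence_params())
  }
  res <- trim_profile(prof$local_cc, plddt, starts, params)
  n_kept <- sum(res$keep)
  if (n_kept == 0) {
    stop(structure(class = c("itermodel_all_trimmed", "error", "condition"),
                   list(message = "all residues trimmed: no segment survived",
                        call = sys.call(), report = res$report)))
  }
  trimmed <- select_residues(model, res$keep)
  res$report$n_input <- length(res$keep)
  res$report$n_kept <- n_kept
  list(model = trimmed, report = res$report)
}

#' Run the three trimming steps on precomputed tracks
#'
#' The map-free core of [trim_to_map()], operating on a raw correlation
#' track, an optional pLDDT track and segment-start flags.
#'
#' @param raw_cc raw per-residue correlation track.
#' @param plddt raw per-residue pLDDT track or NULL.
#' @param starts segment-start flags.
#' @param params a [trim_params()].
#' @return list with `keep` (logical mask) and `report`.
#' @export
trim_profile <- function(raw_cc, plddt = NULL, starts = NULL,
                         params = trim_params()) {
  n <- length(raw_cc)
  if (is.null(starts)) starts <- c(TRUE, rep(FALSE, max(0, n - 1)))
  w <- params$minimum_domain_length
  sm_cc <- smooth_track(raw_cc, w, starts)
  sm_p <- if (!is.null(plddt)) smooth_track(plddt, w, starts) else NULL
  keep1 <- step1_remove_low(sm_cc, sm_p, params)
  keep2 <- step2_trim_ends(keep1, raw_cc, sm_cc, starts, params)
  segs <- .kept_segments(keep2, starts)
  report <- list(
    cutoff_step1_cc = top_half_cutoff(sm_cc, params$cc_sd_ratio),
    cutoff_step1_plddt = if (!is.null(sm_p))
      top_half_cutoff(sm_p, params$cc_sd_ratio) else NA_real_,
    cutoff_step2 = if (any(keep1))
      top_half_cutoff(raw_cc[keep1], params$cc_sd_ratio_end) else NA_real_,
    removed_step1 = sum(!keep1),
    removed_step2 = sum(keep1) - sum(keep2)
  )
  if (!length(segs)) {
    report$removed_step3 <- 0L
    report$cutoff_step3 <- NA_real_
    return(list(keep = rep(FALSE, n), report = report))
  }
  mean_ccs <- vapply(segs, function(s) mean(raw_cc[s]), numeric(1))
  keep_seg <- step3_drop_weak_segments(mean_ccs, params)
  top <- sort(mean_ccs, decreasing = TRUE)[seq_len(ceiling(length(mean_ccs) / 2))]
  report$cutoff_step3 <- max(params$reasonable_cc_ratio^2 * mean(top),
                             mean(top) - 2 * params$reasonable_cc_diff)
  keep <- rep(FALSE, n)
  for (j in which(keep_seg)) keep[segs[[j]]] <- TRUE
  report$removed_step3 <- sum(keep2) - sum(keep)
  report$segment_mean_cc <- mean_ccs
  list(keep = keep, report = report)
}
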