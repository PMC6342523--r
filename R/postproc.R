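# Post-processing: baseline-normalized DF/F extraction, footprint-based
# precision/recall/F1 against a reference set, and SNR-stratified detection
# metrics with AND/OR bounds.

#' DF/F extraction parameters
#'
#' @param window_seconds running-percentile window (default 100 s).
#' @param percentile fixed percentile level in (0, 50], or NULL for the
#'   automatic density-mode level.
#' @param use_residual include the residual trace r_i in the fluorescence
#'   signal f_i (default TRUE).
#' @return an object of class \code{dff_params}.
#' @export
dff_params <- function(window_seconds = 100, percentile = NULL,
                       use_residual = TRUE) {
  if (!is.null(percentile)) stopifnot(percentile > 0, percentile <= 50)
  structure(list(window_seconds = window_seconds, percentile = percentile,
                 use_residual = use_residual), class = "dff_params")
}

#' Baseline-normalized fluorescence (DF/F) traces
#'
#' For each component: f_i = ||a_i|| (c_i + r_i) is the fluorescence trace;
#' f0_i = BASELINE(f_i + B' a_i) the background-inclusive baseline; and
#' DF/F_i = (f_i - BASELINE(f_i)) / f0_i, with BASELINE the running
#' percentile of \code{\link{baseline_trace}}.
#'
#' @param mov a \code{movie}.
#' @param components a \code{\link{component_set}}.
#' @param background a \code{\link{background_model}} or NULL.
#' @param params a \code{\link{dff_params}}.
#' @return N x T matrix of DF/F traces.
#' @export
extract_dff <- function(mov, components, background = NULL,
                        params = dff_params()) {
  A <- components$footprints; C <- components$traces
  N <- ncol(A); Tt <- ncol(C)
  out <- matrix(0, N, Tt)
  if (N == 0L) return(out)
  Bm <- background_matrix(background, mov)
  R <- mov$data - A %*% C
  if (!identical(Bm, 0)) R <- R - Bm
  for (i in seq_len(N)) {
    a <- A[, i]
    nrm <- sqrt(sum(a^2))
    f_i <- nrm * C[i, ]
    if (params$use_residual) {
      f_i <- f_i + nrm * as.numeric(crossprod(R, a)) / sum(a^2)
    }
    # background seen through the unit footprint direction, so the result
    # is invariant to the arbitrary scale split between a_i and c_i
    bg_proj <- if (identical(Bm, 0)) 0 else as.numeric(crossprod(Bm, a)) / nrm
    f0 <- baseline_trace(f_i + bg_proj, mov$frame_rate,
                         params$window_seconds, params$percentile)
    if (any(f0 <= 0)) {
      stop("non-positive DF/F baseline for component ", i,
           " (degenerate background)")
    }
    out[i, ] <- (f_i - baseline_trace(f_i, mov$frame_rate,
                                      params$window_seconds,
                                      params$percentile)) / f0
  }
  out
}

#' Match estimated components against a reference set
#'
#' Registers the two footprint sets (\code{\link{register_pair}} with the
#' Jaccard distance threshold set to \code{match_threshold}) and reports
#' precision = matched / estimated, recall = matched / reference, and their
#' harmonic mean F1.
#'
#' @param estimated d x N footprint matrix (or \code{component_set}).
#' @param truth d x M reference footprint matrix.
#' @param match_threshold maximum Jaccard distance counted as a match
#'   (default 0.7).
#' @param binarize_threshold mask threshold theta_b.
#' @return list with \code{precision}, \code{recall}, \code{f1},
#'   \code{matched_pairs}, \code{unmatched_est}, \code{unmatched_truth}.
#' @export
match_components <- function(estimated, truth, match_threshold = 0.7,
                             binarize_threshold = 0.2) {
  if (inherits(estimated, "component_set")) estimated <- estimated$footprints
  if (is.list(truth) && !is.null(truth$footprints)) truth <- truth$footprints
  res <- register_pair(estimated, truth,
                       params = reg_params(binarize_threshold,
                                           match_threshold))
  n_match <- nrow(res$matched_pairs)
  n_est <- ncol(estimated); n_truth <- ncol(truth)
  precision <- if (n_est > 0) n_match / n_est else NA_real_
  recall <- if (n_truth > 0) n_match / n_truth else NA_real_
  f1 <- if (isTRUE(precision + recall > 0)) {
    2 * precision * recall / (precision + recall)
  } else if (is.na(precision) || is.na(recall)) NA_real_ else 0
  list(precision = precision, recall = recall, f1 = f1,
       matched_pairs = res$matched_pairs,
       unmatched_est = res$unmatched_1,
       unmatched_truth = res$unmatched_2)
}

#' SNR-stratified detection metrics with AND/OR bounds
#'
#' Given matched pairs of reference and estimated trace SNRs (false
#' positives and negatives padded with SNR 0 on the missing side),
#' computes, at every threshold of the grid, the plain, AND, and OR
#' variants of precision, recall and F1. The AND variant requires both
#' SNRs above the threshold; the OR variant counts a pair when either SNR
#' exceeds the threshold and its partner is detected at all. The bound
#' ordering AND <= plain <= OR holds at every threshold, with equality at
#' threshold zero.
#'
#' @param snr_gt,snr_est equal-length vectors of reference and estimated
#'   SNRs per (padded) pair; zeros mark the missing side.
#' @param grid increasing vector of SNR thresholds (must be non-empty).
#' @return data.frame with columns threshold, precision, recall, f1 and
#'   their _and/_or variants (NA where a denominator is empty).
#' @export
snr_stratified_metrics <- function(snr_gt, snr_est, grid) {
  stopifnot(length(snr_gt) == length(snr_est))
  if (length(grid) == 0L) stop("empty SNR threshold grid")
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  rows <- lapply(grid, function(th) {
    det <- snr_est > 0; ref <- snr_gt > 0
    prec <- frac(sum(snr_est > th & ref), sum(snr_est > th))
    rec <- frac(sum(snr_gt > th & det), sum(snr_gt > th))
    prec_and <- frac(sum(snr_est > th & snr_gt > th), sum(snr_est > th))
    rec_and <- frac(sum(snr_gt > th & snr_est > th), sum(snr_gt > th))
    mx <- pmax(snr_gt, snr_est); mn <- pmin(snr_gt, snr_est)
    prec_or <- frac(sum(mx > th & mn > 0), sum(mx > th & det))
    rec_or <- frac(sum(mx > th & mn > 0), sum(mx > th & ref))
    f1 <- function(p, r) {
      if (is.na(p) || is.na(r) || p + r == 0) NA_real_ else 2 * p * r / (p + r)
    }
    data.frame(threshold = th, precision = prec, recall = rec,
               f1 = f1(prec, rec), precision_and = prec_and,
               recall_and = rec_and, f1_and = f1(prec_and, rec_and),
               precision_or = prec_or, recall_or = rec_or,
               f1_or = f1(prec_or, rec_or))
  })
  do.call(rbind, rows)
}
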