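# Component quality assessment: residual traces, half-normal noise level,
# windowed peak-SNR, spatial footprint consistency, combined accept/reject
# logic, and duplicate detection.

#' Quality thresholds for component evaluation
#'
#' @param space_corr_min minimum spatial consistency correlation (theta_sp).
#' @param snr_min minimum trace peak-SNR (theta_SNR).
#' @param classifier_accept classifier score above which a component is
#'   accepted outright when \code{classifier_override} is on (theta_CNN).
#' @param classifier_reject_floor classifier score below which a component
#'   is rejected regardless of the other tests.
#' @param classifier_override when TRUE, a classifier score of at least
#'   \code{classifier_accept} rescues a component failing the SNR test only.
#' @param overlap_dup duplicate overlap threshold (theta_o).
#' @param n_peaks number of trace peaks averaged by the spatial test (Np).
#' @param peak_window (past, future) extent of each peak window in
#'   milliseconds; default 50 ms past, 300 ms future.
#' @param transient_seconds typical transient length in seconds defining the
#'   SNR window N_s = ceiling(transient_seconds * frame_rate).
#' @param spike_snr_test when TRUE, additionally require the deconvolved
#'   trace to carry at least one spike of size snr_min times the trace
#'   noise level (rejects components whose apparent activity is a slow
#'   drift rather than calcium transients). Off by default.
#' @return an object of class \code{quality_thresholds}.
#' @export
quality_thresholds <- function(space_corr_min = 0.5, snr_min = 2,
                               classifier_accept = 0.5,
                               classifier_reject_floor = 0.1,
                               classifier_override = FALSE,
                               overlap_dup = 0.7, n_peaks = 5L,
                               peak_window = c(50, 300),
                               transient_seconds = 0.4,
                               spike_snr_test = FALSE) {
  stopifnot(space_corr_min >= -1, space_corr_min <= 1,
            snr_min >= 0, overlap_dup > 0, overlap_dup <= 1,
            classifier_accept >= 0, classifier_accept <= 1)
  structure(list(space_corr_min = space_corr_min, snr_min = snr_min,
                 classifier_accept = classifier_accept,
                 classifier_reject_floor = classifier_reject_floor,
                 classifier_override = classifier_override,
                 overlap_dup = overlap_dup, n_peaks = as.integer(n_peaks),
                 peak_window = peak_window,
                 transient_seconds = transient_seconds,
                 spike_snr_test = spike_snr_test),
            class = "quality_thresholds")
}

#' Residual trace of one component
#'
#' Projects the model residual R = Y - A C - B onto the spatial footprint of
#' component \code{i}: r_i = R' a_i / ||a_i||^2. The sum c_i + r_i is the
#' non-denoised fluorescence trace of the component.
#'
#' @param mov a \code{movie}.
#' @param components list with \code{footprints} (d x N) and \code{traces}
#'   (N x T).
#' @param background a background model (see \code{\link{background_model}})
#'   or NULL.
#' @param i component index.
#' @return list with \code{residual} (length T) and \code{trace} (c_i).
#' @export
residual_trace <- function(mov, components, background = NULL, i) {
  A <- components$footprints; C <- components$traces
  stopifnot(i >= 1, i <= ncol(A))
  a <- A[, i]
  nrm2 <- sum(a^2)
  if (nrm2 == 0) stop("component ", i, " has an all-zero footprint")
  R <- mov$data - A %*% C
  R <- R - background_matrix(background, mov)
  r <- as.numeric(crossprod(R, a)) / nrm2
  list(residual = r, trace = C[i, ])
}

# Dense background matrix B for a movie (0 when background is NULL).
background_matrix <- function(background, mov) {
  if (is.null(background)) return(0)
  if (background$kind == "low_rank") {
    if (ncol(background$spatial) == 0L) return(0)
    return(background$spatial %*% background$temporal)
  }
  # ring model: B = W (Y - A C) was stored at fit time
  background$dense
}

#' Noise level of a trace via a half-normal fit to sub-baseline samples
#'
#' Calcium transients are positive, so samples at or below the baseline are
#' attributed to noise. Their deviations from the baseline follow a
#' half-normal distribution with scale sigma, estimated as
#' sd(deviations) / sqrt(1 - 2/pi).
#'
#' @param trace numeric vector.
#' @param baseline baseline vector or scalar; by default the trace median,
#'   a robust center whenever transients occupy a minority of frames (a
#'   kernel-density mode would be transient-robust too but its sampling
#'   noise is several percent even on long traces).
#' @param frame_rate frames per second (for a running baseline, if one is
#'   supplied).
#' @return noise standard deviation estimate.
#' @export
noise_level <- function(trace, baseline = NULL, frame_rate = 30) {
  if (is.null(baseline)) {
    baseline <- stats::median(trace)
  }
  dev <- trace - baseline
  sub <- dev[dev <= 0]
  if (length(sub) < 10L) {
    stop("noise_level: fewer than 10 sub-baseline samples; ",
         "trace too short or baseline degenerate")
  }
  stats::sd(sub) / sqrt(1 - 2 / pi)
}

#' Windowed peak signal-to-noise ratio of a trace
#'
#' Z-scores the trace against its baseline and noise level, converts each
#' sample to an upper-tail probability p(t) = Phi(-z(t)), finds the most
#' unlikely excursion as the minimum over t of the geometric mean of p over
#' a window of N_s = ceiling(transient_seconds * frame_rate) samples, and
#' returns SNR = -Phi^{-1}(p_min). All probability arithmetic is done in
#' the log domain. Windows truncated by the end of the trace are skipped.
#'
#' @param trace numeric vector (typically c_i + r_i).
#' @param frame_rate frames per second.
#' @param transient_seconds typical transient duration (default 0.4 s).
#' @param noise noise level; estimated by \code{\link{noise_level}} when
#'   NULL.
#' @param baseline baseline vector or scalar; estimated when NULL.
#' @return the peak-SNR value (non-negative for any real excursion).
#' @export
peak_snr <- function(trace, frame_rate = 30, transient_seconds = 0.4,
                     noise = NULL, baseline = NULL) {
  Tt <- length(trace)
  Ns <- max(1L, ceiling(transient_seconds * frame_rate))
  if (Ns > Tt) stop("peak_snr: window N_s = ", Ns, " exceeds trace length")
  if (is.null(baseline)) {
    baseline <- baseline_trace(trace, frame_rate = frame_rate)
  }
  if (is.null(noise)) {
    noise <- noise_level(trace, baseline = baseline, frame_rate = frame_rate)
  }
  if (noise <= 0) stop("peak_snr: non-positive noise level")
  z <- (trace - baseline) / noise
  logp <- stats::pnorm(-z, log.p = TRUE)
  # mean of logp over each full window of length Ns
  cs <- cumsum(c(0, logp))
  win_means <- (cs[(Ns + 1):(Tt + 1)] - cs[1:(Tt - Ns + 1)]) / Ns
  -stats::qnorm(min(win_means), log.p = TRUE)
}

# Top local maxima of a trace, ordered by height.
trace_peaks <- function(x, n_peaks = 5L, z = NULL, min_z = 0) {
  Tt <- length(x)
  if (Tt < 3L) return(integer(0))
  idx <- which(x[2:(Tt - 1)] > x[1:(Tt - 2)] & x[2:(Tt - 1)] >= x[3:Tt]) + 1L
  if (!is.null(z)) idx <- idx[z[idx] > min_z]
  if (length(idx) == 0L) return(integer(0))
  idx[order(x[idx], decreasing = TRUE)][seq_len(min(n_peaks, length(idx)))]
}

# Effective radius of a footprint from its second spatial moment.
footprint_radius <- function(a, rows, cols) {
  nz <- which(a > 0)
  if (length(nz) == 0L) return(1)
  rc <- pix_coords(nz, cols)
  w <- a[nz] / sum(a[nz])
  mu <- c(sum(rc[, 1] * w), sum(rc[, 2] * w))
  sqrt(sum(((rc[, 1] - mu[1])^2 + (rc[, 2] - mu[2])^2) * w)) + 1
}

footprint_centroid <- function(a, rows, cols) {
  nz <- which(a > 0)
  rc <- pix_coords(nz, cols)
  w <- a[nz] / sum(a[nz])
  c(sum(rc[, 1] * w), sum(rc[, 2] * w))
}

#' Spatial consistency of a footprint with the raw data
#'
#' Removes all other components and the background from the movie, averages
#' the remainder over windows around the strongest peaks of the component's
#' trace (default 50 ms before to 300 ms after each of the top Np peaks),
#' and correlates the resulting mean image with the footprint, both
#' restricted to a box around the footprint centroid of side four times the
#' footprint radius. Peaks during which a spatially overlapping component is
#' active (z-score above 2) are excluded.
#'
#' @inheritParams residual_trace
#' @param thresholds a \code{\link{quality_thresholds}}.
#' @return list with \code{correlation} and \code{reason} ("" or
#'   "no activity").
#' @export
spatial_consistency <- function(mov, components, background = NULL, i,
                                thresholds = quality_thresholds()) {
  A <- components$footprints; C <- components$traces
  rows <- mov$fov_dims[1]; cols <- mov$fov_dims[2]
  Tt <- ncol(C)
  a <- A[, i]; ci <- C[i, ]
  # z-scores of all traces, for the overlapping-activity exclusion
  others <- which(seq_len(ncol(A)) != i & as.numeric(crossprod(A, a) > 0))
  peaks <- trace_peaks(ci, thresholds$n_peaks)
  if (length(peaks) > 0L && length(others) > 0L) {
    zs <- matrix(0, length(others), Tt)
    for (k in seq_along(others)) {
      cj <- C[others[k], ]
      nj <- tryCatch(noise_level(cj, frame_rate = mov$frame_rate),
                     error = function(e) NA_real_)
      if (is.finite(nj) && nj > 0) {
        zs[k, ] <- (cj - baseline_trace(cj, frame_rate = mov$frame_rate)) / nj
      }
    }
    clean <- vapply(peaks, function(p) all(zs[, p] <= 2), logical(1))
    if (any(clean)) peaks <- peaks[clean]
  }
  if (length(peaks) == 0L) {
    return(list(correlation = 0, reason = "no activity"))
  }
  past <- round(thresholds$peak_window[1] / 1000 * mov$frame_rate)
  future <- round(thresholds$peak_window[2] / 1000 * mov$frame_rate)
  frames <- sort(unique(unlist(lapply(peaks, function(p) {
    max(1L, p - past):min(Tt, p + future)
  }))))
  Yi <- mov$data[, frames, drop = FALSE] -
    A[, -i, drop = FALSE] %*% C[-i, frames, drop = FALSE]
  Bm <- background_matrix(background, mov)
  if (!identical(Bm, 0)) Yi <- Yi - Bm[, frames, drop = FALSE]
  img <- rowMeans(Yi)
  # restrict to a box of side 4 * footprint radius around the centroid
  ctr <- footprint_centroid(a, rows, cols)
  half <- max(2L, ceiling(2 * footprint_radius(a, rows, cols)))
  rr <- max(1L, round(ctr[1]) - half):min(rows, round(ctr[1]) + half)
  cc <- max(1L, round(ctr[2]) - half):min(cols, round(ctr[2]) + half)
  box <- as.vector(t(outer((rr - 1L) * cols, cc, "+")))
  if (stats::sd(img[box]) == 0 || stats::sd(a[box]) == 0) {
    return(list(correlation = 0, reason = "degenerate"))
  }
  list(correlation = stats::cor(img[box], a[box]), reason = "")
}

#' Evaluate all components of a factorization
#'
#' Runs the three quality tests per component — spatial consistency, trace
#' peak-SNR, and footprint classification — and accepts a component when all
#' enabled tests pass. With \code{classifier_override} on, a classifier
#' score of at least \code{classifier_accept} rescues a component that
#' failed only the SNR test.
#'
#' @inheritParams spatial_consistency
#' @param classifier optional classifier model (see
#'   \code{\link{train_footprint_classifier}}); the deterministic geometric
#'   scorer is used when NULL.
#' @return a data.frame of class \code{quality_report} with columns
#'   \code{space_correlation}, \code{snr}, \code{classifier_score},
#'   \code{accepted}, \code{rejection_reasons}.
#' @export
evaluate_components <- function(mov, components, background = NULL,
                                thresholds = quality_thresholds(),
                                classifier = NULL) {
  A <- components$footprints; C <- components$traces
  N <- ncol(A)
  if (N == 0L) {
    rep <- data.frame(space_correlation = numeric(0), snr = numeric(0),
                      classifier_score = numeric(0), accepted = logical(0),
                      rejection_reasons = character(0))
    class(rep) <- c("quality_report", class(rep))
    return(rep)
  }
  rows <- mov$fov_dims[1]; cols <- mov$fov_dims[2]
  # shared residual for all components
  R <- mov$data - A %*% C
  Bm <- background_matrix(background, mov)
  if (!identical(Bm, 0)) R <- R - Bm
  sc <- snr <- score <- numeric(N)
  reasons <- character(N)
  crops <- lapply(seq_len(N), function(i) {
    footprint_crop(A[, i], rows, cols)
  })
  score <- classify_footprints(crops, model = classifier)
  for (i in seq_len(N)) {
    nrm2 <- sum(A[, i]^2)
    r_i <- if (nrm2 > 0) as.numeric(crossprod(R, A[, i])) / nrm2 else
      rep(0, ncol(C))
    tr <- C[i, ] + r_i
    snr[i] <- tryCatch(
      peak_snr(tr, frame_rate = mov$frame_rate,
               transient_seconds = thresholds$transient_seconds),
      error = function(e) 0)
    spc <- spatial_consistency(mov, components, background, i, thresholds)
    sc[i] <- spc$correlation
    why <- character(0)
    if (sc[i] < thresholds$space_corr_min) why <- c(why, "space_corr")
    if (snr[i] < thresholds$snr_min) why <- c(why, "snr")
    if (isTRUE(thresholds$spike_snr_test)) {
      sigma_i <- tryCatch(noise_level(tr, frame_rate = mov$frame_rate),
                          error = function(e) NA_real_)
      ok_spike <- FALSE
      if (is.finite(sigma_i) && sigma_i > 0) {
        dtr <- detrend(tr, frame_rate = mov$frame_rate)
        dc <- oasis_deconvolve(dtr, deconv_params(frame_rate = mov$frame_rate))
        ok_spike <- max(dc$spikes) >= thresholds$snr_min * sigma_i
      }
      if (!ok_spike) why <- c(why, "spike_snr")
    }
    if (score[i] < thresholds$classifier_reject_floor) {
      why <- c(why, "classifier")
    }
    if (thresholds$classifier_override &&
        identical(why, "snr") && score[i] >= thresholds$classifier_accept) {
      why <- character(0)
    }
    reasons[i] <- paste(why, collapse = ",")
  }
  rep <- data.frame(space_correlation = sc, snr = snr,
                    classifier_score = score,
                    accepted = reasons == "",
                    rejection_reasons = reasons,
                    stringsAsFactors = FALSE)
  class(rep) <- c("quality_report", class(rep))
  rep
}

#' Remove duplicate components by asymmetric mask overlap
#'
#' Computes the overlap matrix O_ij = |m(a_i) intersect m(a_j)| / |m(a_j)|
#' (i != j, O_ii = 0) on binarized footprints. While any entry exceeds
#' \code{overlap_dup}, the lower-scoring member of the most overlapping pair
#' is removed (ties keep the lower index).
#'
#' @param components list with \code{footprints}.
#' @param scores per-component quality scores (classifier or SNR).
#' @param overlap_dup overlap threshold theta_o.
#' @param binarize_threshold mask threshold theta_b.
#' @return integer vector of kept component indices.
#' @export
detect_duplicates <- function(components, scores, overlap_dup = 0.7,
                              binarize_threshold = 0.2) {
  A <- components$footprints
  N <- ncol(A)
  if (N <= 1L) return(seq_len(N))
  masks <- A >= matrix(binarize_threshold * apply(A, 2, max), nrow(A), N,
                       byrow = TRUE)
  keep <- seq_len(N)
  repeat {
    M <- masks[, keep, drop = FALSE] * 1
    inter <- crossprod(M)                     # |m_i cap m_j|
    sizes <- diag(inter)
    O <- inter / matrix(pmax(sizes, 1), length(keep), length(keep),
                        byrow = TRUE)
    diag(O) <- 0
    if (all(O <= overlap_dup)) break
    worst <- which(O == max(O), arr.ind = TRUE)[1, ]
    i <- worst[1]; j <- worst[2]
    drop_local <- if (scores[keep[i]] < scores[keep[j]]) i
      else if (scores[keep[j]] < scores[keep[i]]) j
      else max(i, j)                           # tie: keep the lower index
    keep <- keep[-drop_local]
    if (length(keep) <= 1L) break
  }
  keep
}
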