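# Baseline extraction for fluorescence traces.
#
# One baseline definition is used package-wide: a (running) percentile of
# the trace. The percentile level can be fixed or chosen automatically as
# the quantile whose value matches the mode of a kernel density estimate of
# the trace — calcium transients are positive excursions, so the density
# mode sits at the resting fluorescence.

#' Automatic percentile level for baseline extraction
#'
#' Estimates the mode of the trace's value distribution with a Gaussian
#' kernel density estimate (Silverman bandwidth, at most 10^4 subsampled
#' points) and returns the empirical quantile level of that mode, clamped
#' to [0.5, 50] percent.
#'
#' @param trace numeric vector.
#' @return percentile level in (0, 50].
#' @export
auto_percentile <- function(trace) {
  x <- trace[is.finite(trace)]
  if (length(x) > 1e4) x <- x[seq(1L, length(x), length.out = 1e4)]
  if (stats::sd(x) == 0) return(50)
  dens <- stats::density(x, bw = "nrd0", n = 512)
  mode_val <- dens$x[which.max(dens$y)]
  lev <- 100 * mean(x <= mode_val)
  min(max(lev, 0.5), 50)
}

#' Running-percentile baseline of a trace
#'
#' Computes the given percentile over non-overlapping blocks of
#' \code{window_seconds} (stride equal to the window), anchored at block
#' centers and linearly interpolated between them. Traces shorter than one
#' window get a constant global-percentile baseline.
#'
#' @param trace numeric vector of length T.
#' @param frame_rate frames per second (used to convert the window to
#'   frames).
#' @param window_seconds window length in seconds (default 100 s).
#' @param percentile percentile level in (0, 50], or \code{NULL} for the
#'   automatic density-mode level (\code{\link{auto_percentile}}).
#' @return numeric vector of length T.
#' @export
baseline_trace <- function(trace, frame_rate = 30, window_seconds = 100,
                           percentile = NULL) {
  Tt <- length(trace)
  if (is.null(percentile)) percentile <- auto_percentile(trace)
  stopifnot(percentile > 0, percentile <= 50)
  w <- max(2L, round(window_seconds * frame_rate))
  if (w >= Tt) {
    return(rep(stats::quantile(trace, percentile / 100, names = FALSE), Tt))
  }
  starts <- seq(1L, Tt, by = w)
  centers <- pmin(starts + (w - 1) / 2, Tt)
  vals <- vapply(starts, function(s) {
    stats::quantile(trace[s:min(Tt, s + w - 1L)], percentile / 100,
                    names = FALSE)
  }, numeric(1))
  stats::approx(centers, vals, xout = seq_len(Tt), rule = 2)$y
}
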