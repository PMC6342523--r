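# Sparse non-negative deconvolution of calcium traces under AR(1) dynamics:
#   minimize  1/2 ||y - c||^2 + lambda * sum(s)
#   subject to s(t) = c(t) - gamma c(t-1) >= 0  (>= s_min after screening)
# solved exactly by pool-adjacent-violators, plus trace detrending and
# moment-based estimation of the AR coefficient and noise level.

#' Deconvolution parameters
#'
#' @param ar_coeff AR(1) coefficient gamma in [0, 1); estimated from the
#'   trace when NULL.
#' @param sparsity_penalty L1 penalty lambda on the spikes (default 0).
#' @param min_spike spikes below this size are zeroed after the exact
#'   solve (default 0).
#' @param noise_estimate optional per-trace noise level (informational).
#' @param frame_rate frames per second, used when gamma must be estimated.
#' @return an object of class \code{deconv_params}.
#' @export
deconv_params <- function(ar_coeff = NULL, sparsity_penalty = 0,
                          min_spike = 0, noise_estimate = NULL,
                          frame_rate = 30) {
  if (!is.null(ar_coeff)) {
    if (ar_coeff < 0 || ar_coeff >= 1) stop("ar_coeff must be in [0, 1)")
  }
  stopifnot(sparsity_penalty >= 0, min_spike >= 0)
  structure(list(ar_coeff = ar_coeff, sparsity_penalty = sparsity_penalty,
                 min_spike = min_spike, noise_estimate = noise_estimate,
                 frame_rate = frame_rate),
            class = "deconv_params")
}

#' Remove slow trends from a trace
#'
#' Subtracts the running-percentile baseline
#' (\code{\link{baseline_trace}}), removing slow non-stationarities such as
#' photobleaching while leaving transients intact. Constant traces map to
#' zero.
#'
#' @param trace numeric vector (length >= 2).
#' @param frame_rate frames per second.
#' @param window_seconds running window (default 100 s).
#' @param percentile percentile level, or NULL for automatic.
#' @return detrended trace.
#' @export
detrend <- function(trace, frame_rate = 30, window_seconds = 100,
                    percentile = NULL) {
  stopifnot(length(trace) >= 2L)
  trace - baseline_trace(trace, frame_rate, window_seconds, percentile)
}

#' Estimate AR(1) coefficient and noise level of a trace
#'
#' The noise level is taken from the high-frequency half of the power
#' spectral density (mean power over [0.25, 0.5] of the sampling rate,
#' where AR(1) signal power is smallest), and the AR coefficient from the
#' lag-1 / lag-2 autocovariance ratio of the noise-corrected process,
#' clipped to [0, 0.998].
#'
#' @param trace numeric vector (length >= 100).
#' @param frame_rate frames per second (unused by the estimators, kept for
#'   interface symmetry).
#' @return list with \code{ar_coeff} and \code{noise}.
#' @export
estimate_ar_noise <- function(trace, frame_rate = 30) {
  Tt <- length(trace)
  stopifnot(Tt >= 100L)
  x <- trace - mean(trace)
  if (stats::sd(x) == 0) return(list(ar_coeff = 0, noise = 0))
  # periodogram; noise variance = mean power in the upper frequency half
  sp <- stats::spec.pgram(x, taper = 0, plot = FALSE, detrend = FALSE,
                          fast = TRUE)
  hi <- sp$freq >= 0.25 & sp$freq <= 0.5
  sigma2 <- mean(sp$spec[hi])
  sigma <- sqrt(max(sigma2, 0))
  # autocovariance ratio: for y = c + noise with AR(1) c,
  # acov(2)/acov(1) = gamma (noise only affects lag 0)
  ac <- stats::acf(x, lag.max = 2L, type = "covariance", plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  # require lag-1 autocovariance significantly above the white-noise level
  thr <- 1.96 * ac[1] / sqrt(Tt)
  gamma <- if (ac[2] > thr && ac[3] > 0) ac[3] / ac[2] else 0
  gamma <- min(max(gamma, 0), 0.998)
  list(ar_coeff = gamma, noise = sigma)
}

#' Sparse non-negative AR(1) deconvolution (pool adjacent violators)
#'
#' Exactly minimizes 1/2 ||y - c||^2 + lambda sum(s) subject to
#' c(t) >= gamma c(t-1) and c >= 0, with s(t) = c(t) - gamma c(t-1)
#' (s(1) = c(1)). Pools are merged strictly left to right, which makes the
#' solution deterministic. Spikes smaller than \code{min_spike} are zeroed
#' afterwards (the corresponding trace is re-propagated through the AR
#' dynamics).
#'
#' @param trace numeric vector y.
#' @param params a \code{\link{deconv_params}}; gamma is estimated when
#'   absent.
#' @return list with \code{denoised} (c), \code{spikes} (s) and
#'   \code{ar_coeff}.
#' @export
oasis_deconvolve <- function(trace, params = deconv_params()) {
  Tt <- length(trace)
  gamma <- params$ar_coeff
  if (is.null(gamma)) {
    gamma <- if (Tt >= 100L) estimate_ar_noise(trace)$ar_coeff else 0.9
  }
  if (gamma < 0 || gamma >= 1) stop("ar_coeff must be in [0, 1)")
  lambda <- params$sparsity_penalty
  # the L1 term in c-coordinates: sum(s) = sum_t c_t (1 - gamma) + gamma c_T
  # so lambda shifts each observation; last frame gets the full weight
  y <- trace - lambda * (1 - gamma)
  if (Tt >= 1L) y[Tt] <- trace[Tt] - lambda
  # pools: value v = num/den, num = sum gamma^k y, den = sum gamma^(2k),
  # start t, length l; fitted c within a pool is v * gamma^(t - t_start)
  num <- y
  den <- rep(1, Tt)
  start <- seq_len(Tt)
  len <- rep(1L, Tt)
  np <- 0L          # pools kept so far
  i <- 1L
  while (i <= Tt) {
    np <- np + 1L
    num[np] <- num[i]; den[np] <- den[i]; start[np] <- start[i]; len[np] <- len[i]
    i <- i + 1L
    # merge backwards while the new pool violates the AR constraint
    while (np > 1L) {
      g_l <- gamma^len[np - 1L]
      v_prev <- num[np - 1L] / den[np - 1L]
      v_cur <- num[np] / den[np]
      if (v_cur >= g_l * v_prev) break
      num[np - 1L] <- num[np - 1L] + g_l * num[np]
      den[np - 1L] <- den[np - 1L] + g_l^2 * den[np]
      len[np - 1L] <- len[np - 1L] + len[np]
      np <- np - 1L
    }
  }
  c_hat <- numeric(Tt)
  for (p in seq_len(np)) {
    v <- max(num[p] / den[p], 0)
    k <- seq_len(len[p]) - 1L
    c_hat[start[p] + k] <- v * gamma^k
  }
  s_hat <- c(c_hat[1], c_hat[-1] - gamma * c_hat[-Tt])
  s_hat[s_hat < 0] <- 0            # numerical dust at pool boundaries
  if (params$min_spike > 0) {
    s_hat[s_hat < params$min_spike] <- 0
    c_hat <- stats::filter(s_hat, gamma, method = "recursive")
    c_hat <- as.numeric(c_hat)
  }
  list(denoised = c_hat, spikes = s_hat, ar_coeff = gamma)
}

#' KKT residual of an AR(1) deconvolution solution
#'
#' For the problem min 1/2||y - c||^2 + lambda 1's, s = G c >= 0 (G the
#' AR(1) difference operator), the stationarity condition determines the
#' multipliers mu = G^{-T}(c - y + lambda G' 1). The returned residual is
#' the larger of the dual-feasibility violation max(-mu, 0) and the
#' complementary-slackness violation max |mu * s|, scaled by the trace
#' norm.
#'
#' @param trace the observed y.
#' @param denoised the fitted c.
#' @param spikes the fitted s.
#' @param gamma AR coefficient used in the fit.
#' @param lambda sparsity penalty used in the fit.
#' @return maximum KKT violation (0 at the exact optimum).
#' @export
oasis_kkt_residual <- function(trace, denoised, spikes, gamma, lambda = 0) {
  Tt <- length(trace)
  # grad = c - y + lambda G' 1 - G' mu = 0  =>  G' mu = c - y + lambda G' 1
  # G' 1 = (1 - gamma, ..., 1 - gamma, 1)'
  g1 <- c(rep(1 - gamma, Tt - 1L), 1)
  rhs <- denoised - trace + lambda * g1
  # G' is upper bidiagonal with unit diagonal and -gamma superdiagonal:
  # (G' mu)_t = mu_t - gamma mu_{t+1}; back-substitute from the end
  mu <- numeric(Tt)
  mu[Tt] <- rhs[Tt]
  for (t in (Tt - 1L):1L) mu[t] <- rhs[t] + gamma * mu[t + 1L]
  scale <- max(1, sqrt(sum(trace^2)))
  max(max(-mu, 0), max(abs(mu * spikes))) / scale
}
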