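# Synthetic calcium-imaging movies realizing the CNMF generative model
#   Y = A C + b f + E
# with rank-one Gaussian somata, AR(1) calcium dynamics driven by Bernoulli
# spiking, a low-rank smooth neuropil background, and i.i.d. Gaussian noise.

#' Parameters for the synthetic movie generator
#'
#' Defines the generative conditions for a simulated two-photon style
#' recording: \code{n_neurons} somata with isotropic Gaussian footprints of
#' scale \code{gaussian_radius} pixels (truncated at three radii and
#' normalized to unit Euclidean norm), temporal traces following first-order
#' autoregressive dynamics \code{c(t) = ar_coeff * c(t-1) + s(t)} with
#' Bernoulli spikes of height \code{transient_amplitude} at
#' \code{spike_rate} Hz, a rank-\code{background_rank} smooth non-negative
#' background, and additive i.i.d. Gaussian noise of standard deviation
#' \code{noise_sigma}.
#'
#' Defaults describe a 64 x 64 pixel field of view imaged at 30 Hz for 1000
#' frames with 20 neurons whose transient amplitude is ten times the noise
#' level of the projected trace (unit-norm footprints make the two scales
#' directly comparable).
#'
#' @param fov_dims integer(2); (rows, cols) of the field of view.
#' @param n_frames number of frames T.
#' @param frame_rate imaging rate in Hz.
#' @param n_neurons number of components N.
#' @param gaussian_radius Gaussian scale (sigma) of each footprint, pixels.
#' @param spike_rate expected spikes per second per neuron.
#' @param ar_coeff AR(1) decay per frame, in [0, 1).
#' @param transient_amplitude spike height in trace fluorescence units.
#' @param background_rank number of background components n_b.
#' @param background_amplitude scale of the background temporal modes.
#' @param noise_sigma standard deviation of the additive Gaussian noise.
#' @param bleach_tau optional photobleaching time constant in seconds; when
#'   finite, all non-noise signal is multiplied by exp(-t / bleach_tau)
#'   (used for detrending tests). Default \code{Inf} (no bleaching).
#' @param min_separation minimum center-to-center distance between neurons in
#'   pixels; default twice \code{gaussian_radius}.
#' @param seed integer seed; identical seeds give bit-identical movies.
#' @return an object of class \code{synth_params} (a named list).
#' @export
synth_params <- function(fov_dims = c(64L, 64L), n_frames = 1000L,
                         frame_rate = 30, n_neurons = 20L,
                         gaussian_radius = 3, spike_rate = 0.5,
                         ar_coeff = 0.95, transient_amplitude = 1,
                         background_rank = 2L, background_amplitude = 1,
                         noise_sigma = 0.1, bleach_tau = Inf,
                         min_separation = NULL, seed = 1L) {
  stopifnot(length(fov_dims) == 2L, all(fov_dims >= 1L),
            n_frames >= 1L, frame_rate > 0,
            n_neurons >= 0L, gaussian_radius >= 1,
            ar_coeff >= 0, ar_coeff < 1,
            noise_sigma >= 0, background_rank >= 0L)
  if (is.null(min_separation)) min_separation <- 2 * gaussian_radius
  structure(list(
    fov_dims = as.integer(fov_dims), n_frames = as.integer(n_frames),
    frame_rate = frame_rate, n_neurons = as.integer(n_neurons),
    gaussian_radius = gaussian_radius, spike_rate = spike_rate,
    ar_coeff = ar_coeff, transient_amplitude = transient_amplitude,
    background_rank = as.integer(background_rank),
    background_amplitude = background_amplitude,
    noise_sigma = noise_sigma, bleach_tau = bleach_tau,
    min_separation = min_separation, seed = as.integer(seed)
  ), class = "synth_params")
}

# Place n centers with a minimum pairwise separation by rejection sampling.
# A retry cap turns an overfull FOV into a deterministic error rather than
# silent clumping.
place_centers <- function(rows, cols, n, radius, min_sep, retry_cap = 1000L) {
  if (n == 0L) return(matrix(numeric(0), 0L, 2L))
  margin <- min(radius, (min(rows, cols) - 1) / 2)
  centers <- matrix(NA_real_, n, 2L)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    cand <- c(stats::runif(1, 1 + margin, rows - margin),
              stats::runif(1, 1 + margin, cols - margin))
    ok <- placed == 0L ||
      all(sqrt((centers[seq_len(placed), 1] - cand[1])^2 +
               (centers[seq_len(placed), 2] - cand[2])^2) >= min_sep)
    if (ok) {
      placed <- placed + 1L
      centers[placed, ] <- cand
      tries <- 0L
    } else {
      tries <- tries + 1L
      if (tries > retry_cap) {
        stop("FOV too small to place ", n, " neurons at minimum separation ",
             min_sep, " pixels (placed ", placed, ")")
      }
    }
  }
  centers
}

# Unit-norm truncated Gaussian footprint as a length-d vector (row-major FOV).
gaussian_footprint <- function(center, rows, cols, radius) {
  rr <- matrix(seq_len(rows), rows, cols)
  cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  d2 <- (rr - center[1])^2 + (cc - center[2])^2
  a <- exp(-d2 / (2 * radius^2))
  a[d2 > (3 * radius)^2] <- 0
  a <- as.vector(t(a))          # row-major flattening
  a / sqrt(sum(a^2))
}

#' Generate a synthetic movie with ground truth
#'
#' Draws a movie \code{Y = A C + b f + E} from the generative model described
#' in \code{\link{synth_params}}, returning both the movie and the exact
#' decomposition used to build it.
#'
#' @param params a \code{\link{synth_params}} object.
#' @return a list with elements \code{movie} (a \code{\link{movie}} object)
#'   and \code{truth}, where \code{truth} contains \code{footprints} (d x N,
#'   unit-norm columns), \code{traces} (N x T), \code{spikes} (N x T),
#'   \code{background_spatial} (d x n_b), \code{background_temporal}
#'   (n_b x T), \code{centers} (N x 2), \code{noise_sigma} and \code{seed}.
#' @export
generate_movie <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  rows <- p$fov_dims[1]; cols <- p$fov_dims[2]
  d <- rows * cols; Tt <- p$n_frames; N <- p$n_neurons
  with_seed(p$seed, {
    centers <- place_centers(rows, cols, N, p$gaussian_radius, p$min_separation)
    A <- matrix(0, d, N)
    for (i in seq_len(N)) {
      A[, i] <- gaussian_footprint(centers[i, ], rows, cols, p$gaussian_radius)
    }
    # Bernoulli spikes and AR(1) traces
    pr <- min(1, p$spike_rate / p$frame_rate)
    S <- matrix(stats::rbinom(N * Tt, 1L, pr) * p$transient_amplitude, N, Tt)
    C <- matrix(0, N, Tt)
    if (N > 0L) {
      C[, 1] <- S[, 1]
      for (t in seq_len(Tt - 1L) + 1L) C[, t] <- p$ar_coeff * C[, t - 1L] + S[, t]
    }
    # smooth low-rank background: blurred noise surfaces, slow rectified walks
    # neuropil: smooth spatial surfaces of mean pixel weight one, times
    # slow non-negative random walks; with the default amplitude each pixel
    # carries a DC offset of about 0.5 fluorescence units per mode pair and
    # slow fluctuations on the order of the noise level
    nb <- p$background_rank
    b <- matrix(0, d, nb); f <- matrix(0, nb, Tt)
    for (j in seq_len(nb)) {
      surf <- gauss_blur(matrix(stats::runif(d), rows, cols),
                         sigma = max(rows, cols) / 8)
      surf <- surf - min(surf)
      bj <- as.vector(t(surf))
      b[, j] <- bj / mean(bj)
      walk <- cumsum(stats::rnorm(Tt, sd = 0.2 / sqrt(Tt)))
      f[j, ] <- p$background_amplitude * pmax(0.5 + walk - walk[1], 0) /
        max(nb, 1L)
    }
    signal <- b %*% f
    if (N > 0L) signal <- signal + A %*% C
    if (is.finite(p$bleach_tau)) {
      decay <- exp(-(seq_len(Tt) - 1L) / (p$bleach_tau * p$frame_rate))
      signal <- sweep(signal, 2L, decay, "*")
    }
    E <- if (p$noise_sigma > 0) {
      matrix(stats::rnorm(d * Tt, sd = p$noise_sigma), d, Tt)
    } else 0
    Y <- signal + E
    mov <- movie(Y, fov_dims = c(rows, cols), frame_rate = p$frame_rate)
    truth <- list(footprints = A, traces = C, spikes = S,
                  background_spatial = b, background_temporal = f,
                  centers = centers, noise_sigma = p$noise_sigma,
                  seed = p$seed)
    list(movie = mov, truth = truth)
  })
}

#' Generate multi-session footprint sets with known correspondence
#'
#' Builds a master pool of components, then draws per-session subsets with a
#' controlled expected overlap between consecutive sessions and applies a
#' per-session rigid integer shift. Used as a fixture for multi-session
#' component registration.
#'
#' @param params a \code{\link{synth_params}} object (defines FOV, radius,
#'   pool size \code{n_neurons} and seed).
#' @param n_sessions number of sessions (>= 2).
#' @param overlap_fraction probability in [0, 1] that a master component is
#'   present in any given session (1 = present everywhere, 0 = each master
#'   component appears in at most one session).
#' @param shift_pixels integer matrix n_sessions x 2 of per-session (dy, dx)
#'   rigid shifts; default all zero.
#' @return a list with \code{sessions} (each with \code{footprints} d x N_i
#'   and \code{template} image), and \code{correspondence}, an
#'   n_master x n_sessions integer matrix giving each master component's
#'   index within each session (NA when absent).
#' @export
generate_sessions <- function(params, n_sessions, overlap_fraction = 0.5,
                              shift_pixels = NULL) {
  stopifnot(inherits(params, "synth_params"), n_sessions >= 2L,
            overlap_fraction >= 0, overlap_fraction <= 1)
  p <- params
  rows <- p$fov_dims[1]; cols <- p$fov_dims[2]
  if (is.null(shift_pixels)) {
    shift_pixels <- matrix(0L, n_sessions, 2L)
  }
  shift_pixels <- matrix(as.integer(shift_pixels), n_sessions, 2L)
  if (any(abs(shift_pixels[, 1]) >= rows) || any(abs(shift_pixels[, 2]) >= cols)) {
    stop("session shift larger than the FOV")
  }
  with_seed(p$seed + 104729L, {
    N <- p$n_neurons
    centers <- place_centers(rows, cols, N, p$gaussian_radius,
                             p$min_separation)
    # presence: overlap_fraction 1 -> all sessions share everything;
    # 0 -> each master component is assigned to exactly one session.
    presence <- matrix(FALSE, N, n_sessions)
    if (overlap_fraction == 0) {
      assign_to <- sample.int(n_sessions, N, replace = TRUE)
      presence[cbind(seq_len(N), assign_to)] <- TRUE
    } else {
      presence[] <- stats::runif(N * n_sessions) < overlap_fraction
      # every master component must exist somewhere
      missing <- rowSums(presence) == 0L
      presence[cbind(which(missing),
                     sample.int(n_sessions, sum(missing), replace = TRUE))] <- TRUE
    }
    sessions <- vector("list", n_sessions)
    correspondence <- matrix(NA_integer_, N, n_sessions)
    for (s in seq_len(n_sessions)) {
      idx <- which(presence[, s])
      Afull <- matrix(0, rows * cols, length(idx))
      ok <- logical(length(idx))
      for (k in seq_along(idx)) {
        ctr <- centers[idx[k], ] + shift_pixels[s, ]
        if (ctr[1] < 1 || ctr[1] > rows || ctr[2] < 1 || ctr[2] > cols) next
        Afull[, k] <- gaussian_footprint(ctr, rows, cols, p$gaussian_radius)
        ok[k] <- TRUE
      }
      Afull <- Afull[, ok, drop = FALSE]
      idx <- idx[ok]
      correspondence[idx, s] <- seq_along(idx)
      template <- matrix(rowSums(matrix(Afull, rows * cols)), rows, cols,
                         byrow = TRUE)
      sessions[[s]] <- list(footprints = Afull, template = template,
                            shift = shift_pixels[s, ])
    }
    list(sessions = sessions, correspondence = correspondence,
         centers = centers)
  })
}
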