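# Summary images (correlation image, max-correlation image, peak-to-noise
# image) and initialization strategies for the bi-convex CNMF problem:
# GreedyROI, RollingGreedyROI, GreedyCorr and seeded initialization.

#' Initialization parameters
#'
#' @param method one of "greedy_roi", "rolling_greedy_roi", "greedy_corr",
#'   "seeded".
#' @param n_components number of components K for the greedy methods.
#' @param gaussian_width smoothing kernel width in pixels (match the neuron
#'   radius).
#' @param rolling_window rolling-window length in seconds for
#'   RollingGreedyROI (default 3 s; stride is half the window).
#' @param min_corr,min_pnr acceptance thresholds for GreedyCorr.
#' @param background_rank number of background components n_b.
#' @return an object of class \code{init_params}.
#' @export
init_params <- function(method = c("greedy_roi", "rolling_greedy_roi",
                                   "greedy_corr", "seeded"),
                        n_components = 10L, gaussian_width = 3,
                        rolling_window = 3, min_corr = 0.8, min_pnr = 5,
                        background_rank = 2L) {
  method <- match.arg(method)
  stopifnot(n_components >= 0L, min_corr >= 0, min_corr <= 1 || min_corr > 1,
            background_rank >= 0L)
  structure(list(method = method, n_components = as.integer(n_components),
                 gaussian_width = gaussian_width,
                 rolling_window = rolling_window,
                 min_corr = min_corr, min_pnr = min_pnr,
                 background_rank = as.integer(background_rank)),
            class = "init_params")
}

neighbor_shifts <- function(neighborhood) {
  if (neighborhood == 4L) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else if (neighborhood == 8L) {
    s <- expand.grid(dr = -1:1, dc = -1:1)
    s <- s[!(s$dr == 0 & s$dc == 0), ]
    lapply(seq_len(nrow(s)), function(i) c(s$dr[i], s$dc[i]))
  } else stop("neighborhood must be 4 or 8")
}

#' Correlation image of a movie
#'
#' Each pixel holds the mean Pearson correlation between its time series and
#' those of its 4- or 8-neighbors; border pixels average over their existing
#' neighbors only. Zero-variance pixels contribute (and receive)
#' correlation 0.
#'
#' @param mov a \code{movie} (or d x T matrix with \code{fov_dims}).
#' @param neighborhood 4 or 8 (default 8).
#' @param frames optional frame subset.
#' @return image matrix rows x cols with values in [-1, 1].
#' @export
correlation_image <- function(mov, neighborhood = 8L, frames = NULL) {
  rows <- mov$fov_dims[1]; cols <- mov$fov_dims[2]
  Y <- if (is.null(frames)) mov$data else mov$data[, frames, drop = FALSE]
  Tt <- ncol(Y)
  stopifnot(Tt >= 2L)
  mu <- rowMeans(Y)
  Z <- Y - mu
  sdv <- sqrt(rowSums(Z^2))
  zero_var <- sdv == 0
  sdv[zero_var] <- 1
  Z <- Z / sdv                       # unit-norm centered rows
  Z[zero_var, ] <- 0                 # zero-variance pixels correlate 0
  if (rows * cols == 1L) return(matrix(0, 1L, 1L))
  acc <- numeric(rows * cols)
  cnt <- numeric(rows * cols)
  # arrange pixel indices on the grid (row-major flattening)
  idx_grid <- matrix(seq_len(rows * cols), rows, cols, byrow = TRUE)
  for (sh in neighbor_shifts(as.integer(neighborhood))) {
    r_src <- seq_len(rows) + sh[1]
    c_src <- seq_len(cols) + sh[2]
    ok_r <- r_src >= 1L & r_src <= rows
    ok_c <- c_src >= 1L & c_src <= cols
    tgt <- idx_grid[which(ok_r), which(ok_c)]
    src <- idx_grid[r_src[ok_r], c_src[ok_c]]
    acc[tgt] <- acc[tgt] + rowSums(Z[tgt, , drop = FALSE] *
                                     Z[src, , drop = FALSE])
    cnt[tgt] <- cnt[tgt] + 1
  }
  matrix(acc / pmax(cnt, 1), rows, cols, byrow = TRUE)
}

#' Max-correlation image over temporal batches
#'
#' Computes the correlation image per consecutive batch of
#' \code{batch_seconds} and takes the pointwise maximum. Neurons active only
#' briefly stand out relative to the full-movie correlation image.
#'
#' @inheritParams correlation_image
#' @param batch_seconds batch length in seconds (default 33 s).
#' @return image matrix rows x cols.
#' @export
max_correlation_image <- function(mov, batch_seconds = 33, neighborhood = 8L) {
  Tt <- ncol(mov$data)
  bl <- max(2L, round(batch_seconds * mov$frame_rate))
  starts <- seq(1L, Tt, by = bl)
  out <- NULL
  for (s in starts) {
    e <- min(Tt, s + bl - 1L)
    if (e - s + 1L < 2L) next
    ci <- correlation_image(mov, neighborhood, frames = s:e)
    out <- if (is.null(out)) ci else pmax(out, ci)
  }
  out
}

#' Peak-to-noise image
#'
#' Per pixel: (maximum of the temporally smoothed, median-subtracted trace)
#' divided by the pixel's noise level. Noise is taken from the mean power
#' in the upper frequency half of the periodogram, where transient signal
#' power is negligible, so active pixels do not inflate their own noise
#' estimate.
#'
#' @inheritParams correlation_image
#' @param smooth_frames width of the temporal box smoother (default 3).
#' @return image matrix rows x cols.
#' @export
pnr_image <- function(mov, smooth_frames = 3L) {
  rows <- mov$fov_dims[1]; cols <- mov$fov_dims[2]
  Y <- mov$data
  Tt <- ncol(Y)
  med <- apply(Y, 1L, stats::median)
  Yc <- Y - med
  # per-pixel high-frequency noise floor from one batched FFT
  Z <- stats::mvfft(t(Yc))
  pgram <- Mod(Z)^2 / Tt
  freqs <- (seq_len(Tt) - 1L) / Tt
  hi <- freqs >= 0.25 & freqs <= 0.5
  nz <- sqrt(colMeans(pgram[hi, , drop = FALSE]))
  if (smooth_frames > 1L) {
    k <- rep(1 / smooth_frames, smooth_frames)
    Yc <- t(apply(Yc, 1L, function(x) {
      v <- stats::filter(x, k, sides = 2)
      v[is.na(v)] <- 0
      as.numeric(v)
    }))
  }
  pk <- apply(Yc, 1L, max)
  matrix(pk / pmax(nz, .Machine$double.eps), rows, cols, byrow = TRUE)
}

# Rank-1 fit seeded from a peak, in a local window of the (residual)
# movie. The footprint is regressed on the mean-centered trace so constant
# background within the window does not leak into the shape. Returns the
# unit-norm local footprint, its pixel indices, and the trace.
local_rank1 <- function(Y, pix, iterations = 10L, center_trace = NULL) {
  Yl <- Y[pix, , drop = FALSE]
  c0 <- if (is.null(center_trace)) {
    as.numeric(crossprod(Yl, pmax(rowMeans(Yl), 0)))
  } else center_trace
  a <- rep(0, length(pix))
  c_old <- NULL
  for (it in seq_len(iterations)) {
    cc <- c0 - mean(c0)
    den_c <- sum(cc^2)
    if (den_c <= 0) break
    a <- pmax(as.numeric(Yl %*% cc) / den_c, 0)
    den_a <- sum(a^2)
    if (den_a <= 0) break
    c0 <- as.numeric(crossprod(Yl, a)) / den_a
    if (!is.null(c_old)) {
      rel <- sqrt(sum((c0 - c_old)^2)) / max(sqrt(sum(c_old^2)), 1e-12)
      if (rel < 1e-4) break
    }
    c_old <- c0
  }
  nrm <- sqrt(sum(a^2))
  if (nrm > 0) a <- a / nrm
  cc <- pmax(as.numeric(crossprod(Yl, a)), 0)
  list(a = as.numeric(a), pix = pix, c = cc)
}

square_window <- function(center_rc, half, rows, cols) {
  rr <- max(1L, center_rc[1] - half):min(rows, center_rc[1] + half)
  cc <- max(1L, center_rc[2] - half):min(cols, center_rc[2] + half)
  as.vector(t(outer((rr - 1L) * cols, cc, "+")))   # row-major order
}

#' Greedy ROI initialization
#'
#' Seeds K components at successive maxima of the variance of the spatially
#' Gaussian-smoothed movie (optionally over a rolling temporal window for
#' the rolling variant). Each seed is refined by a local rank-1 NMF in a
#' square of side 4 * gaussian_width + 1 around the peak, and the explained
#' activity is subtracted before the next seed is picked.
#'
#' @param mov a \code{movie}.
#' @param params an \code{\link{init_params}} (method "greedy_roi" or
#'   "rolling_greedy_roi").
#' @return list with \code{footprints} (d x K) and \code{traces} (K x T).
#' @export
greedy_roi <- function(mov, params = init_params()) {
  rows <- mov$fov_dims[1]; cols <- mov$fov_dims[2]
  d <- rows * cols; Tt <- ncol(mov$data)
  K <- params$n_components
  if (K > d) stop("requested more components than pixels")
  A <- matrix(0, d, K); C <- matrix(0, K, Tt)
  if (K == 0L) return(list(footprints = A, traces = C))
  S <- smoothing_operator(rows, cols, min(params$gaussian_width, 2))
  # the diffuse neuropil background dominates raw variance; it is close to
  # low-rank, so project out the movie's top temporal singular subspace
  # (background rank + 1 modes, the extra one for the DC offset) before
  # variance-based seeding
  if (params$background_rank > 0L) {
    r_bg <- params$background_rank + 1L
    ev <- eigen(crossprod(mov$data), symmetric = TRUE)
    V <- ev$vectors[, seq_len(min(r_bg, ncol(ev$vectors))), drop = FALSE]
    R <- mov$data - (mov$data %*% V) %*% t(V)
  } else {
    R <- mov$data - rowMeans(mov$data)
  }
  Rs <- as.matrix(S %*% R)                 # smoothed residual
  rolling <- params$method == "rolling_greedy_roi"
  if (rolling) {
    wlen <- max(2L, round(params$rolling_window * mov$frame_rate))
    stride <- max(1L, wlen %/% 2L)
    starts <- unique(c(seq(1L, max(1L, Tt - wlen + 1L), by = stride)))
  }
  half <- ceiling(2 * params$gaussian_width)      # window side 4w + 1
  blocked <- rep(FALSE, d)   # seeded sites are excluded from later picks
  seed_var <- numeric(0)     # smoothed variance at each selected seed
  for (k in seq_len(K)) {
    if (rolling) {
      # variance per pixel over the best rolling window
      v <- -Inf
      best <- NULL
      for (s in starts) {
        e <- min(Tt, s + wlen - 1L)
        vr <- rowSums(Rs[, s:e, drop = FALSE]^2) / (e - s + 1L) -
          rowMeans(Rs[, s:e, drop = FALSE])^2
        if (max(vr) > v) { v <- max(vr); best <- vr }
      }
      vtot <- best
    } else {
      vtot <- rowSums(Rs^2) / Tt - rowMeans(Rs)^2
    }
    vtot[blocked] <- -Inf
    p <- which.max(vtot)
    if (!is.finite(vtot[p])) break
    seed_var <- c(seed_var, vtot[p])
    ctr <- pix_coords(p, cols)[1, ]
    blocked[square_window(ctr, max(1L, round(params$gaussian_width / 2)),
                          rows, cols)] <- TRUE
    pix <- square_window(ctr, half, rows, cols)
    ctr_pix <- square_window(ctr, 1L, rows, cols)
    fit <- local_rank1(R, pix, center_trace = colMeans(R[ctr_pix, , drop = FALSE]))
    if (sum(fit$a) == 0 || sum(fit$c) == 0) next
    A[pix, k] <- fit$a
    C[k, ] <- fit$c
    upd <- fit$a %*% t(fit$c)
    R[pix, ] <- R[pix, ] - upd
    # the smoothed residual changes only through columns of S touching pix
    Rs <- Rs - as.matrix(S[, pix, drop = FALSE] %*% upd)
  }
  keep <- colSums(A) > 0
  out <- list(footprints = A[, keep, drop = FALSE],
              traces = C[keep, , drop = FALSE])
  attr(out, "seed_variance") <- seed_var[keep]
  out
}

#' GreedyCorr initialization
#'
#' Seeds components at local maxima of the pointwise product of the
#' correlation image and the peak-to-noise image, accepting peaks whose
#' correlation-image value exceeds \code{min_corr} and whose PNR exceeds
#' \code{min_pnr}; the number of components is data-driven.
#'
#' @inheritParams greedy_roi
#' @return list with \code{footprints} and \code{traces}.
#' @export
greedy_corr <- function(mov, params = init_params(method = "greedy_corr")) {
  rows <- mov$fov_dims[1]; cols <- mov$fov_dims[2]
  d <- rows * cols; Tt <- ncol(mov$data)
  ci <- correlation_image(mov)
  pnr <- pnr_image(mov)
  score <- ci * pnr
  hw <- max(1L, ceiling(params$gaussian_width))
  peaks <- local_maxima(score, half_width = hw)
  if (nrow(peaks) > 0L) {
    ok <- ci[peaks] > params$min_corr & pnr[peaks] > params$min_pnr
    peaks <- peaks[ok, , drop = FALSE]
  }
  K <- nrow(peaks)
  A <- matrix(0, d, K); C <- matrix(0, K, Tt)
  R <- detrend_movie(mov$data, mov$frame_rate)
  half <- ceiling(2 * params$gaussian_width)
  for (k in seq_len(K)) {
    ctr <- c(peaks[k, 1], peaks[k, 2])
    pix <- square_window(ctr, half, rows, cols)
    fit <- local_rank1(R, pix)
    A[pix, k] <- fit$a
    C[k, ] <- fit$c
    R[pix, ] <- R[pix, ] - fit$a %*% t(fit$c)
  }
  keep <- colSums(A) > 0
  list(footprints = A[, keep, drop = FALSE], traces = C[keep, , drop = FALSE])
}

#' Seeded initialization from binary or real-valued masks
#'
#' Estimates the temporal background from pixels outside all masks, then the
#' spatial background by non-negative regression, temporal traces by
#' non-negative projection, and spatial footprints by non-negative
#' regression with support confined to the masks, optionally followed by a
#' few HALS polish iterations.
#'
#' @param mov a \code{movie}.
#' @param masks d x N matrix of binary or non-negative masks.
#' @param background_rank rank n_b of the background model.
#' @param hals_iterations polish iterations (0 to skip).
#' @return list with \code{footprints}, \code{traces} and \code{background}
#'   (a low-rank \code{\link{background_model}}).
#' @export
seeded_initialization <- function(mov, masks, background_rank = 2L,
                                  hals_iterations = 5L) {
  Y <- mov$data
  d <- nrow(Y); Tt <- ncol(Y)
  if (is.null(dim(masks))) masks <- matrix(masks, d, 1L)
  N <- ncol(masks)
  if (N == 0L) {
    warning("empty mask set: returning a background-only model")
    bf <- nmf_hals(Y, background_rank, seed = 7L)
    bg <- background_model("low_rank", spatial = bf$W, temporal = bf$H)
    return(list(footprints = matrix(0, d, 0L), traces = matrix(0, 0L, Tt),
                background = bg))
  }
  covered <- rowSums(masks > 0) > 0
  if (all(covered)) stop("no background pixels: masks cover the full FOV")
  # temporal background from mask-free pixels, then spatial by regression
  nb <- background_rank
  f <- nmf_hals(Y[!covered, , drop = FALSE], nb, seed = 7L)$H
  b <- nnls_footprints(Y, f, A0 = matrix(0, d, max(nb, 0L)))
  # traces by non-negative projection through the mask pseudoinverse
  M <- (masks > 0) * 1
  G <- crossprod(M)
  Cproj <- tryCatch(solve(G, crossprod(M, Y - b %*% f)),
                    error = function(e) {
                      MASS_ginv <- function(X) {
                        s <- svd(X)
                        pos <- s$d > max(s$d) * 1e-10
                        s$v[, pos, drop = FALSE] %*%
                          ((1 / s$d[pos]) * t(s$u[, pos, drop = FALSE]))
                      }
                      MASS_ginv(G) %*% crossprod(M, Y - b %*% f)
                    })
  C <- pmax(Cproj, 0)
  A <- nnls_footprints(Y - b %*% f, C, A0 = masks * 0, mask = masks > 0)
  if (hals_iterations > 0L) {
    ref <- hals_refine(mov,
                       list(footprints = A, traces = C),
                       background_model("low_rank", spatial = b, temporal = f),
                       iterations = hals_iterations,
                       support = masks > 0)
    A <- ref$components$footprints; C <- ref$components$traces
    b <- ref$background$spatial; f <- ref$background$temporal
  }
  list(footprints = A, traces = C,
       background = background_model("low_rank", spatial = b, temporal = f))
}
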