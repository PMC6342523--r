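# Internal numerical helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so that library functions do not
#' perturb user-level random streams.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' 1D Gaussian kernel truncated at 3 sigma
#' @noRd
gauss_kernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-h:h)^2 / (2 * sigma^2))
  k / sum(k)
}

#' Separable Gaussian blur of a matrix (image), replicate-padded borders
#' @noRd
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gauss_kernel1d(sigma)
  conv1 <- function(x, k) {
    h <- (length(k) - 1L) / 2L
    n <- length(x)
    xp <- c(rep(x[1], h), x, rep(x[n], h))
    as.numeric(stats::filter(xp, k, sides = 2))[(h + 1L):(h + n)]
  }
  out <- apply(img, 2L, conv1, k = k)
  t(apply(out, 1L, conv1, k = k))
}

#' Sparse d x d smoothing operator for a rows x cols FOV (separable Gaussian)
#'
#' Pixel flattening is row-major: index = (row - 1) * cols + col.
#' @noRd
smoothing_operator <- function(rows, cols, sigma) {
  k <- gauss_kernel1d(sigma)
  h <- (length(k) - 1L) / 2L
  band1d <- function(n) {
    ii <- jj <- xx <- vector("list", length(k))
    for (m in seq_along(k)) {
      off <- m - h - 1L
      i <- seq_len(n)
      j <- i + off
      keep <- j >= 1L & j <= n
      ii[[m]] <- i[keep]; jj[[m]] <- j[keep]; xx[[m]] <- rep(k[m], sum(keep))
    }
    B <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                              dims = c(n, n))
    # renormalize rows at borders so the kernel integrates to one
    rs <- Matrix::rowSums(B)
    Matrix::Diagonal(x = 1 / rs) %*% B
  }
  Br <- band1d(rows)
  Bc <- band1d(cols)
  # row-major flattening: pixel = (r-1)*cols + c, so rows vary slowest
  Matrix::kronecker(Br, Bc)
}

#' Pixel index helpers for row-major FOV flattening (0-based grid, 1-based index)
#' @noRd
pix_index <- function(r, c, cols) (r - 1L) * cols + c

#' @noRd
pix_coords <- function(idx, cols) {
  r <- (idx - 1L) %/% cols + 1L
  c <- (idx - 1L) %% cols + 1L
  cbind(r, c)
}

#' Rank-r non-negative matrix factorization by HALS updates
#'
#' Minimizes ||Y - W H||_F over W >= 0 (n x r), H >= 0 (r x m). Used for
#' background estimation and local rank-1 fits. Deterministic given `seed`.
#' @noRd
nmf_hals <- function(Y, rank, iterations = 30, seed = 1L, tol = 1e-5,
                     W0 = NULL, H0 = NULL) {
  n <- nrow(Y); m <- ncol(Y)
  if (rank == 0L) {
    return(list(W = matrix(0, n, 0L), H = matrix(0, 0L, m)))
  }
  Ypos <- pmax(Y, 0)
  if (is.null(W0) || is.null(H0)) {
    sc <- sqrt(max(mean(Ypos), .Machine$double.eps) / rank)
    rnd <- with_seed(seed, list(W = matrix(stats::runif(n * rank), n, rank),
                                H = matrix(stats::runif(rank * m), rank, m)))
    W <- if (is.null(W0)) rnd$W * sc else W0
    H <- if (is.null(H0)) rnd$H * sc else H0
  } else {
    W <- W0; H <- H0
  }
  obj_prev <- Inf
  for (it in seq_len(iterations)) {
    # update H rows then W columns, one cycle of HALS
    WtY <- crossprod(W, Y); WtW <- crossprod(W)
    for (j in seq_len(rank)) {
      denom <- WtW[j, j]
      if (denom <= 0) next
      H[j, ] <- pmax(H[j, ] + (WtY[j, ] - WtW[j, ] %*% H) / denom, 0)
    }
    YHt <- Y %*% t(H); HHt <- tcrossprod(H)
    for (j in seq_len(rank)) {
      denom <- HHt[j, j]
      if (denom <= 0) next
      W[, j] <- pmax(W[, j] + (YHt[, j] - W %*% HHt[, j]) / denom, 0)
    }
    if (it %% 5L == 0L || it == iterations) {
      obj <- sum((Y - W %*% H)^2)
      if (is.finite(obj_prev) && obj_prev - obj < tol * max(obj_prev, 1e-12)) break
      obj_prev <- obj
    }
  }
  list(W = W, H = H)
}

#' Non-negative least squares trace update (HALS on rows of C)
#'
#' One or more passes of blockwise coordinate descent for
#' min_{C >= 0} ||Y - A C||_F with A fixed. `AtY` and `AtA` may be
#' precomputed.
#' @noRd
nnls_traces <- function(A, Y, C0 = NULL, passes = 10, AtY = NULL, AtA = NULL) {
  K <- ncol(A)
  Tt <- ncol(Y)
  if (K == 0L) return(matrix(0, 0L, Tt))
  if (is.null(AtY)) AtY <- crossprod(A, Y)
  if (is.null(AtA)) AtA <- crossprod(A)
  C <- if (is.null(C0)) matrix(0, K, Tt) else C0
  for (p in seq_len(passes)) {
    delta <- 0
    for (j in seq_len(K)) {
      denom <- AtA[j, j]
      if (denom <= 0) next
      new <- pmax(C[j, ] + (AtY[j, ] - AtA[j, ] %*% C) / denom, 0)
      delta <- max(delta, max(abs(new - C[j, ])))
      C[j, ] <- new
    }
    if (delta < 1e-9) break
  }
  C
}

#' Support-constrained non-negative footprint update (HALS on columns of A)
#'
#' min_{A >= 0, supp(A) <= mask} ||Y - A C||_F with C fixed.
#' `mask` is a d x K logical matrix (TRUE where the footprint may be nonzero).
#' @noRd
nnls_footprints <- function(Y, C, A0, mask = NULL, passes = 10,
                            YCt = NULL, CCt = NULL) {
  K <- nrow(C)
  A <- A0
  if (K == 0L) return(A)
  if (is.null(YCt)) YCt <- Y %*% t(C)
  if (is.null(CCt)) CCt <- tcrossprod(C)
  for (p in seq_len(passes)) {
    delta <- 0
    for (j in seq_len(K)) {
      denom <- CCt[j, j]
      if (denom <= 0) next
      new <- pmax(A[, j] + (YCt[, j] - A %*% CCt[, j]) / denom, 0)
      if (!is.null(mask)) new[!mask[, j]] <- 0
      delta <- max(delta, max(abs(new - A[, j])))
      A[, j] <- new
    }
    if (delta < 1e-9) break
  }
  A
}

#' Dilate a set of footprint supports by one pixel (4-neighborhood)
#' @noRd
dilate_support <- function(mask_vec, rows, cols) {
  m <- matrix(mask_vec, nrow = rows, ncol = cols, byrow = TRUE)
  out <- m
  out[-1, ] <- out[-1, ] | m[-rows, ]
  out[-rows, ] <- out[-rows, ] | m[-1, ]
  out[, -1] <- out[, -1] | m[, -cols]
  out[, -cols] <- out[, -cols] | m[, -1]
  as.vector(t(out))
}

#' Local maxima of an image with a minimum separation
#'
#' Returns (row, col) positions where the image attains the maximum of its
#' (2h+1)^2 neighborhood, ordered by decreasing value.
#' @noRd
local_maxima <- function(img, half_width, n_max = Inf, threshold = -Inf) {
  rows <- nrow(img); cols <- ncol(img)
  h <- max(1L, as.integer(half_width))
  # running max filter, separable
  maxfilt1 <- function(x, h) {
    n <- length(x)
    out <- x
    for (off in seq_len(h)) {
      out <- pmax(out, c(x[-seq_len(off)], rep(-Inf, off)),
                  c(rep(-Inf, off), x[seq_len(n - off)]))
    }
    out
  }
  mrow <- apply(img, 2L, maxfilt1, h = h)
  mfull <- t(apply(mrow, 1L, maxfilt1, h = h))
  is_peak <- img >= mfull & img > threshold
  idx <- which(is_peak, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(idx)
  ord <- order(img[idx], decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  # enforce pairwise separation > h among the chosen peaks
  keep <- logical(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    ok <- TRUE
    if (any(keep)) {
      prev <- idx[keep, , drop = FALSE]
      if (any(pmax(abs(prev[, 1] - idx[i, 1]), abs(prev[, 2] - idx[i, 2])) <= h)) ok <- FALSE
    }
    keep[i] <- ok
    if (sum(keep) >= n_max) break
  }
  idx[keep, , drop = FALSE]
}

#' Frobenius objective of the CNMF model
#' @noRd
cnmf_objective <- function(Y, A, C, b, f) {
  R <- Y - b %*% f
  if (ncol(A) > 0L) R <- R - A %*% C
  sum(R^2)
}

#' Per-pixel running-percentile detrend of a movie matrix
#'
#' Subtracts a running low percentile (block quantiles at the given stride,
#' linearly interpolated) from every pixel's time series. Removes slow
#' neuropil/background drifts while leaving second-scale transients intact.
#' @noRd
detrend_movie <- function(Y, frame_rate, window_seconds = 10,
                          percentile = 20) {
  Tt <- ncol(Y)
  w <- max(2L, round(window_seconds * frame_rate))
  if (w >= Tt) {
    base <- apply(Y, 1L, stats::quantile, probs = percentile / 100,
                  names = FALSE)
    return(Y - base)
  }
  starts <- seq(1L, Tt, by = w)
  centers <- pmin(starts + (w - 1) / 2, Tt)
  V <- vapply(starts, function(s) {
    blk <- Y[, s:min(Tt, s + w - 1L), drop = FALSE]
    apply(blk, 1L, stats::quantile, probs = percentile / 100, names = FALSE)
  }, numeric(nrow(Y)))
  # interpolation weights from block centers to every frame
  W <- vapply(seq_len(Tt), function(t) {
    if (t <= centers[1]) return(c(1, rep(0, length(centers) - 1L)))
    if (t >= centers[length(centers)]) {
      return(c(rep(0, length(centers) - 1L), 1))
    }
    j <- findInterval(t, centers)
    wgt <- numeric(length(centers))
    frac <- (t - centers[j]) / (centers[j + 1L] - centers[j])
    wgt[j] <- 1 - frac; wgt[j + 1L] <- frac
    wgt
  }, numeric(ncol(V)))
  Y - V %*% W
}
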