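# Footprint classification: decide whether a spatial footprint looks like a
# neuron soma. Two backends are provided:
#  - a deterministic geometric scorer (compactness x solidity of the
#    thresholded crop), used when no trained model is supplied;
#  - a single-hidden-layer neural network trained on synthetic soma crops
#    (Gaussian and donut shapes) versus non-soma crops (noise fields, edges,
#    off-center partial shapes).

CLASSIFIER_SIDE <- 24L

#' Crop a footprint to a square image around its centroid
#'
#' @param a length-d footprint vector (row-major FOV flattening).
#' @param rows,cols FOV dimensions.
#' @param side output side length in pixels; the crop is clipped at the FOV
#'   border and zero-padded to \code{side}.
#' @return a \code{side} x \code{side} matrix, max-normalized.
#' @export
footprint_crop <- function(a, rows, cols, side = NULL) {
  if (is.null(side)) side <- max(12L, 2L * ceiling(2 * footprint_radius(a, rows, cols)))
  img <- matrix(a, rows, cols, byrow = TRUE)
  ctr <- round(footprint_centroid(a, rows, cols))
  half <- side %/% 2L
  out <- matrix(0, side, side)
  rr <- (ctr[1] - half):(ctr[1] + half - 1L + side %% 2L)
  cc <- (ctr[2] - half):(ctr[2] + half - 1L + side %% 2L)
  ok_r <- rr >= 1L & rr <= rows
  ok_c <- cc >= 1L & cc <= cols
  out[which(ok_r), which(ok_c)] <- img[rr[ok_r], cc[ok_c]]
  mx <- max(out)
  if (mx > 0) out <- out / mx
  out
}

# Bilinear resampling of a square image to side n.
resample_image <- function(img, n) {
  m <- nrow(img)
  if (m == n) return(img)
  src <- (seq_len(n) - 0.5) * m / n + 0.5
  src <- pmin(pmax(src, 1), m)
  i0 <- pmin(floor(src), m - 1L); w <- src - i0
  out <- matrix(0, n, n)
  for (r in seq_len(n)) {
    row <- img[i0[r], ] * (1 - w[r]) + img[i0[r] + 1L, ] * w[r]
    out[r, ] <- row[i0] * (1 - w) + row[i0 + 1L] * w
  }
  out
}

# Pixel count covered by the convex hull of a pixel set: shoelace area of
# the hull polygon through pixel centers, plus the boundary correction
# (perimeter / 2 + 1, cf. Pick's theorem).
hull_area <- function(pts) {
  if (nrow(pts) < 3L) return(nrow(pts))
  h <- grDevices::chull(pts)
  xy <- pts[h, , drop = FALSE]
  n <- nrow(xy)
  s <- abs(sum(xy[, 1] * xy[c(2:n, 1), 2] - xy[c(2:n, 1), 1] * xy[, 2])) / 2
  per <- sum(sqrt(rowSums((xy - xy[c(2:n, 1), , drop = FALSE])^2)))
  s + per / 2 + 1
}

#' Deterministic geometric footprint score
#'
#' Thresholds the max-normalized crop at half its maximum and scores the
#' resulting mask by circular fill (mask area over the area of the
#' circumscribed circle around its centroid) times solidity (mask area over
#' convex hull area). Compact, convex blobs score near 1; scattered or
#' elongated masks score low.
#'
#' @param crop square image matrix (max-normalized).
#' @return score in [0, 1].
#' @export
fallback_footprint_score <- function(crop) {
  mx <- max(crop)
  if (mx <= 0) return(0)
  mask <- which(crop >= 0.5 * mx, arr.ind = TRUE)
  area <- nrow(mask)
  if (area == 0L) return(0)
  ctr <- colMeans(mask)
  rmax <- max(1, sqrt(max((mask[, 1] - ctr[1])^2 + (mask[, 2] - ctr[2])^2)))
  fill <- area / (pi * rmax^2)
  sol <- area / max(hull_area(mask), area)
  min(1, fill) * min(1, sol)
}

# --- synthetic crop generator for classifier training ---------------------

# One synthetic crop plus its label (1 = soma-like, 0 = not).
synth_crop <- function(side = CLASSIFIER_SIDE, positive = TRUE) {
  r <- stats::runif(1, side / 8, side / 4.5)
  noise <- stats::runif(1, 0.02, 0.15)
  gauss <- function(ctr, sd) {
    d2 <- outer((seq_len(side) - ctr[1])^2, (seq_len(side) - ctr[2])^2, "+")
    exp(-d2 / (2 * sd^2))
  }
  if (positive) {
    ctr <- (side + 1) / 2 + stats::runif(2, -1.5, 1.5)
    img <- gauss(ctr, r)
    if (stats::runif(1) < 0.4) img <- img - 0.65 * gauss(ctr, r / 2) # donut
  } else {
    kind <- sample(3L, 1L)
    if (kind == 1L) {                     # structured noise field
      img <- gauss_blur(matrix(stats::runif(side^2), side, side), 1)
    } else if (kind == 2L) {              # edge / gradient
      ang <- stats::runif(1, 0, pi)
      img <- outer(seq_len(side) * cos(ang), seq_len(side) * sin(ang), "+")
      img <- (img - min(img)) / diff(range(img))
    } else {                              # partial off-center shape
      ctr <- c(sample(c(1, side), 1), stats::runif(1, 1, side))
      img <- gauss(ctr, r * stats::runif(1, 1, 2))
    }
  }
  img <- pmax(img + matrix(stats::rnorm(side^2, sd = noise), side, side), 0)
  img / max(img)
}

#' Generate a labeled set of synthetic footprint crops
#'
#' @param n number of crops.
#' @param side crop side length in pixels.
#' @param seed RNG seed.
#' @return list with \code{crops} (list of matrices) and \code{labels}
#'   (0/1 vector, balanced).
#' @export
synth_crop_set <- function(n, side = CLASSIFIER_SIDE, seed = 1L) {
  with_seed(seed, {
    labels <- rep(c(1L, 0L), length.out = n)
    crops <- lapply(labels, function(l) synth_crop(side, positive = l == 1L))
    list(crops = crops, labels = labels)
  })
}

#' Train the footprint classifier on synthetic crops
#'
#' Fits a single-hidden-layer neural network (\code{nnet}) on max-normalized
#' crops resampled to a fixed input side. Positives are centered Gaussian or
#' donut shapes; negatives are noise fields, edges and off-center partial
#' shapes, all generated by \code{\link{synth_crop_set}}.
#'
#' @param n_train number of training crops.
#' @param side network input side (crops are resampled to side x side).
#' @param hidden hidden-layer size.
#' @param seed RNG seed for data generation and weight initialization.
#' @return an object of class \code{footprint_classifier}.
#' @export
train_footprint_classifier <- function(n_train = 800L, side = 16L,
                                       hidden = 12L, seed = 1L) {
  dat <- synth_crop_set(n_train, side = side, seed = seed)
  X <- t(vapply(dat$crops, function(cr) as.vector(resample_image(cr, side)),
                numeric(side^2)))
  fit <- with_seed(seed + 1L, {
    nnet::nnet(X, dat$labels, size = hidden, decay = 1e-3, maxit = 200,
               MaxNWts = 100000L, trace = FALSE, entropy = TRUE)
  })
  structure(list(net = fit, side = side), class = "footprint_classifier")
}

#' Score footprint crops as soma-like or not
#'
#' @param crops list of square crop matrices (max-normalized; see
#'   \code{\link{footprint_crop}}).
#' @param model a \code{footprint_classifier}, or NULL to use the
#'   deterministic geometric scorer.
#' @return numeric vector of scores in [0, 1].
#' @export
classify_footprints <- function(crops, model = NULL) {
  if (is.null(model)) {
    return(vapply(crops, fallback_footprint_score, numeric(1)))
  }
  stopifnot(inherits(model, "footprint_classifier"))
  X <- t(vapply(crops, function(cr) {
    as.vector(resample_image(cr, model$side))
  }, numeric(model$side^2)))
  as.numeric(stats::predict(model$net, X))
}
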