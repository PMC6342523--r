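# Batch CNMF: patch decomposition, per-patch factorization, merging across
# patch seams, background merging, full-FOV HALS refinement, and the ring
# background model for one-photon data.

#' Background model container
#'
#' @param kind "low_rank" (B = spatial %*% temporal) or "ring"
#'   (B = W (Y - A C), with W a sparse pixel-by-pixel weight matrix whose
#'   rows are supported on an annulus around each pixel).
#' @param spatial d x n_b matrix (low-rank).
#' @param temporal n_b x T matrix (low-rank).
#' @param ring_weights sparse d x d matrix W (ring).
#' @param ring_radius annulus inner radius in pixels (ring).
#' @param dense optional precomputed dense B (ring).
#' @return an object of class \code{background_model}.
#' @export
background_model <- function(kind = c("low_rank", "ring"), spatial = NULL,
                             temporal = NULL, ring_weights = NULL,
                             ring_radius = NULL, dense = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, spatial = spatial, temporal = temporal,
                 ring_weights = ring_weights, ring_radius = ring_radius,
                 dense = dense),
            class = "background_model")
}

#' Component set container
#'
#' @param footprints d x N non-negative matrix A.
#' @param traces N x T non-negative matrix C.
#' @param deconvolved optional N x T spike matrix S.
#' @return an object of class \code{component_set} (a list).
#' @export
component_set <- function(footprints, traces, deconvolved = NULL) {
  stopifnot(ncol(footprints) == nrow(traces))
  structure(list(footprints = footprints, traces = traces,
                 deconvolved = deconvolved), class = "component_set")
}

#' Batch pipeline parameters
#'
#' @param patch_size integer(2) patch size in pixels (default 48 x 48).
#' @param overlap seam overlap in pixels (default 8).
#' @param components_per_patch greedy components K per patch.
#' @param background_rank background rank n_b per patch and for the final
#'   model.
#' @param merge_threshold temporal correlation threshold for merging
#'   spatially overlapping components (default 0.8).
#' @param merged_background_rank rank g_b used to compress each patch
#'   background before embedding (default 1).
#' @param hals_iterations HALS refinement iterations (default 5).
#' @param init an \code{\link{init_params}}.
#' @param thresholds a \code{\link{quality_thresholds}}.
#' @param mode "2p" (low-rank background) or "1p" (ring background).
#' @param ring_radius annulus radius for 1p mode; default twice the neuron
#'   radius.
#' @param seed seed for the NMF initializations.
#' @return an object of class \code{batch_params}.
#' @export
batch_params <- function(patch_size = c(48L, 48L), overlap = 8L,
                         components_per_patch = 10L, background_rank = 2L,
                         merge_threshold = 0.8, merged_background_rank = 1L,
                         hals_iterations = 5L, init = init_params(),
                         thresholds = quality_thresholds(),
                         mode = c("2p", "1p"), ring_radius = NULL,
                         seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(merge_threshold >= 0, merge_threshold <= 1)
  structure(list(patch_size = as.integer(patch_size),
                 overlap = as.integer(overlap),
                 components_per_patch = as.integer(components_per_patch),
                 background_rank = as.integer(background_rank),
                 merge_threshold = merge_threshold,
                 merged_background_rank = as.integer(merged_background_rank),
                 hals_iterations = as.integer(hals_iterations),
                 init = init, thresholds = thresholds, mode = mode,
                 ring_radius = ring_radius, seed = as.integer(seed)),
            class = "batch_params")
}

#' Tile a field of view into overlapping patches
#'
#' Patches start at multiples of \code{patch_size - overlap}; a patch is
#' truncated at the FOV border, and trailing patches that would start after
#' the border is already covered are dropped.
#'
#' @param fov_dims integer(2) (rows, cols).
#' @param patch_size integer(2).
#' @param overlap overlap in pixels (must be smaller than the patch).
#' @return an object of class \code{patch_layout} with \code{patches} (list
#'   of row/col inclusive ranges) and \code{coverage} (rows x cols count
#'   image).
#' @export
construct_patches <- function(fov_dims, patch_size, overlap = 0L) {
  patch_size <- rep(as.integer(patch_size), length.out = 2L)
  fov_dims <- as.integer(fov_dims)
  overlap <- as.integer(overlap)
  if (any(overlap >= patch_size)) stop("overlap must be smaller than patch_size")
  if (any(patch_size > fov_dims)) stop("patch_size exceeds the FOV")
  axis_starts <- function(dim, ps, os) {
    stride <- ps - os
    starts <- integer(0)
    s <- 1L
    while (s <= dim) {
      starts <- c(starts, s)
      if (s + ps - 1L >= dim) break   # border covered
      s <- s + stride
    }
    starts
  }
  rs <- axis_starts(fov_dims[1], patch_size[1], overlap)
  cs <- axis_starts(fov_dims[2], patch_size[2], overlap)
  patches <- list()
  coverage <- matrix(0L, fov_dims[1], fov_dims[2])
  for (r0 in rs) for (c0 in cs) {
    r1 <- min(fov_dims[1], r0 + patch_size[1] - 1L)
    c1 <- min(fov_dims[2], c0 + patch_size[2] - 1L)
    patches[[length(patches) + 1L]] <- list(rows = c(r0, r1), cols = c(c0, c1))
    coverage[r0:r1, c0:c1] <- coverage[r0:r1, c0:c1] + 1L
  }
  structure(list(patches = patches, coverage = coverage,
                 fov_dims = fov_dims, patch_size = patch_size,
                 overlap = overlap),
            class = "patch_layout")
}

#' Merge duplicated components
#'
#' Groups components that overlap spatially (a_i' a_j > 0) and whose traces
#' correlate at or above \code{merge_threshold}, and replaces each connected
#' group by the non-negative rank-1 pair (a_m, c_m) minimizing
#' ||A_old C_old - a_m c_m'|| over the group (50 alternating updates,
#' initialized from the largest-norm member). Merged footprints are
#' rescaled to unit Euclidean norm.
#'
#' @param components a \code{\link{component_set}} or compatible list.
#' @param merge_threshold correlation threshold in [0, 1].
#' @return a \code{\link{component_set}} with at most as many components.
#' @export
merge_components <- function(components, merge_threshold = 0.8) {
  A <- components$footprints; C <- components$traces
  N <- ncol(A)
  if (N <= 1L) return(component_set(A, C))
  overlap <- as.matrix(crossprod(A)) > 0
  cors <- suppressWarnings(stats::cor(t(C)))
  cors[!is.finite(cors)] <- 0
  adj <- overlap & cors >= merge_threshold
  diag(adj) <- FALSE
  # connected components by BFS
  group_id <- integer(N)
  g <- 0L
  for (i in seq_len(N)) {
    if (group_id[i] > 0L) next
    g <- g + 1L
    queue <- i
    while (length(queue) > 0L) {
      v <- queue[1]; queue <- queue[-1]
      if (group_id[v] > 0L) next
      group_id[v] <- g
      queue <- c(queue, which(adj[v, ] & group_id == 0L))
    }
  }
  keepA <- list(); keepC <- list()
  for (grp in seq_len(g)) {
    members <- which(group_id == grp)
    if (length(members) == 1L) {
      keepA[[grp]] <- A[, members]; keepC[[grp]] <- C[members, ]
      next
    }
    fit <- merge_rank1(A[, members, drop = FALSE], C[members, , drop = FALSE])
    keepA[[grp]] <- fit$a; keepC[[grp]] <- fit$c
  }
  component_set(do.call(cbind, keepA),
                do.call(rbind, keepC))
}

# Rank-1 non-negative fit to the product A C of a merge group, restricted
# to the union support. 50 alternating updates from the largest-norm member.
merge_rank1 <- function(A, C, iterations = 50L) {
  d <- nrow(A)
  supp <- which(rowSums(A) > 0)
  M <- A[supp, , drop = FALSE] %*% C
  norms <- sqrt(colSums(A^2)) * sqrt(rowSums(C^2))
  a <- A[supp, which.max(norms)]
  for (it in seq_len(iterations)) {
    cc <- pmax(as.numeric(crossprod(M, a)) / sum(a^2), 0)
    den <- sum(cc^2)
    if (den == 0) break
    a <- pmax(as.numeric(M %*% cc) / den, 0)
    if (sum(a^2) == 0) break
  }
  cc <- pmax(as.numeric(crossprod(M, a)) / max(sum(a^2), 1e-300), 0)
  nrm <- sqrt(sum(a^2))
  a_full <- numeric(d)
  if (nrm > 0) {
    a_full[supp] <- a / nrm
    cc <- cc * nrm
  }
  list(a = a_full, c = cc)
}

#' Merge patch backgrounds into one low-rank model
#'
#' Each patch background is compressed to rank g_b by NMF, embedded into
#' the full FOV with coverage normalization, and — when the total number of
#' columns exceeds the target rank — compressed once more by a final NMF of
#' rank \code{background_rank}.
#'
#' @param patch_backgrounds list of lists with \code{spatial} (patch pixels
#'   x n_b), \code{temporal} (n_b x T), and \code{pixels} (their full-FOV
#'   indices).
#' @param d total pixel count.
#' @param coverage per-pixel patch coverage counts (length d, row-major).
#' @param g_b per-patch compression rank.
#' @param background_rank final rank n_b.
#' @param seed NMF seed.
#' @return a low-rank \code{\link{background_model}}.
#' @export
merge_backgrounds <- function(patch_backgrounds, d, coverage, g_b = 1L,
                              background_rank = 2L, seed = 1L) {
  patch_backgrounds <- Filter(function(p) !is.null(p$spatial) &&
                                ncol(p$spatial) > 0, patch_backgrounds)
  if (length(patch_backgrounds) == 0L) {
    Tt <- 0L
    return(background_model("low_rank", spatial = matrix(0, d, 0L),
                            temporal = matrix(0, 0L, Tt)))
  }
  Tt <- ncol(patch_backgrounds[[1]]$temporal)
  bs <- list(); fs <- list()
  for (p in patch_backgrounds) {
    b <- p$spatial; f <- p$temporal
    if (ncol(b) > g_b) {
      fit <- nmf_hals(b %*% f, g_b, seed = seed, iterations = 50)
      b <- fit$W; f <- fit$H
    }
    bf <- matrix(0, d, ncol(b))
    bf[p$pixels, ] <- b / coverage[p$pixels]
    bs[[length(bs) + 1L]] <- bf
    fs[[length(fs) + 1L]] <- f
  }
  B <- do.call(cbind, bs)
  Fm <- do.call(rbind, fs)
  if (ncol(B) > background_rank) {
    fit <- nmf_hals(B %*% Fm, background_rank, seed = seed, iterations = 50)
    B <- fit$W; Fm <- fit$H
  }
  background_model("low_rank", spatial = B, temporal = Fm)
}

#' HALS refinement of a full factorization
#'
#' Alternates non-negative updates of the background (warm-started NMF on
#' the residual), the traces (non-negative regression), and the footprints
#' (non-negative regression with support confined to the current support
#' dilated by one pixel). Every update is a block-coordinate descent step on
#' ||Y - A C - b f||_F^2, so the objective is non-increasing; an increase
#' beyond 1e-8 relative aborts with diagnostics.
#'
#' @param mov a \code{movie}.
#' @param components a \code{\link{component_set}}.
#' @param background a low-rank \code{\link{background_model}}.
#' @param iterations number of refinement rounds (0 returns the inputs).
#' @param support optional fixed d x N logical support mask; by default the
#'   current nonzero support dilated by one pixel each round.
#' @return list with updated \code{components}, \code{background} and the
#'   per-iteration \code{objective} values.
#' @export
hals_refine <- function(mov, components, background, iterations = 5L,
                        support = NULL) {
  Y <- mov$data
  rows <- mov$fov_dims[1]; cols <- mov$fov_dims[2]
  A <- components$footprints; C <- components$traces
  b <- background$spatial; f <- background$temporal
  if (is.null(b)) { b <- matrix(0, nrow(Y), 0L); f <- matrix(0, 0L, ncol(Y)) }
  nb <- ncol(b)
  obj <- cnmf_objective(Y, A, C, b, f)
  objs <- obj
  for (it in seq_len(iterations)) {
    if (nb > 0L) {
      R <- Y - A %*% C
      fit <- nmf_hals(R, nb, W0 = b, H0 = f, iterations = 5)
      b <- fit$W; f <- fit$H
    }
    Yr <- Y - b %*% f
    C <- nnls_traces(A, Yr, C0 = C, passes = 5)
    if (ncol(A) > 0L) {
      mask <- if (is.null(support)) {
        apply(A > 0, 2L, dilate_support, rows = rows, cols = cols)
      } else support
      A <- nnls_footprints(Yr, C, A0 = A, mask = mask, passes = 5)
    }
    new_obj <- cnmf_objective(Y, A, C, b, f)
    if (new_obj > obj * (1 + 1e-8) + 1e-12) {
      stop(sprintf(
        "hals_refine: objective increased at iteration %d (%.6g -> %.6g)",
        it, obj, new_obj))
    }
    obj <- new_obj
    objs <- c(objs, obj)
  }
  keep <- colSums(A) > 0    # no all-zero footprint leaves a pipeline stage
  list(components = component_set(A[, keep, drop = FALSE],
                                  C[keep, , drop = FALSE]),
       background = background_model("low_rank", spatial = b, temporal = f),
       objective = objs)
}

#' Ring model of the one-photon background
#'
#' Estimates, for every pixel, non-negative weights onto the residual
#' traces of pixels in an annulus [ring_radius, ring_radius + ring_width)
#' around it, so that B = W (Y - A C). The annulus is downsampled to at most
#' \code{max_regressors} pixels, and the weights are fit on a temporal
#' subsample of the residual for tractability.
#'
#' @param mov a \code{movie}.
#' @param components a \code{\link{component_set}} (may be empty).
#' @param ring_radius annulus inner radius in pixels.
#' @param ring_width annulus width (default 1 pixel).
#' @param max_regressors maximum annulus pixels used per target pixel.
#' @param fit_frames maximum frames used to estimate the weights.
#' @return a ring \code{\link{background_model}} with the dense B attached.
#' @export
ring_background <- function(mov, components = NULL, ring_radius = 6,
                            ring_width = 1, max_regressors = 32L,
                            fit_frames = 256L) {
  Y <- mov$data
  rows <- mov$fov_dims[1]; cols <- mov$fov_dims[2]
  d <- rows * cols
  R <- Y
  if (!is.null(components) && ncol(components$footprints) > 0L) {
    R <- R - components$footprints %*% components$traces
  }
  # annulus offsets
  rad <- ceiling(ring_radius + ring_width)
  offs <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  dist <- sqrt(offs$dr^2 + offs$dc^2)
  offs <- offs[dist >= ring_radius & dist < ring_radius + ring_width, ]
  if (nrow(offs) == 0L || ring_radius >= sqrt(sum((fovd <- mov$fov_dims - 1)^2))) {
    stop("empty annulus: FOV or radius too small")
  }
  sub <- if (ncol(R) > fit_frames) {
    R[, round(seq(1L, ncol(R), length.out = fit_frames))]
  } else R
  ii <- list(); jj <- list(); xx <- list()
  for (p in seq_len(d)) {
    rc <- pix_coords(p, cols)[1, ]
    nr <- rc[1] + offs$dr; nc <- rc[2] + offs$dc
    ok <- nr >= 1 & nr <= rows & nc >= 1 & nc <= cols
    ann <- pix_index(nr[ok], nc[ok], cols)
    if (length(ann) == 0L) next
    if (length(ann) > max_regressors) {
      ann <- ann[round(seq(1L, length(ann), length.out = max_regressors))]
    }
    X <- sub[ann, , drop = FALSE]
    # active-set NNLS: the annulus regressors are strongly correlated, so
    # coordinate descent converges too slowly to be usable here
    w <- tryCatch(pracma::lsqnonneg(t(X), sub[p, ])$x,
                  error = function(e) numeric(length(ann)))
    nz <- which(w > 0)
    if (length(nz) > 0L) {
      ii[[length(ii) + 1L]] <- rep(p, length(nz))
      jj[[length(jj) + 1L]] <- ann[nz]
      xx[[length(xx) + 1L]] <- w[nz]
    }
  }
  W <- if (length(ii) == 0L) {
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(d, d))
  } else {
    Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                         dims = c(d, d))
  }
  dense <- as.matrix(W %*% R)
  background_model("ring", ring_weights = W, ring_radius = ring_radius,
                   dense = dense)
}

# CNMF on one (patch) movie: initialization, HALS, quality filter.
cnmf_single <- function(mov, params) {
  ip <- params$init
  ip$background_rank <- params$background_rank
  ip$n_components <- params$components_per_patch
  init <- switch(ip$method,
                 greedy_roi = greedy_roi(mov, ip),
                 rolling_greedy_roi = greedy_roi(mov, ip),
                 greedy_corr = greedy_corr(mov, ip),
                 stop("unsupported init method for patch processing"))
  A <- init$footprints; C <- init$traces
  bf <- nmf_hals(mov$data - A %*% C, params$background_rank,
                 seed = params$seed)
  bg <- background_model("low_rank", spatial = bf$W, temporal = bf$H)
  ref <- hals_refine(mov, component_set(A, C), bg,
                     iterations = params$hals_iterations)
  # patch-stage screening: skip the shape classifier here because patch
  # borders clip footprints; shapes are judged on the assembled FOV
  th_patch <- params$thresholds
  th_patch$classifier_reject_floor <- 0
  rep <- evaluate_components(mov, ref$components, ref$background, th_patch)
  keep <- which(rep$accepted)
  list(components = component_set(
         ref$components$footprints[, keep, drop = FALSE],
         ref$components$traces[keep, , drop = FALSE]),
       background = ref$background, quality = rep)
}

#' Patch-parallel CNMF over a field of view
#'
#' Runs CNMF independently on each patch of the layout, embeds the results
#' at their patch offsets with per-pixel coverage normalization, merges
#' duplicated components across seams and merges the patch backgrounds.
#' Patch results are independent of processing order.
#'
#' @param mov a \code{movie} or \code{memmap_movie}.
#' @param layout a \code{\link{construct_patches}} layout.
#' @param params a \code{\link{batch_params}}.
#' @param patch_order optional processing order (for order-invariance
#'   checks).
#' @return list with \code{components}, \code{background}.
#' @export
process_in_patches <- function(mov, layout, params = batch_params(),
                               patch_order = NULL) {
  fov <- layout$fov_dims
  d <- prod(fov)
  coverage <- as.vector(t(layout$coverage))
  n_patch <- length(layout$patches)
  if (is.null(patch_order)) patch_order <- seq_len(n_patch)
  results <- vector("list", n_patch)
  for (k in patch_order) {
    pt <- layout$patches[[k]]
    if (inherits(mov, "memmap_movie")) {
      Yp <- read_patch(mov, rows = pt$rows, cols = pt$cols)
      frame_rate <- mov$frame_rate
    } else {
      pix <- as.vector(t(outer((pt$rows[1]:pt$rows[2] - 1L) * fov[2],
                               pt$cols[1]:pt$cols[2], "+")))
      Yp <- mov$data[pix, , drop = FALSE]
      frame_rate <- mov$frame_rate
    }
    pmov <- movie(Yp, fov_dims = c(pt$rows[2] - pt$rows[1] + 1L,
                                   pt$cols[2] - pt$cols[1] + 1L),
                  frame_rate = frame_rate)
    results[[k]] <- cnmf_single(pmov, params)
    results[[k]]$pixels <- as.vector(t(outer(
      (pt$rows[1]:pt$rows[2] - 1L) * fov[2], pt$cols[1]:pt$cols[2], "+")))
  }
  Tt <- ncol(results[[1]]$components$traces)
  if (Tt == 0L) Tt <- if (inherits(mov, "memmap_movie")) mov$dims[3] else ncol(mov$data)
  As <- list(); Cs <- list()
  bgs <- list()
  for (k in seq_len(n_patch)) {
    res <- results[[k]]
    Np <- ncol(res$components$footprints)
    if (Np > 0L) {
      Af <- matrix(0, d, Np)
      Af[res$pixels, ] <- res$components$footprints / coverage[res$pixels]
      As[[length(As) + 1L]] <- Af
      Cs[[length(Cs) + 1L]] <- res$components$traces
    }
    bgs[[k]] <- list(spatial = res$background$spatial,
                     temporal = res$background$temporal,
                     pixels = res$pixels)
  }
  if (length(As) > 0L) {
    A <- do.call(cbind, As); C <- do.call(rbind, Cs)
    merged <- merge_components(component_set(A, C), params$merge_threshold)
  } else {
    merged <- component_set(matrix(0, d, 0L), matrix(0, 0L, Tt))
  }
  bg <- merge_backgrounds(bgs, d, coverage,
                          g_b = params$merged_background_rank,
                          background_rank = params$background_rank,
                          seed = params$seed)
  list(components = merged, background = bg)
}

#' Run the batch CNMF pipeline
#'
#' Full batch analysis: patch layout, patch-parallel CNMF, quality
#' filtering on the full FOV, final HALS refinement, and AR(1)
#' deconvolution of the accepted traces.
#'
#' @param mov a \code{movie}, \code{memmap_movie}, or path to a TIFF or
#'   ".pmap" file.
#' @param params a \code{\link{batch_params}}.
#' @param final_hals iterations of full-FOV HALS after quality filtering.
#' @param deconvolve run AR(1) deconvolution on the final traces.
#' @return list with \code{components} (footprints, traces, deconvolved),
#'   \code{background}, \code{quality} (the final quality report) and
#'   \code{params}.
#' @export
run_batch <- function(mov, params = batch_params(), final_hals = 2L,
                      deconvolve = TRUE) {
  if (is.character(mov)) {
    mov <- if (grepl("\\.pmap$", mov)) memmap_to_movie(open_memmap(mov))
           else read_movie_tiff(mov)
  }
  if (inherits(mov, "memmap_movie")) mov <- memmap_to_movie(mov)
  ps <- pmin(params$patch_size, mov$fov_dims)   # clamp to small FOVs
  layout <- construct_patches(mov$fov_dims, ps,
                              min(params$overlap, min(ps) - 1L))
  res <- process_in_patches(mov, layout, params)
  comps <- res$components
  bg <- res$background
  if (ncol(comps$footprints) > 0L && final_hals > 0L) {
    ref <- hals_refine(mov, comps, bg, iterations = final_hals)
    comps <- ref$components; bg <- ref$background
    # refined traces expose residual duplicates missed at the seam merge
    comps <- merge_components(comps, params$merge_threshold)
    # strip low-weight shells accreted during support dilation
    A_thr <- threshold_footprints(comps$footprints, mov$fov_dims)
    keep <- colSums(A_thr) > 0
    comps <- component_set(A_thr[, keep, drop = FALSE],
                           comps$traces[keep, , drop = FALSE])
  }
  rep <- evaluate_components(mov, comps, bg, params$thresholds)
  keep <- which(rep$accepted)
  if (length(keep) == 0L && ncol(comps$footprints) > 0L) {
    warning("all components rejected by the quality tests")
  }
  comps <- component_set(comps$footprints[, keep, drop = FALSE],
                         comps$traces[keep, , drop = FALSE])
  rep <- rep[keep, , drop = FALSE]
  # duplicate removal on the accepted set
  if (ncol(comps$footprints) > 1L) {
    kept <- detect_duplicates(comps, rep$classifier_score,
                              overlap_dup = params$thresholds$overlap_dup)
    comps <- component_set(comps$footprints[, kept, drop = FALSE],
                           comps$traces[kept, , drop = FALSE])
    rep <- rep[kept, , drop = FALSE]
  }
  if (deconvolve && ncol(comps$footprints) > 0L) {
    S <- matrix(0, nrow(comps$traces), ncol(comps$traces))
    Cd <- comps$traces
    for (i in seq_len(nrow(S))) {
      dc <- oasis_deconvolve(comps$traces[i, ],
                             deconv_params(frame_rate = mov$frame_rate))
      S[i, ] <- dc$spikes; Cd[i, ] <- dc$denoised
    }
    comps$deconvolved <- S
  }
  list(components = comps, background = bg, quality = rep, params = params)
}

#' Threshold footprints to their energy core
#'
#' For each footprint, keeps the smallest pixel set holding the given
#' fraction of its squared energy, restricted to the connected component
#' (4-neighborhood) containing the maximum pixel; stray low-weight shells
#' accumulated during support dilation are removed.
#'
#' @param A d x N footprint matrix.
#' @param fov_dims (rows, cols).
#' @param energy_fraction energy fraction to retain (default 0.99).
#' @return thresholded footprint matrix (all-zero columns possible if an
#'   input column was all zero).
#' @export
threshold_footprints <- function(A, fov_dims, energy_fraction = 0.99) {
  rows <- fov_dims[1]; cols <- fov_dims[2]
  out <- A
  for (j in seq_len(ncol(A))) {
    a <- A[, j]
    nz <- which(a > 0)
    if (length(nz) == 0L) next
    ord <- nz[order(a[nz], decreasing = TRUE)]
    cum <- cumsum(a[ord]^2) / sum(a[ord]^2)
    keep <- ord[seq_len(which(cum >= energy_fraction)[1])]
    # connected component containing the maximum pixel
    keep_set <- logical(length(a))
    keep_set[keep] <- TRUE
    comp <- logical(length(a))
    queue <- ord[1]
    comp[queue] <- TRUE
    while (length(queue) > 0L) {
      p <- queue[1]; queue <- queue[-1]
      rc <- pix_coords(p, cols)[1, ]
      for (sh in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        r2 <- rc[1] + sh[1]; c2 <- rc[2] + sh[2]
        if (r2 < 1L || r2 > rows || c2 < 1L || c2 > cols) next
        q <- pix_index(r2, c2, cols)
        if (keep_set[q] && !comp[q]) { comp[q] <- TRUE; queue <- c(queue, q) }
      }
    }
    a[!comp] <- 0
    out[, j] <- a
  }
  out
}
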