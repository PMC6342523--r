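# Streaming source extraction: per-frame trace updates via sufficient
# statistics, residual-buffer detection of new components with classifier
# and SNR screening, distributed shape updates, and multi-epoch passes.

#' Online processing parameters
#'
#' @param init_frames frames used for initialization (t').
#' @param init_mode "bare" (small CNMF on the prefix), "batch" (full
#'   \code{\link{run_batch}} on the prefix) or "seeded" (masks).
#' @param init_components components extracted by bare initialization
#'   (default 2).
#' @param candidates_per_frame maximum new-component candidates per frame
#'   (N_comp, default 5).
#' @param buffer_frames residual buffer length l_b; default
#'   max(100, ceiling(3.3 * frame_rate)) set at run time.
#' @param shape_update_period T_u: every footprint is updated at least once
#'   every T_u frames (default 200).
#' @param epochs passes over the data (default 2; later epochs replay the
#'   movie with detection still enabled).
#' @param classifier_threshold screen for candidate footprints.
#' @param snr_threshold screen for candidate buffer traces.
#' @param max_overlap_cos candidates whose footprint cosine similarity with
#'   an existing component exceeds this are discarded as re-detections.
#' @param neuron_radius expected neuron radius r in pixels.
#' @param background_rank background rank n_b.
#' @param masks seed masks for init_mode = "seeded".
#' @param seed RNG seed.
#' @return an object of class \code{online_params}.
#' @export
online_params <- function(init_frames = 200L,
                          init_mode = c("bare", "batch", "seeded"),
                          init_components = 2L, candidates_per_frame = 5L,
                          buffer_frames = NULL, shape_update_period = 200L,
                          epochs = 2L, classifier_threshold = 0.5,
                          snr_threshold = 1.5, max_overlap_cos = 0.5,
                          neuron_radius = 3, background_rank = 2L,
                          masks = NULL, seed = 1L) {
  init_mode <- match.arg(init_mode)
  stopifnot(candidates_per_frame >= 0L, epochs >= 1L)
  structure(list(init_frames = as.integer(init_frames),
                 init_mode = init_mode,
                 init_components = as.integer(init_components),
                 candidates_per_frame = as.integer(candidates_per_frame),
                 buffer_frames = buffer_frames,
                 shape_update_period = as.integer(shape_update_period),
                 epochs = as.integer(epochs),
                 classifier_threshold = classifier_threshold,
                 snr_threshold = snr_threshold,
                 max_overlap_cos = max_overlap_cos,
                 neuron_radius = neuron_radius,
                 background_rank = as.integer(background_rank),
                 masks = masks, seed = as.integer(seed)),
            class = "online_params")
}

# Greedy graph coloring of the footprint overlap graph into groups of
# mutually non-overlapping components (any valid partition is acceptable).
determine_groups <- function(A) {
  K <- ncol(A)
  if (K == 0L) return(list())
  adj <- as.matrix(crossprod(A)) > 0
  diag(adj) <- FALSE
  color <- integer(K)
  for (i in seq_len(K)) {
    used <- unique(color[which(adj[i, ] & color > 0L)])
    color[i] <- min(setdiff(seq_len(K), used))
  }
  lapply(seq_len(max(color)), function(g) which(color == g))
}

# Trace history matrices are preallocated and grown geometrically; th
# counts the filled columns.
grow_history <- function(M, extra_rows = 0L) {
  out <- matrix(0, nrow(M) + extra_rows, max(2L * ncol(M), 64L))
  if (nrow(M) > 0L && ncol(M) > 0L) out[seq_len(nrow(M)), seq_len(ncol(M))] <- M
  out
}

#' Initialize the online state from a movie prefix
#'
#' Bare mode extracts a small number of components plus the background from
#' the prefix; batch mode runs the full batch pipeline on it; seeded mode
#' uses the provided masks. Sufficient statistics, the non-overlapping
#' component groups, the residual buffer and the shape-update counters are
#' then initialized.
#'
#' @param mov a \code{movie} (the full movie; only the first
#'   \code{init_frames} frames are touched).
#' @param params an \code{\link{online_params}}.
#' @return an object of class \code{online_state}.
#' @export
initialize_online <- function(mov, params = online_params()) {
  tp <- params$init_frames
  stopifnot(tp <= ncol(mov$data))
  lb <- params$buffer_frames
  if (is.null(lb)) lb <- max(100L, ceiling(3.3 * mov$frame_rate))
  if (lb > tp) stop("initialization prefix shorter than the residual buffer")
  prefix <- movie(mov$data[, seq_len(tp), drop = FALSE], mov$fov_dims,
                  mov$frame_rate)
  if (params$init_mode == "bare") {
    init <- greedy_roi(prefix, init_params(
      n_components = params$init_components,
      gaussian_width = params$neuron_radius,
      background_rank = params$background_rank))
    A <- init$footprints; C <- init$traces
    bf <- nmf_hals(prefix$data - A %*% C, params$background_rank,
                   seed = params$seed)
    ref <- hals_refine(prefix, component_set(A, C),
                       background_model("low_rank", spatial = bf$W,
                                        temporal = bf$H),
                       iterations = 3L)
    A <- ref$components$footprints; C <- ref$components$traces
    b <- ref$background$spatial; f <- ref$background$temporal
  } else if (params$init_mode == "batch") {
    res <- run_batch(prefix, batch_params(
      patch_size = pmin(mov$fov_dims, 48L),
      background_rank = params$background_rank,
      init = init_params(gaussian_width = params$neuron_radius),
      seed = params$seed), deconvolve = FALSE)
    A <- res$components$footprints; C <- res$components$traces
    b <- res$background$spatial; f <- res$background$temporal
  } else {
    stopifnot(!is.null(params$masks))
    res <- seeded_initialization(prefix, params$masks,
                                 params$background_rank)
    A <- res$footprints; C <- res$traces
    b <- res$background$spatial; f <- res$background$temporal
  }
  K <- ncol(A)
  Cf <- rbind(C, f)
  stat_yc <- prefix$data %*% t(Cf) / tp
  stat_cc <- tcrossprod(Cf) / tp
  Rbuf <- prefix$data[, (tp - lb + 1L):tp, drop = FALSE] -
    cbind(A, b) %*% Cf[, (tp - lb + 1L):tp, drop = FALSE]
  structure(list(
    A = A, b = b, C = C, f = f, S = matrix(0, K, tp), th = tp,
    stat_yc = stat_yc, stat_cc = stat_cc,
    groups = determine_groups(A), Rbuf = Rbuf,
    q = init_update_counter(K), t = tp, lb = lb,
    fov_dims = mov$fov_dims, frame_rate = mov$frame_rate,
    params = params, detect_log = list(),
    classifier_model = NULL,
    energy = rowSums(pmax(Rbuf, 0)^2)), class = "online_state")
}

# Counters logarithmically spaced in (1, 2], halved once per T_u frames; a
# component is updated when its counter drops to <= 1.
init_update_counter <- function(K) {
  if (K == 0L) return(numeric(0))
  2^(seq_len(K) / K)
}

#' Shape-update schedule
#'
#' Decays every component's counter by 0.5^(1/T_u) per frame. With no new
#' components this frame, all components whose counter dropped to <= 1 are
#' scheduled and their counters incremented by one; when components were
#' just added, nothing is scheduled and the counters of components
#' overlapping a new one are zeroed so they are updated at the next frame.
#'
#' @param q counter vector (one per component).
#' @param A d x K footprint matrix (for the overlap search).
#' @param newly_added indices J of components added this frame.
#' @param T_u update period.
#' @return list with \code{update} (indices I_u) and \code{q} (new
#'   counters).
#' @export
shape_update_schedule <- function(q, A, newly_added = integer(0), T_u = 200L) {
  q <- q * 0.5^(1 / T_u)
  if (length(newly_added) == 0L) {
    I_u <- which(q <= 1)
    q[I_u] <- q[I_u] + 1
  } else {
    I_u <- integer(0)
    if (ncol(A) > 0L) {
      ov <- rep(FALSE, ncol(A))
      for (j in newly_added) {
        ov <- ov | as.numeric(crossprod(A, A[, j])) > 0
      }
      ov[newly_added] <- TRUE
      q[ov] <- 0
    }
  }
  list(update = I_u, q = q)
}

#' Update footprints from the sufficient statistics
#'
#' Applies the dictionary-learning normal-equation step
#' a_i <- max(a_i + (stat_yc[, i] - [A, b] stat_cc[, i]) / stat_cc[i, i], 0)
#' restricted to the one-pixel-dilated support, for the scheduled indices
#' only. Indices beyond K address the background columns (whose support is
#' unconstrained).
#'
#' @param state an \code{online_state}.
#' @param indices component indices I_u to update.
#' @return the state with updated footprints.
#' @export
update_shapes <- function(state, indices) {
  if (length(indices) == 0L) return(state)
  Ab <- cbind(state$A, state$b)
  K <- ncol(state$A)
  rows <- state$fov_dims[1]; cols <- state$fov_dims[2]
  for (i in indices) {
    denom <- state$stat_cc[i, i]
    if (denom <= 0) {
      warning("update_shapes: component ", i, " never active; skipped")
      next
    }
    step <- (state$stat_yc[, i] - Ab %*% state$stat_cc[, i]) / denom
    new <- pmax(Ab[, i] + as.numeric(step), 0)
    if (i <= K) {
      supp <- dilate_support(Ab[, i] > 0, rows, cols)
      new[!supp] <- 0
      state$A[, i] <- new
    } else {
      state$b[, i - K] <- new
    }
    Ab[, i] <- new
  }
  state
}

#' Detect new components in the residual buffer
#'
#' Builds the buffer energy image (summed squared positive residuals),
#' enhances its contrast by subtracting a Gaussian blur at twice the neuron
#' radius, and proposes up to N_comp local maxima at pairwise distance of
#' at least 2r. Each proposal is screened by the footprint classifier on
#' the mean positive residual crop, by the peak-SNR of its buffer trace,
#' and against re-detection of an existing component (footprint cosine
#' similarity). Accepted proposals are fit by a local rank-1 factorization
#' of the buffer.
#'
#' @param Rbuf d x l_b residual buffer.
#' @param fov_dims (rows, cols).
#' @param n_candidates maximum proposals (N_comp).
#' @param neuron_radius expected radius r in pixels.
#' @param classifier classifier model or NULL for the geometric scorer.
#' @param classifier_threshold acceptance score.
#' @param snr_threshold minimum buffer-trace peak-SNR (candidates whose
#'   noise level cannot be estimated are rejected).
#' @param frame_rate frames per second (for the SNR window).
#' @param energy optional precomputed energy image vector.
#' @param existing_footprints optional d x K matrix of current footprints;
#'   candidates too similar to one of them are discarded.
#' @param max_overlap_cos cosine similarity bound for the re-detection
#'   guard.
#' @return list with \code{footprints} (d x K_new), \code{traces}
#'   (K_new x l_b) and \code{centers}.
#' @export
find_new_components <- function(Rbuf, fov_dims, n_candidates = 5L,
                                neuron_radius = 3, classifier = NULL,
                                classifier_threshold = 0.5,
                                snr_threshold = 1.5, frame_rate = 30,
                                energy = NULL, existing_footprints = NULL,
                                max_overlap_cos = 0.5) {
  rows <- fov_dims[1]; cols <- fov_dims[2]
  d <- rows * cols
  if (is.null(energy)) energy <- rowSums(pmax(Rbuf, 0)^2)
  E <- gauss_blur(matrix(energy, rows, cols, byrow = TRUE), 1)
  Ehp <- E - gauss_blur(E, 2 * neuron_radius)
  # a fresh transient stands 8+ robust sigmas above the high-passed energy
  # noise floor; noise-only buffers peak near 3.5
  sig_E <- 1.4826 * stats::mad(Ehp)
  r <- max(1L, round(neuron_radius))
  peaks <- local_maxima(Ehp, half_width = 2L * r, n_max = n_candidates,
                        threshold = 4 * sig_E)
  keepA <- list(); keepC <- list(); centers <- NULL
  if (nrow(peaks) > 0L) {
    mean_pos <- matrix(rowMeans(pmax(Rbuf, 0)), rows, cols, byrow = TRUE)
    h <- 2L * r        # fit window covers the full footprint extent
    for (k in seq_len(nrow(peaks))) {
      ctr <- c(peaks[k, 1], peaks[k, 2])
      pix <- square_window(ctr, h, rows, cols)
      rr <- (ctr[1] - h):(ctr[1] + h); cc <- (ctr[2] - h):(ctr[2] + h)
      okr <- rr >= 1L & rr <= rows; okc <- cc >= 1L & cc <= cols
      mean_crop <- matrix(0, length(rr), length(cc))
      mean_crop[which(okr), which(okc)] <- mean_pos[rr[okr], cc[okc]]
      if (max(mean_crop) > 0) mean_crop <- mean_crop / max(mean_crop)
      score <- classify_footprints(list(mean_crop), model = classifier)
      if (score < classifier_threshold) next
      fit <- local_rank1(Rbuf, pix)
      if (sum(fit$c) == 0 || sum(fit$a) == 0) next
      snr <- tryCatch(
        peak_snr(fit$c, frame_rate = frame_rate,
                 baseline = stats::median(fit$c)),
        error = function(e) 0)     # unestimable noise: reject
      if (snr < snr_threshold) next
      if (!is.null(existing_footprints) && ncol(existing_footprints) > 0L) {
        sim <- as.numeric(crossprod(existing_footprints[pix, , drop = FALSE],
                                    fit$a))
        nrm <- sqrt(colSums(existing_footprints^2))
        if (max(sim / pmax(nrm, 1e-12)) > max_overlap_cos) next
      }
      a_full <- numeric(d)
      a_full[pix] <- fit$a
      keepA[[length(keepA) + 1L]] <- a_full
      keepC[[length(keepC) + 1L]] <- fit$c
      centers <- rbind(centers, ctr)
    }
  }
  if (length(keepA) == 0L) {
    return(list(footprints = matrix(0, d, 0L),
                traces = matrix(0, 0L, ncol(Rbuf)), centers = NULL))
  }
  list(footprints = do.call(cbind, keepA),
       traces = do.call(rbind, keepC), centers = centers)
}

#' Process one frame of the stream
#'
#' Updates the traces by block coordinate descent over the non-overlapping
#' groups, searches the residual buffer for new components and integrates
#' them (zero past trace, expanded statistics, repartitioned groups), rolls
#' the residual buffer, applies the rank-one sufficient-statistic update,
#' and runs the scheduled shape updates (background shapes are refreshed
#' alongside every scheduled update).
#'
#' @param state an \code{online_state}.
#' @param y length-d frame vector (row-major pixels).
#' @param detect enable new-component detection for this frame.
#' @return the updated state.
#' @export
process_frame <- function(state, y, detect = TRUE) {
  if (any(!is.finite(y))) stop("non-finite values in frame")
  p <- state$params
  K <- ncol(state$A)
  nb <- ncol(state$b)
  Ab <- cbind(state$A, state$b)
  M <- K + nb
  prev <- c(if (K > 0L) state$C[, state$th] else numeric(0),
            if (nb > 0L) state$f[, state$th] else numeric(0))
  ct <- prev
  if (M > 0L) {
    nrm2 <- colSums(Ab^2)
    Aty <- as.numeric(crossprod(Ab, y))
    AtA <- crossprod(Ab)
    groups <- c(state$groups, if (nb > 0L) list(K + seq_len(nb)) else NULL)
    for (pass in 1:3) {
      for (g in groups) {
        resid_coef <- Aty[g] - as.numeric(AtA[g, , drop = FALSE] %*% ct)
        ct[g] <- pmax(ct[g] + resid_coef / pmax(nrm2[g], 1e-12), 0)
      }
    }
  }
  # detection on the current residual buffer
  added <- integer(0)
  if (detect && p$candidates_per_frame > 0L && ncol(state$Rbuf) >= state$lb) {
    found <- find_new_components(
      state$Rbuf, state$fov_dims, p$candidates_per_frame, p$neuron_radius,
      classifier = state$classifier_model,
      classifier_threshold = p$classifier_threshold,
      snr_threshold = p$snr_threshold, frame_rate = state$frame_rate,
      energy = state$energy, existing_footprints = state$A,
      max_overlap_cos = p$max_overlap_cos)
    Knew <- ncol(found$footprints)
    if (Knew > 0L) {
      lb <- ncol(state$Rbuf)
      # past activity before detection is unknown and defaults to zero;
      # the buffer interval just fit is kept
      C_new <- matrix(0, Knew, ncol(state$C))
      C_new[, (state$th - lb + 1L):state$th] <- found$traces
      state$C <- rbind(state$C, C_new)
      state$S <- rbind(state$S, matrix(0, Knew, ncol(state$S)))
      state$A <- cbind(state$A, found$footprints)
      ct <- c(ct[seq_len(K)], found$traces[, lb], ct[K + seq_len(nb)])
      state <- expand_stats(state, Knew)
      state$Rbuf <- state$Rbuf - found$footprints %*% found$traces
      state$energy <- rowSums(pmax(state$Rbuf, 0)^2)
      K_old <- K
      K <- ncol(state$A)
      added <- (K_old + 1L):K
      state$groups <- determine_groups(state$A)
      state$q <- c(state$q, rep(2, Knew))
      Ab <- cbind(state$A, state$b)
      M <- K + nb
      state$detect_log[[length(state$detect_log) + 1L]] <-
        list(t = state$t + 1L, centers = found$centers)
    }
  }
  # commit traces for this frame (histories grow geometrically)
  if (state$th + 1L > ncol(state$C)) {
    state$C <- grow_history(state$C)
    state$f <- grow_history(state$f)
    state$S <- grow_history(state$S)
  }
  state$th <- state$th + 1L
  if (K > 0L) state$C[, state$th] <- ct[seq_len(K)]
  if (nb > 0L) state$f[, state$th] <- ct[K + seq_len(nb)]
  # roll the residual buffer with this frame's residual
  rnew <- y - as.numeric(Ab %*% ct)
  drop_col <- state$Rbuf[, 1]
  state$energy <- state$energy - pmax(drop_col, 0)^2 + pmax(rnew, 0)^2
  state$Rbuf <- cbind(state$Rbuf[, -1, drop = FALSE], rnew)
  # rank-one sufficient statistics update
  t_new <- state$t + 1L
  state$stat_yc <- (state$stat_yc * state$t + y %*% t(ct)) / t_new
  state$stat_cc <- (state$stat_cc * state$t + ct %*% t(ct)) / t_new
  state$t <- t_new
  # shape-update schedule; background shapes ride along with every update
  sched <- shape_update_schedule(state$q, state$A, added,
                                 p$shape_update_period)
  state$q <- sched$q
  if (length(sched$update) > 0L && nb > 0L) {
    state <- update_shapes(state, c(sched$update, K + seq_len(nb)))
  } else {
    state <- update_shapes(state, sched$update)
  }
  state
}

# Expand stat_yc / stat_cc with zero rows and columns for Knew components
# appended at the end of A (new components enter with zero past trace).
expand_stats <- function(state, Knew) {
  K <- ncol(state$A)
  nb <- ncol(state$b)
  old_order <- c(seq_len(K - Knew), K + seq_len(nb))
  stat_yc <- matrix(0, nrow(state$A), K + nb)
  stat_cc <- matrix(0, K + nb, K + nb)
  stat_yc[, old_order] <- state$stat_yc
  stat_cc[old_order, old_order] <- state$stat_cc
  state$stat_yc <- stat_yc
  state$stat_cc <- stat_cc
  state
}

#' Run the streaming pipeline over a movie
#'
#' Initializes on the movie prefix, then processes every remaining frame in
#' order for the requested number of epochs (later epochs replay all frames
#' with detection still enabled, back-filling traces of components found
#' late). Components that never carried activity after their insertion are
#' dropped at the end.
#'
#' @param mov a \code{movie} (or path to a TIFF / ".pmap" file).
#' @param params an \code{\link{online_params}}.
#' @param classifier optional footprint classifier used for candidate
#'   screening.
#' @param final_thresholds a \code{\link{quality_thresholds}} applied to
#'   the finished component set (NULL skips the final screen).
#' @return list with \code{components} (\code{\link{component_set}}),
#'   \code{background} (low-rank \code{\link{background_model}}),
#'   \code{quality} (final quality report, if screened), \code{state}
#'   (final \code{online_state}) and \code{timing} (per-stage seconds).
#' @export
run_online <- function(mov, params = online_params(), classifier = NULL,
                       final_thresholds = quality_thresholds()) {
  if (is.character(mov)) {
    mov <- if (grepl("\\.pmap$", mov)) memmap_to_movie(open_memmap(mov))
           else read_movie_tiff(mov)
  }
  t0 <- proc.time()[3]
  state <- initialize_online(mov, params)
  state$classifier_model <- classifier
  t_init <- proc.time()[3] - t0
  Tt <- ncol(mov$data)
  t_stream <- 0
  for (ep in seq_len(params$epochs)) {
    from <- if (ep == 1L) params$init_frames + 1L else 1L
    if (from > Tt) next
    t1 <- proc.time()[3]
    for (tt in from:Tt) {
      state <- process_frame(state, mov$data[, tt])
    }
    t_stream <- t_stream + (proc.time()[3] - t1)
  }
  # final traces: non-negative regression of the whole movie on [A, b]
  A <- state$A; b <- state$b
  active <- which(diag(state$stat_cc)[seq_len(ncol(A))] > 0)
  A <- A[, active, drop = FALSE]
  K <- ncol(A)
  if (K > 0L) {
    Cfin <- nnls_traces(cbind(A, b), mov$data, passes = 8)
    bg_f <- Cfin[K + seq_len(ncol(b)), , drop = FALSE]
    comps <- component_set(A, Cfin[seq_len(K), , drop = FALSE])
  } else {
    bg_f <- nnls_traces(b, mov$data, passes = 8)
    comps <- component_set(matrix(0, nrow(mov$data), 0L), matrix(0, 0L, Tt))
  }
  bg <- background_model("low_rank", spatial = b, temporal = bg_f)
  rep <- NULL
  if (!is.null(final_thresholds) && ncol(comps$footprints) > 0L) {
    A_thr <- threshold_footprints(comps$footprints, mov$fov_dims)
    ok <- colSums(A_thr) > 0
    comps <- component_set(A_thr[, ok, drop = FALSE],
                           comps$traces[ok, , drop = FALSE])
    rep <- evaluate_components(mov, comps, bg, final_thresholds)
    keep <- which(rep$accepted)
    comps <- component_set(comps$footprints[, keep, drop = FALSE],
                           comps$traces[keep, , drop = FALSE])
    if (length(keep) > 1L) {
      kept <- detect_duplicates(comps, rep$classifier_score[keep],
                                overlap_dup = final_thresholds$overlap_dup)
      comps <- component_set(comps$footprints[, kept, drop = FALSE],
                             comps$traces[kept, , drop = FALSE])
    }
  }
  list(components = comps, background = bg, quality = rep,
       state = state,
       timing = c(init = t_init, stream = t_stream))
}
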