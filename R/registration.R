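# Component registration across sessions: footprint binarization, modified
# Jaccard distance with a containment rule, optimal matching by the
# Hungarian algorithm, chronological union tracking, and a transitivity
# diagnostic.

#' Registration parameters
#'
#' @param binarize_threshold theta_b in (0, 1): mask = footprint >=
#'   theta_b * max (default 0.2).
#' @param match_threshold theta_d in (0, 1]: pairs with Jaccard distance
#'   above it are non-matching (distance infinity; default 0.5).
#' @param alignment "none" or "rigid" (integer-pixel translation by
#'   template cross-correlation).
#' @return an object of class \code{reg_params}.
#' @export
reg_params <- function(binarize_threshold = 0.2, match_threshold = 0.5,
                       alignment = c("none", "rigid")) {
  alignment <- match.arg(alignment)
  stopifnot(binarize_threshold > 0, binarize_threshold < 1,
            match_threshold > 0, match_threshold <= 1)
  structure(list(binarize_threshold = binarize_threshold,
                 match_threshold = match_threshold, alignment = alignment),
            class = "reg_params")
}

#' Binarize a footprint
#'
#' @param a non-negative footprint vector (not all zero).
#' @param threshold theta_b; mask pixels satisfy a >= threshold * max(a).
#' @return logical vector.
#' @export
binarize_footprint <- function(a, threshold = 0.2) {
  mx <- max(a)
  if (mx <= 0) stop("cannot binarize an all-zero footprint")
  a >= threshold * mx
}

#' Modified Jaccard distance between two footprints
#'
#' Distance 1 - J on the binarized masks when that is at most theta_d;
#' 0 when one mask contains the other (even if 1 - J exceeds theta_d);
#' infinity otherwise.
#'
#' @param a1,a2 footprint vectors on the same pixel grid.
#' @param binarize_threshold theta_b.
#' @param match_threshold theta_d.
#' @return distance in [0, 1] or \code{Inf}.
#' @export
pair_distance <- function(a1, a2, binarize_threshold = 0.2,
                          match_threshold = 0.5) {
  m1 <- binarize_footprint(a1, binarize_threshold)
  m2 <- binarize_footprint(a2, binarize_threshold)
  inter <- sum(m1 & m2)
  uni <- sum(m1 | m2)
  if (inter == sum(m1) || inter == sum(m2)) return(0)  # containment
  dist <- 1 - inter / uni
  if (dist <= match_threshold) dist else Inf
}

# Pairwise distance matrix between footprint sets (columns), with Inf for
# non-matching pairs. Masks are precomputed for speed.
distance_matrix <- function(A1, A2, binarize_threshold, match_threshold) {
  mk <- function(A) {
    mx <- apply(A, 2L, max)
    if (any(mx <= 0)) stop("cannot binarize an all-zero footprint")
    A >= matrix(binarize_threshold * mx, nrow(A), ncol(A), byrow = TRUE)
  }
  M1 <- mk(A1) * 1; M2 <- mk(A2) * 1
  inter <- crossprod(M1, M2)
  s1 <- colSums(M1); s2 <- colSums(M2)
  uni <- outer(s1, s2, "+") - inter
  D <- 1 - inter / uni
  D[D > match_threshold] <- Inf
  contain <- inter == matrix(s1, length(s1), length(s2)) |
    inter == matrix(s2, length(s1), length(s2), byrow = TRUE)
  D[contain & inter > 0] <- 0
  D
}

# Integer-pixel rigid shift estimated by the cross-correlation peak of two
# templates; returns c(dy, dx) such that shifting img1 by it aligns to img2.
estimate_shift <- function(img1, img2, max_shift = NULL) {
  rows <- nrow(img1); cols <- ncol(img1)
  if (is.null(max_shift)) max_shift <- floor(min(rows, cols) / 4)
  best <- c(0L, 0L); best_v <- -Inf
  z1 <- img1 - mean(img1); z2 <- img2 - mean(img2)
  for (dy in -max_shift:max_shift) for (dx in -max_shift:max_shift) {
    r1 <- max(1, 1 + dy):min(rows, rows + dy)
    c1 <- max(1, 1 + dx):min(cols, cols + dx)
    r0 <- r1 - dy; c0 <- c1 - dx
    v <- sum(z1[r0, c0] * z2[r1, c1])
    if (v > best_v) { best_v <- v; best <- c(dy, dx) }
  }
  best
}

# Shift footprint columns rigidly by (dy, dx); pixels leaving the FOV drop.
shift_footprints <- function(A, shift, rows, cols) {
  if (all(shift == 0L)) return(A)
  out <- matrix(0, nrow(A), ncol(A))
  src <- matrix(A, nrow = rows * cols)
  rr <- seq_len(rows); cc <- seq_len(cols)
  r_t <- rr + shift[1]; c_t <- cc + shift[2]
  okr <- r_t >= 1 & r_t <= rows; okc <- c_t >= 1 & c_t <= cols
  for (j in seq_len(ncol(A))) {
    img <- matrix(A[, j], rows, cols, byrow = TRUE)
    tgt <- matrix(0, rows, cols)
    tgt[r_t[okr], c_t[okc]] <- img[rr[okr], cc[okc]]
    out[, j] <- as.vector(t(tgt))
  }
  out
}

# Optimal assignment on a rectangular matrix with Inf entries: pad to
# square with a finite big-M, solve with the Hungarian method, drop pairs
# assigned at infinite cost.
assign_hungarian <- function(D) {
  n1 <- nrow(D); n2 <- ncol(D)
  if (n1 == 0L || n2 == 0L) return(cbind(integer(0), integer(0)))
  n <- max(n1, n2)
  finite <- D[is.finite(D)]
  bigM <- if (length(finite) > 0) max(finite) * n + 10 else 10
  Dp <- matrix(bigM, n, n)
  Dp[seq_len(n1), seq_len(n2)] <- pmin(D, bigM)
  sol <- clue::solve_LSAP(Dp)
  pairs <- cbind(seq_len(n), as.integer(sol))
  pairs <- pairs[pairs[, 1] <= n1 & pairs[, 2] <= n2, , drop = FALSE]
  keep <- is.finite(D[pairs])
  pairs[keep, , drop = FALSE]
}

#' Register two sessions of components
#'
#' Optionally aligns session 1 onto session 2's template by an integer
#' rigid shift, builds the modified Jaccard distance matrix, and matches
#' components optimally by the Hungarian algorithm; pairs at infinite
#' distance are never matched.
#'
#' @param A1,A2 d x N_i footprint matrices.
#' @param template1,template2 summary images used for alignment (required
#'   for rigid alignment).
#' @param params a \code{\link{reg_params}}.
#' @param fov_dims (rows, cols); required for rigid alignment.
#' @return list with \code{matched_pairs} (m x 2 index matrix),
#'   \code{unmatched_1}, \code{unmatched_2}, \code{distances} (per matched
#'   pair), \code{distance_matrix}, \code{shift}, and the aligned \code{A1}.
#' @export
register_pair <- function(A1, A2, template1 = NULL, template2 = NULL,
                          params = reg_params(), fov_dims = NULL) {
  shift <- c(0L, 0L)
  if (params$alignment == "rigid") {
    stopifnot(!is.null(template1), !is.null(template2), !is.null(fov_dims))
    shift <- estimate_shift(template1, template2)
    A1 <- shift_footprints(A1, shift, fov_dims[1], fov_dims[2])
    # components shifted fully out of the FOV keep zero columns and are
    # treated as unmatchable below
  }
  n1 <- ncol(A1); n2 <- ncol(A2)
  if (n1 == 0L || n2 == 0L) {
    return(list(matched_pairs = cbind(integer(0), integer(0)),
                unmatched_1 = seq_len(n1), unmatched_2 = seq_len(n2),
                distances = numeric(0),
                distance_matrix = matrix(Inf, n1, n2),
                shift = shift, A1_aligned = A1))
  }
  ok1 <- colSums(A1) > 0
  D <- matrix(Inf, n1, n2)
  if (any(ok1)) {
    D[ok1, ] <- distance_matrix(A1[, ok1, drop = FALSE], A2,
                                params$binarize_threshold,
                                params$match_threshold)
  }
  pairs <- assign_hungarian(D)
  list(matched_pairs = pairs,
       unmatched_1 = setdiff(seq_len(n1), pairs[, 1]),
       unmatched_2 = setdiff(seq_len(n2), pairs[, 2]),
       distances = D[pairs],
       distance_matrix = D, shift = shift, A1_aligned = A1)
}

#' Register components across multiple sessions
#'
#' Chronologically registers each session against the running union of all
#' distinct components: matched union members are replaced by the newer
#' footprints, unmatched new components are appended, and a matching list
#' maps every session component to its union index.
#'
#' @param sessions list of lists with \code{footprints} and optional
#'   \code{template}.
#' @param params a \code{\link{reg_params}}.
#' @param fov_dims (rows, cols) for rigid alignment.
#' @return list with \code{union_footprints} (d x K_tot), \code{matchings}
#'   (per session, session index -> union index), and \code{K_tot}.
#' @export
register_multi <- function(sessions, params = reg_params(),
                           fov_dims = NULL) {
  stopifnot(length(sessions) >= 2L)
  Au <- sessions[[1]]$footprints
  templ_u <- sessions[[1]]$template
  K1 <- ncol(Au)
  matchings <- list(seq_len(K1))
  K_tot <- K1
  for (i in 2:length(sessions)) {
    Ai <- sessions[[i]]$footprints
    res <- register_pair(Au, Ai, templ_u, sessions[[i]]$template,
                         params, fov_dims)
    Au <- res$A1_aligned
    m_i <- integer(ncol(Ai))
    if (nrow(res$matched_pairs) > 0L) {
      Au[, res$matched_pairs[, 1]] <- Ai[, res$matched_pairs[, 2]]
      m_i[res$matched_pairs[, 2]] <- res$matched_pairs[, 1]
    }
    if (length(res$unmatched_2) > 0L) {
      Au <- cbind(Au, Ai[, res$unmatched_2, drop = FALSE])
      m_i[res$unmatched_2] <- K_tot + seq_along(res$unmatched_2)
      K_tot <- K_tot + length(res$unmatched_2)
    }
    matchings[[i]] <- m_i
    templ_u <- sessions[[i]]$template
  }
  list(union_footprints = Au, matchings = matchings, K_tot = K_tot)
}

#' Transitivity of pairwise registrations across three sessions
#'
#' Over components matched in sessions 1 -> 2 and 2 -> 3, the fraction
#' whose direct 1 -> 3 match agrees with the composition of the two.
#'
#' @param A1,A2,A3 footprint matrices.
#' @param templates optional list of three templates.
#' @param params a \code{\link{reg_params}}.
#' @param fov_dims (rows, cols).
#' @return fraction in [0, 1], or NA when no chains are composable.
#' @export
transitivity_index <- function(A1, A2, A3, templates = NULL,
                               params = reg_params(), fov_dims = NULL) {
  tpl <- function(i) if (is.null(templates)) NULL else templates[[i]]
  r12 <- register_pair(A1, A2, tpl(1), tpl(2), params, fov_dims)
  r23 <- register_pair(A2, A3, tpl(2), tpl(3), params, fov_dims)
  r13 <- register_pair(A1, A3, tpl(1), tpl(3), params, fov_dims)
  m12 <- r12$matched_pairs; m23 <- r23$matched_pairs
  m13 <- r13$matched_pairs
  map12 <- stats::setNames(m12[, 2], m12[, 1])
  map23 <- stats::setNames(m23[, 2], m23[, 1])
  map13 <- stats::setNames(m13[, 2], m13[, 1])
  chains <- m12[as.character(m12[, 2]) %in% names(map23), 1, drop = TRUE]
  if (length(chains) == 0L) return(NA_real_)
  agree <- vapply(chains, function(i) {
    k_comp <- map23[[as.character(map12[[as.character(i)]])]]
    k_direct <- if (as.character(i) %in% names(map13))
      map13[[as.character(i)]] else NA_integer_
    isTRUE(k_comp == k_direct)
  }, logical(1))
  mean(agree)
}
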