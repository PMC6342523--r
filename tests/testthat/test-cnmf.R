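test_that("patch layouts tile the FOV with the stated starts and coverage", {
  one <- construct_patches(c(64L, 64L), c(64L, 64L), 8L)
  expect_equal(length(one$patches), 1L)
  expect_true(all(one$coverage == 1L))
  lay <- construct_patches(c(64L, 64L), c(40L, 40L), 8L)
  starts <- sort(unique(vapply(lay$patches, function(p) p$rows[1], integer(1))))
  expect_equal(starts, c(1L, 33L))       # 0-based {0, 32}
  expect_equal(length(lay$patches), 4L)
  # interior seam pixels are covered exactly twice
  expect_equal(lay$coverage[35, 10], 2L)
  expect_true(all(lay$coverage >= 1L))
  expect_error(construct_patches(c(64L, 64L), c(40L, 40L), 40L), "overlap")
  expect_error(construct_patches(c(32L, 32L), c(40L, 40L), 0L), "exceeds")
})

test_that("merging collapses duplicates exactly and spares uncorrelated pairs", {
  d <- 100L; Tt <- 80L
  a <- numeric(d); a[c(22, 23, 32, 33)] <- 0.5
  tr <- ar1_trace(rbinom(Tt, 1, 0.1), 0.8) + 0.1
  # two half-amplitude copies of one rank-1 component
  comps <- component_set(cbind(a, a), rbind(tr / 2, tr / 2))
  merged <- merge_components(comps, 0.8)
  expect_equal(ncol(merged$footprints), 1L)
  recon <- merged$footprints %*% merged$traces
  want <- a %*% t(tr)
  expect_lt(sqrt(sum((recon - want)^2)) / sqrt(sum(want^2)), 1e-6)
  # overlapping but temporally uncorrelated: kept apart
  set.seed(71)
  tr2 <- ar1_trace(rbinom(Tt, 1, 0.1), 0.8)
  while (abs(cor(tr, tr2)) > 0.3) tr2 <- ar1_trace(rbinom(Tt, 1, 0.1), 0.8)
  comps2 <- component_set(cbind(a, a), rbind(tr, tr2))
  expect_equal(ncol(merge_components(comps2, 0.8)$footprints), 2L)
})

test_that("chained merge groups match a multi-start rank-1 oracle", {
  set.seed(72)
  d <- 64L; Tt <- 60L
  for (case in 1:5) {
    # three overlapping, correlated components forming a chain
    base <- ar1_trace(rbinom(Tt, 1, 0.15), 0.8) + 0.05
    A <- matrix(0, d, 3)
    A[1:12, 1] <- runif(12); A[9:20, 2] <- runif(12); A[17:28, 3] <- runif(12)
    A <- apply(A, 2, function(x) x / sqrt(sum(x^2)))
    C <- rbind(base * runif(1, 0.8, 1.2) + rnorm(Tt, sd = 0.02),
               base * runif(1, 0.8, 1.2) + rnorm(Tt, sd = 0.02),
               base * runif(1, 0.8, 1.2) + rnorm(Tt, sd = 0.02))
    C <- pmax(C, 0)
    merged <- merge_components(component_set(A, C), 0.8)
    expect_equal(ncol(merged$footprints), 1L)
    got_res <- sum((A %*% C - merged$footprints %*% merged$traces)^2)
    # multi-start alternating rank-1 oracle
    M <- A %*% C
    best <- Inf
    for (s in 1:20) {
      a0 <- runif(d)
      for (it in 1:200) {
        c0 <- pmax(as.numeric(crossprod(M, a0)) / sum(a0^2), 0)
        if (sum(c0^2) == 0) break
        a0 <- pmax(as.numeric(M %*% c0) / sum(c0^2), 0)
      }
      best <- min(best, sum((M - a0 %*% t(c0))^2))
    }
    expect_lte(got_res, best * 1.01 + 1e-12)
  }
})

test_that("background merging embeds disjoint patch backgrounds exactly", {
  d <- 200L; Tt <- 40L
  b1 <- runif(80); f1 <- runif(Tt) + 0.5
  b2 <- runif(80); f2 <- runif(Tt) + 0.5
  pb <- list(list(spatial = matrix(b1, ncol = 1), temporal = matrix(f1, 1),
                  pixels = 1:80),
             list(spatial = matrix(b2, ncol = 1), temporal = matrix(f2, 1),
                  pixels = 101:180))
  bg <- merge_backgrounds(pb, d, rep(1, d), g_b = 1L, background_rank = 2L)
  B <- bg$spatial %*% bg$temporal
  want <- matrix(0, d, Tt)
  want[1:80, ] <- b1 %*% t(f1)
  want[101:180, ] <- b2 %*% t(f2)
  expect_lt(sqrt(sum((B - want)^2)) / sqrt(sum(want^2)), 1e-6)
  # zero backgrounds give a zero model
  none <- merge_backgrounds(list(), d, rep(1, d))
  expect_equal(ncol(none$spatial), 0L)
})

test_that("HALS refinement is monotone, fixed at the truth, and inert at 0 iterations", {
  g <- generate_movie(tiny_params(seed = 73L, noise_sigma = 0))
  comps <- component_set(g$truth$footprints, g$truth$traces)
  bg <- background_model("low_rank", spatial = g$truth$background_spatial,
                         temporal = g$truth$background_temporal)
  # noiseless truth is a fixed point: objective stays ~0
  ref <- hals_refine(g$movie, comps, bg, iterations = 3L)
  expect_lt(max(ref$objective), 1e-10 * sum(g$movie$data^2))
  expect_equal(ref$components$footprints, g$truth$footprints,
               tolerance = 1e-6)
  # zero iterations: inputs unchanged
  ref0 <- hals_refine(g$movie, comps, bg, iterations = 0L)
  expect_identical(ref0$components$footprints, comps$footprints)
  # perturbed truth: first iteration strictly decreases the objective
  pert <- comps
  set.seed(2)
  pert$traces <- pmax(pert$traces + matrix(rnorm(length(pert$traces), sd = 0.05),
                                           nrow(pert$traces)), 0)
  refp <- hals_refine(g$movie, pert, bg, iterations = 1L)
  expect_lt(refp$objective[2], refp$objective[1])
})

test_that("HALS objective is non-increasing on random synthetic movies", {
  for (s in 1:20) {
    g <- generate_movie(synth_params(fov_dims = c(16L, 16L), n_frames = 80L,
                                     n_neurons = 3L, gaussian_radius = 2,
                                     background_rank = 1L, seed = 100L + s))
    init <- greedy_roi(g$movie, init_params(n_components = 3L,
                                            gaussian_width = 2,
                                            background_rank = 1L))
    bf <- cnmfr:::nmf_hals(g$movie$data - init$footprints %*% init$traces,
                           1L, seed = s)
    ref <- hals_refine(g$movie, component_set(init$footprints, init$traces),
                       background_model("low_rank", spatial = bf$W,
                                        temporal = bf$H),
                       iterations = 20L)
    expect_true(all(diff(ref$objective) <= 1e-8 * ref$objective[1] + 1e-12))
    expect_true(all(ref$components$footprints >= 0))
    expect_true(all(ref$components$traces >= 0))
    expect_true(all(ref$background$spatial >= 0))
  }
})

test_that("ring background reconstructs a smooth static field and zeroes a zero movie", {
  rows <- 20L; cols <- 20L; Tt <- 60L
  surf <- cnmfr:::gauss_blur(matrix(runif(rows * cols), rows, cols), 4)
  Y <- as.vector(t(surf)) %*% t(rep(1, Tt)) +
    matrix(rnorm(rows * cols * Tt, sd = 1e-3), rows * cols, Tt)
  mov <- movie(Y, c(rows, cols))
  bg <- ring_background(mov, NULL, ring_radius = 4)
  rel <- sqrt(sum((bg$dense - Y)^2)) / sqrt(sum(Y^2))
  expect_lt(rel, 0.1)
  # ring weights confined to the annulus
  W <- as.matrix(bg$ring_weights)
  nz <- which(W != 0, arr.ind = TRUE)
  rc_i <- cnmfr:::pix_coords(nz[, 1], cols)
  rc_j <- cnmfr:::pix_coords(nz[, 2], cols)
  dist <- sqrt(rowSums((rc_i - rc_j)^2))
  expect_true(all(dist >= 4 - 1e-9 & dist < 5 + 1e-9))
  z <- ring_background(movie(matrix(0, rows * cols, 10L), c(rows, cols)),
                       NULL, ring_radius = 4)
  expect_equal(max(abs(z$dense)), 0)
  expect_error(ring_background(movie(matrix(1, 4L, 5L), c(2L, 2L)), NULL,
                               ring_radius = 10), "annulus")
})

test_that("ring plus trace refinement recovers neurons over a smooth background", {
  p <- synth_params(fov_dims = c(32L, 32L), n_frames = 300L, n_neurons = 3L,
                    gaussian_radius = 2.5, background_rank = 1L,
                    background_amplitude = 2, seed = 74L)
  g <- generate_movie(p)
  comps <- component_set(g$truth$footprints, g$truth$traces)
  bg <- ring_background(g$movie, comps, ring_radius = 5)
  C1 <- cnmfr:::nnls_traces(g$truth$footprints, g$movie$data - bg$dense,
                            C0 = g$truth$traces, passes = 5)
  for (i in 1:3) expect_gt(cor(C1[i, ], g$truth$traces[i, ]), 0.9)
})

test_that("patch processing matches whole-FOV processing for a single patch", {
  p <- synth_params(fov_dims = c(32L, 32L), n_frames = 300L, n_neurons = 5L,
                    gaussian_radius = 2.5, seed = 75L)
  g <- generate_movie(p)
  bp <- batch_params(patch_size = c(32L, 32L), components_per_patch = 6L,
                     init = init_params(gaussian_width = 2.5))
  lay <- construct_patches(c(32L, 32L), c(32L, 32L), 8L)
  via_patches <- process_in_patches(g$movie, lay, bp)
  direct <- cnmfr:::cnmf_single(g$movie, bp)
  expect_equal(via_patches$components$footprints,
               direct$components$footprints, tolerance = 1e-8)
  # patch execution order does not change the result
  lay2 <- construct_patches(c(32L, 32L), c(24L, 24L), 6L)
  r12 <- process_in_patches(g$movie, lay2, bp)
  r21 <- process_in_patches(g$movie, lay2, bp,
                            patch_order = rev(seq_along(lay2$patches)))
  expect_equal(r12$components$footprints, r21$components$footprints)
  expect_equal(r12$components$traces, r21$components$traces)
})

test_that("a neuron on a patch seam comes out once with a faithful footprint", {
  # place one neuron straddling the seam of a 2-patch layout
  rows <- 24L; cols <- 48L; Tt <- 300L
  set.seed(76)
  a <- cnmfr:::gaussian_footprint(c(12, 24), rows, cols, 2.5)
  tr <- ar1_trace(rbinom(Tt, 1, 0.03), 0.9)
  Y <- a %*% t(tr) + matrix(rnorm(rows * cols * Tt, sd = 0.02),
                            rows * cols, Tt)
  mov <- movie(Y, c(rows, cols), frame_rate = 30)
  bp <- batch_params(patch_size = c(24L, 28L), overlap = 8L,
                     components_per_patch = 1L, background_rank = 0L,
                     init = init_params(gaussian_width = 2.5,
                                        background_rank = 0L))
  lay <- construct_patches(c(rows, cols), bp$patch_size, bp$overlap)
  res <- process_in_patches(mov, lay, bp)
  expect_equal(ncol(res$components$footprints), 1L)
  cs <- sum(res$components$footprints[, 1] * a) /
    sqrt(sum(res$components$footprints[, 1]^2))
  expect_gte(cs, 0.95)
})

test_that("run_batch is reproducible and returns nothing on background-only movies", {
  p <- synth_params(fov_dims = c(32L, 32L), n_frames = 200L, n_neurons = 0L,
                    seed = 77L)
  g <- generate_movie(p)
  bp <- batch_params(patch_size = c(32L, 32L), components_per_patch = 3L,
                     thresholds = quality_thresholds(
                       classifier_reject_floor = 0.2, spike_snr_test = TRUE))
  hits <- 0L
  for (s in 1:5) {
    gs <- generate_movie(synth_params(fov_dims = c(32L, 32L),
                                      n_frames = 200L, n_neurons = 0L,
                                      seed = 200L + s))
    res <- suppressWarnings(run_batch(gs$movie, bp))
    hits <- hits + (ncol(res$components$footprints) > 0L)
  }
  expect_lte(hits, 1L)
  # reproducibility on a real movie
  g2 <- generate_movie(tiny_params(seed = 78L))
  bp2 <- batch_params(patch_size = c(24L, 24L), components_per_patch = 5L,
                      init = init_params(gaussian_width = 2.5))
  r1 <- run_batch(g2$movie, bp2)
  r2 <- run_batch(g2$movie, bp2)
  expect_identical(r1$components$footprints, r2$components$footprints)
  expect_identical(r1$components$deconvolved, r2$components$deconvolved)
})

test_that("footprint thresholding keeps the energy core connected component", {
  rows <- 10L; cols <- 10L
  a <- cnmfr:::gaussian_footprint(c(5, 5), rows, cols, 1.5)
  noisy <- a
  noisy[c(1, 100)] <- 0.01 * max(a)      # stray shell pixels
  thr <- threshold_footprints(cbind(noisy), c(rows, cols), 0.99)
  expect_equal(unname(thr[1, 1]), 0)
  expect_equal(unname(thr[100, 1]), 0)
  core <- which(a >= 0.5 * max(a))
  expect_true(all(thr[core, 1] > 0))
})
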