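test_that("half-normal noise estimates are calibrated and homogeneous", {
  set.seed(31)
  x <- rnorm(1e5)
  est <- noise_level(x)
  expect_gt(est, 0.97); expect_lt(est, 1.03)
  # degree-1 homogeneity and shift invariance (baseline re-estimated)
  expect_equal(noise_level(3 * x), 3 * est, tolerance = 1e-10)
  expect_equal(noise_level(x + 7), est, tolerance = 0.02)
  x2 <- rnorm(1e5, sd = 2)
  expect_lt(abs(noise_level(x2) - 2) / 2, 0.05)
  expect_error(noise_level(rep(1, 5)), "sub-baseline")
})

test_that("peak-SNR is exact for constant z-scores and analytic transients", {
  # z identically 3: SNR equals 3 exactly
  tr <- rep(3, 100)
  expect_equal(peak_snr(tr, frame_rate = 30, noise = 1, baseline = 0), 3,
               tolerance = 1e-12)
  # 10-sigma rectangular transient longer than the window
  tr2 <- c(rep(0, 50), rep(10, 20), rep(0, 30))
  got <- peak_snr(tr2, frame_rate = 30, noise = 1, baseline = 0)
  expect_equal(got, 10, tolerance = 0.1)
  expect_error(peak_snr(rep(1, 5), frame_rate = 30, transient_seconds = 1,
                        noise = 1, baseline = 0), "exceeds")
})

test_that("log-domain SNR matches a direct-product oracle on random traces", {
  set.seed(32)
  direct_snr <- function(z, Ns) {
    p <- pnorm(-z)
    Tt <- length(z)
    gm <- vapply(seq_len(Tt - Ns + 1L), function(t) {
      prod(p[t:(t + Ns - 1L)])^(1 / Ns)
    }, numeric(1))
    -qnorm(min(gm))
  }
  for (k in 1:100) {
    Tt <- sample(60:500, 1)
    z <- rnorm(Tt, sd = 1.5)
    Ns <- ceiling(0.4 * 30)
    ours <- peak_snr(z, frame_rate = 30, noise = 1, baseline = 0)
    expect_lt(abs(ours - direct_snr(z, Ns)), 1e-6)
  }
  # pure noise SNR stays modest
  snrs <- replicate(20, peak_snr(rnorm(1e4), frame_rate = 30, noise = 1,
                                 baseline = 0))
  expect_true(all(snrs < 4))
})

test_that("SNR never decreases when a positive transient is added", {
  set.seed(33)
  base <- rnorm(500, sd = 1)
  tr <- dexp(seq(0, 5, length.out = 60)) * 8
  for (k in 1:10) {
    at <- sample(400, 1)
    bumped <- base
    bumped[at:(at + 59)] <- bumped[at:(at + 59)] + tr
    expect_gte(peak_snr(bumped, frame_rate = 30, noise = 1, baseline = 0),
               peak_snr(base, frame_rate = 30, noise = 1, baseline = 0))
  }
})

test_that("residual traces obey the projection identity and scaling law", {
  g <- generate_movie(tiny_params(seed = 41L, noise_sigma = 0))
  comps <- component_set(g$truth$footprints, g$truth$traces)
  bg <- background_model("low_rank", spatial = g$truth$background_spatial,
                         temporal = g$truth$background_temporal)
  r <- residual_trace(g$movie, comps, bg, 1L)
  expect_lt(max(abs(r$residual)), 1e-6)
  # with noise: residual std close to the noise level (unit-norm footprint)
  gn <- generate_movie(tiny_params(seed = 41L, noise_sigma = 0.2))
  compsn <- component_set(gn$truth$footprints, gn$truth$traces)
  bgn <- background_model("low_rank", spatial = gn$truth$background_spatial,
                          temporal = gn$truth$background_temporal)
  rn <- residual_trace(gn$movie, compsn, bgn, 2L)
  expect_lt(abs(sd(rn$residual) - 0.2) / 0.2, 0.15)
  # scaling law: doubling the footprint halves the projected residual
  a <- gn$truth$footprints[, 2]
  R <- gn$movie$data - gn$truth$footprints %*% gn$truth$traces -
    gn$truth$background_spatial %*% gn$truth$background_temporal
  r_1x <- as.numeric(crossprod(R, a)) / sum(a^2)
  r_2x <- as.numeric(crossprod(R, 2 * a)) / sum((2 * a)^2)
  expect_equal(r_2x, r_1x / 2, tolerance = 1e-12)
  expect_error(residual_trace(gn$movie,
                              component_set(matrix(0, 576, 1),
                                            matrix(0, 1, 300)), NULL, 1L),
               "all-zero")
})

test_that("spatial consistency is high for true components and low for misplaced ones", {
  g <- generate_movie(tiny_params(seed = 42L, noise_sigma = 0))
  comps <- component_set(g$truth$footprints, g$truth$traces)
  bg <- background_model("low_rank", spatial = g$truth$background_spatial,
                         temporal = g$truth$background_temporal)
  sc <- spatial_consistency(g$movie, comps, bg, 1L)
  expect_gte(sc$correlation, 0.99)
  # replace the footprint by one at a distant location
  wrong <- comps
  shifted <- cnmfr:::gaussian_footprint(
    c(24, 24) - g$truth$centers[1, ] + c(1, 1), 24, 24, 2.5)
  wrong$footprints[, 1] <- shifted
  scw <- spatial_consistency(g$movie, wrong, bg, 1L)
  expect_lt(scw$correlation, 0.2)
  # flat trace: no activity
  flat <- comps
  flat$traces[1, ] <- 1
  scf <- spatial_consistency(g$movie, flat, bg, 1L)
  expect_equal(scf$correlation, 0)
  expect_equal(scf$reason, "no activity")
})

test_that("component evaluation applies the threshold logic and reasons", {
  g <- generate_movie(tiny_params(seed = 43L))
  comps <- component_set(g$truth$footprints, g$truth$traces)
  bg <- background_model("low_rank", spatial = g$truth$background_spatial,
                         temporal = g$truth$background_temporal)
  rep <- evaluate_components(g$movie, comps, bg, quality_thresholds())
  expect_true(all(rep$accepted))
  # inject a spurious random blob: it should be rejected
  set.seed(1)
  blob <- numeric(576); blob[sample(576, 30)] <- runif(30)
  blob <- blob / sqrt(sum(blob^2))
  aug <- component_set(cbind(g$truth$footprints, blob),
                       rbind(g$truth$traces, rnorm(300)^2))
  rep2 <- evaluate_components(g$movie, aug, bg, quality_thresholds())
  expect_true(all(rep2$accepted[1:4]))
  expect_false(rep2$accepted[5])
  expect_match(rep2$rejection_reasons[5], "space_corr|snr|classifier")
})

test_that("duplicate detection follows the asymmetric overlap rule", {
  d <- 100L
  a1 <- numeric(d); a1[1:9] <- 1          # 3x3-ish mask
  a2 <- numeric(d); a2[1:4] <- 1          # subset mask
  a3 <- numeric(d); a3[50:58] <- 1        # disjoint
  comps <- list(footprints = cbind(a1, a2, a3))
  # identical masks: lower score removed
  twin <- list(footprints = cbind(a1, a1))
  expect_equal(detect_duplicates(twin, c(0.9, 0.2)), 1L)
  expect_equal(detect_duplicates(twin, c(0.2, 0.9)), 2L)
  # disjoint masks: nothing removed
  expect_equal(detect_duplicates(list(footprints = cbind(a1, a3)),
                                 c(0.5, 0.5)), c(1L, 2L))
  # subset: O(sub -> big) = 4/9 < 0.7 but O(big -> sub) = 1 > 0.7;
  # equal scores: tie broken by keeping the lower index
  kept <- detect_duplicates(comps, c(0.5, 0.5, 0.5), overlap_dup = 0.7)
  expect_equal(kept, c(1L, 3L))
  # exhaustive-enumeration oracle on the same fixture: only pair (1,2)
  # exceeds the threshold in one direction
  masks <- cbind(a1, a2, a3) > 0
  O <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) if (i != j) {
    O[i, j] <- sum(masks[, i] & masks[, j]) / sum(masks[, j])
  }
  expect_equal(which(O > 0.7, arr.ind = TRUE), cbind(row = 1L, col = 2L),
               ignore_attr = TRUE)
})

test_that("duplicate removal output is duplicate-free by construction", {
  set.seed(44)
  for (k in 1:5) {
    A <- random_footprints(8, 16, 16, 2)
    comps <- list(footprints = A)
    kept <- detect_duplicates(comps, runif(8), overlap_dup = 0.5,
                              binarize_threshold = 0.3)
    masks <- (A[, kept, drop = FALSE] >=
                0.3 * matrix(apply(A[, kept, drop = FALSE], 2, max),
                             nrow(A), length(kept), byrow = TRUE)) * 1
    if (length(kept) > 1L) {
      inter <- crossprod(masks)
      O <- inter / matrix(diag(inter), length(kept), length(kept),
                          byrow = TRUE)
      diag(O) <- 0
      expect_true(all(O <= 0.5))
    }
  }
})
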