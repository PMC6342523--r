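# Shared fixtures: all synthetic, generated in code at test time.

# Small movie for fast unit tests: 24 x 24 px, 10 s at 30 Hz, 4 neurons.
tiny_params <- function(seed = 1L, ...) {
  args <- list(...)
  base <- list(fov_dims = c(24L, 24L), n_frames = 300L, n_neurons = 4L,
               gaussian_radius = 2.5, background_rank = 1L, seed = seed)
  base[names(args)] <- args
  do.call(synth_params, base)
}

# The standard benchmark conditions: 64 x 64 x 1000 frames, 20 neurons with
# transient peak at ten times the noise level of the projected trace.
benchmark_params <- function(seed = 1L) synth_params(seed = seed)

# Pipeline configuration used for end-to-end runs on the benchmark movie:
# component count sized to the expected per-patch density, spike-domain
# SNR screening enabled.
benchmark_batch_params <- function(seed = 1L) {
  batch_params(components_per_patch = 20L,
               thresholds = quality_thresholds(space_corr_min = 0.8,
                                               classifier_reject_floor = 0.2,
                                               spike_snr_test = TRUE),
               init = init_params(gaussian_width = 3),
               seed = seed)
}

# Noiseless AR(1) trace from a given spike train.
ar1_trace <- function(spikes, gamma) {
  as.numeric(stats::filter(spikes, gamma, method = "recursive"))
}

# Random footprint set on a small grid: disjoint-ish Gaussian blobs.
random_footprints <- function(n, rows = 20L, cols = 20L, radius = 2) {
  A <- matrix(0, rows * cols, n)
  centers <- cbind(runif(n, radius + 1, rows - radius),
                   runif(n, radius + 1, cols - radius))
  for (i in seq_len(n)) {
    A[, i] <- cnmfr:::gaussian_footprint(centers[i, ], rows, cols, radius)
  }
  A
}

# Online benchmark configuration: bare initialization, two epochs, final
# screen tuned to the rougher streamed footprints.
benchmark_online_params <- function() {
  online_params(epochs = 2L, neuron_radius = 3)
}
benchmark_online_thresholds <- function() {
  quality_thresholds(space_corr_min = 0.65, spike_snr_test = TRUE)
}
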