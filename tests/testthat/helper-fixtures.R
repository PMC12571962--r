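# Shared fixtures: small configurations that keep unit tests fast while the
# acceptance suite exercises the full study geometry.

tiny_config <- function(..., n_per_group = 3L, n_parcels = 6L,
                        voxels_per_parcel = 4L, n_volumes = 160L,
                        n_trials = 18L, seed = 101L) {
  sim_config(n_per_group = n_per_group, n_parcels = n_parcels,
             voxels_per_parcel = voxels_per_parcel, n_volumes = n_volumes,
             n_trials = n_trials, seed = seed, ...)
}

tiny_events <- function(config = tiny_config(), group = "HC", seed = 1L) {
  withr::with_seed(seed, simulate_events(config, group))
}

# deterministic motion fixture
tiny_motion <- function(n_volumes, seed = 9L) {
  withr::with_seed(seed, matrix(cumsum(stats::rnorm(n_volumes * 6, 0, 0.01)),
                                n_volumes, 6))
}

# brute-force convolution + middle-bin downsampling oracle (O(n * k) loop)
oracle_convolve <- function(neural, kernel, n_volumes, bins) {
  n <- length(neural)
  out <- numeric(n)
  for (t in seq_len(n)) {
    kmax <- min(t, length(kernel))
    out[t] <- sum(kernel[seq_len(kmax)] * neural[t - seq_len(kmax) + 1L])
  }
  out[(seq_len(n_volumes) - 1L) * bins + bins %/% 2L + 1L]
}
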