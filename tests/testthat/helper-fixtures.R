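# Fixtures are built in code at test time; nothing is stored on disk.

# plain Gaussian-noise recording on a small grid
noise_recording <- function(duration_s = 2, fs = 512, grid = c(4, 4),
                            noise_sd = 1, seed = 1) {
  set.seed(seed)
  n <- round(duration_s * fs)
  nch <- grid[1] * grid[2]
  grid_recording(matrix(rnorm(n * nch, sd = noise_sd), n, nch),
                 fs, grid[1], grid[2])
}

# compact biphasic test spike (positive then negative lobe), ~10 ms
add_test_spike <- function(signal, channel, at_s, fs, amp_uv = 300) {
  half <- round(0.005 * fs)
  u <- seq(-1, 1, length.out = 2 * half + 1)
  w <- sin(pi * u) * 0.5 * (1 + cos(pi * u))
  w <- w / max(abs(w)) * amp_uv
  centre <- round(at_s * fs) + 1
  idx <- (centre - half):(centre + half)
  ok <- idx >= 1 & idx <= nrow(signal)
  signal[idx[ok], channel] <- signal[idx[ok], channel] + w[ok]
  signal
}

# spike times of a jittered regular train inside an interval
train_times <- function(start_s, end_s, rate_hz, cv = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- start_s
  out <- numeric(0)
  while (t < end_s) {
    out <- c(out, t)
    t <- t + (1 / rate_hz) * (1 + cv * rnorm(1))
  }
  out
}

# minimal per-potential table accepted by apply_strategy / exclude_noisy_blocks
potential_table <- function(peak_time_s,
                            at_inc_uv = rep(10, length(peak_time_s)),
                            included = rep(TRUE, length(peak_time_s))) {
  data.frame(peak_time_s = peak_time_s,
             p2t_uv = rep(100, length(peak_time_s)),
             noise_band_uv = at_inc_uv / 8,
             at_inc_uv = at_inc_uv,
             included = included,
             exclusion_reason = ifelse(included, NA_character_, "below_at_inc"))
}

# two well-separated interval-feature clusters for classifier tests
sep_clusters <- function(n_per_class, seed = 1) {
  set.seed(seed)
  cfg <- pipeline_config()
  one <- function(mean_ms, sd_ms) {
    ints <- pmax(rnorm(12, mean_ms, sd_ms), 20) / 1000
    extract_interval_features(cumsum(c(0, ints)), 10, cfg)
  }
  feats <- rbind(
    do.call(rbind, replicate(n_per_class, one(130, 15), simplify = FALSE)),
    do.call(rbind, replicate(n_per_class, one(600, 300), simplify = FALSE))
  )
  labels <- factor(rep(c("voluntary", "false_positive"), each = n_per_class),
                   levels = c("false_positive", "voluntary"))
  list(features = feats, labels = labels)
}
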