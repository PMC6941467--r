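test_that("screening ignores flat channels and respects the occupancy budget", {
  rec <- noise_recording(duration_s = 4, fs = 512, grid = c(3, 3), seed = 2)
  rec$signal[, 4] <- 0
  expect_warning(ev <- screen_potentials(rec, pipeline_config()),
                 "constant")
  expect_false(4 %in% ev$channel)
  # strict threshold crossings occupy at most 2% of samples on any channel
  thr <- attr(ev, "thresholds")
  for (j in setdiff(1:9, 4)) {
    x <- rec$signal[, j]
    occ <- mean(x > thr$pos_uv[j] | x < thr$neg_uv[j])
    expect_lte(occ, 0.02)
  }
})

test_that("a spike on a quiet channel yields exactly one screened event", {
  fs <- 2048
  sig <- matrix(0, nrow = 60 * fs, ncol = 9)
  sig <- add_test_spike(sig, 1, at_s = 30, fs = fs, amp_uv = 300)
  rec <- grid_recording(sig + 1e-6, fs, 3, 3)  # break exact zero ties
  ev <- suppressWarnings(screen_potentials(rec, pipeline_config()))
  ev1 <- ev[ev$channel == 1, ]
  expect_equal(nrow(ev1), 1)
  expect_true(ev1$start <= 30 * fs + 1 && ev1$end > 30 * fs + 1)
})

test_that("a spike in Gaussian noise survives thresholding; noise does not", {
  fs <- 2048
  set.seed(8)
  sig <- matrix(rnorm(60 * fs * 9, sd = 2), ncol = 9)
  sig <- add_test_spike(sig, 5, at_s = 30, fs = fs, amp_uv = 300)
  rec <- grid_recording(sig, fs, 3, 3)
  cfg <- pipeline_config()
  ev <- screen_potentials(rec, cfg)
  hits <- ev[ev$channel == 5 & ev$start <= 30 * fs + 1 & ev$end > 30 * fs + 1, ]
  expect_equal(nrow(hits), 1)
  det <- detect_potentials(rec, cfg)
  inc <- det$potentials[det$potentials$included, ]
  expect_equal(nrow(inc), 1)
  expect_lt(abs(inc$peak_time_s - 30), 0.010)
  expect_equal(inc$channel, 5)
})

test_that("merged potentials are sourced from the dominant channel", {
  fs <- 1024
  set.seed(3)
  sig <- matrix(rnorm(10 * fs * 16, sd = 0.5), ncol = 16)
  amps <- seq(50, 200, length.out = 12)
  for (k in 1:12) sig <- add_test_spike(sig, k, 5, fs, amps[k])
  rec <- grid_recording(sig, fs, 4, 4)
  cfg <- pipeline_config()
  ev <- screen_potentials(rec, cfg)
  sc <- build_superchannel(rec, ev, cfg)
  near <- sc$potentials[sc$potentials$span_start <= 5 * fs + 1 &
                          sc$potentials$span_end > 5 * fs + 1, ]
  expect_equal(nrow(near), 1)
  expect_equal(near$channel, 12)  # the 200 uV channel wins
  # merging is permutation invariant in the event order
  sc2 <- build_superchannel(rec, ev[sample(nrow(ev)), ], cfg)
  expect_equal(sc$potentials, sc2$potentials)
})

test_that("distant spikes stay distinct and spans never overlap", {
  fs <- 1024
  set.seed(4)
  sig <- matrix(rnorm(10 * fs * 9, sd = 0.5), ncol = 9)
  sig <- add_test_spike(sig, 2, 4.0, fs, 200)
  sig <- add_test_spike(sig, 7, 4.5, fs, 200)
  rec <- grid_recording(sig, fs, 3, 3)
  cfg <- pipeline_config()
  sc <- build_superchannel(rec, screen_potentials(rec, cfg), cfg)
  p <- sc$potentials
  near <- p[(p$span_start <= 4.0 * fs + 1 & p$span_end > 4.0 * fs + 1) |
              (p$span_start <= 4.5 * fs + 1 & p$span_end > 4.5 * fs + 1), ]
  expect_equal(nrow(near), 2)
  expect_equal(sort(near$channel), c(2, 7))
  expect_true(all(diff(p$peak_time_s) > 0))
  expect_true(all(utils::head(p$span_end, -1) <= utils::tail(p$span_start, -1)))
})

test_that("the noise band matches its defining arithmetic", {
  fs <- 512
  cfg <- pipeline_config()
  # constant +3 uV surroundings: no negative samples, band = 3
  sig <- matrix(3, nrow = 4 * fs, ncol = 1)
  rec <- grid_recording(sig, fs, 1, 1)
  expect_equal(compute_noise_band(rec, 2 * fs, 2 * fs + 10, 1, config = cfg), 3)
  # alternating +-2 uV: mean(+2) - mean(-2) = 4
  sig2 <- matrix(rep(c(2, -2), 2 * fs), ncol = 1)
  rec2 <- grid_recording(sig2, fs, 1, 1)
  expect_equal(compute_noise_band(rec2, 2 * fs, 2 * fs + 10, 1, config = cfg), 4)
  # fully masked window is undefined
  other <- data.frame(start = 1L, end = nrow(sig2) + 1L)
  expect_true(is.na(compute_noise_band(rec2, 2 * fs, 2 * fs + 10, 1,
                                       other_spans = other, config = cfg)))
})

test_that("Monte-Carlo noise bands agree with the half-normal closed form", {
  fs <- 2048
  cfg <- pipeline_config()
  sigma <- 3
  bands <- vapply(1:40, function(seed) {
    set.seed(seed)
    rec <- grid_recording(matrix(rnorm(4 * fs, sd = sigma), ncol = 1),
                          fs, 1, 1)
    compute_noise_band(rec, 2 * fs, 2 * fs + 20, 1, config = cfg)
  }, numeric(1))
  expected <- 2 * sigma * sqrt(2 / pi)  # E|N(0,s)| on each side
  expect_lt(abs(mean(bands) - expected) / expected, 0.02)
})

test_that("median noise is robust and uses the midpoint convention", {
  expect_equal(median_noise(data.frame(noise_band_uv = c(2, 3, 100))), 3)
  expect_equal(median_noise(data.frame(noise_band_uv = c(2, 4))), 3)
  expect_equal(median_noise(data.frame(noise_band_uv = 7)), 7)
  expect_warning(out <- median_noise(data.frame(noise_band_uv = NA_real_)),
                 "undefined")
  expect_true(is.na(out))
})

test_that("the inclusion threshold scales linearly with the noise band", {
  cfg <- pipeline_config()
  bands <- c(0, 0.5, 1, 5, 12.5, 40)
  pots <- data.frame(p2t_uv = rep(99, 6), noise_band_uv = bands)
  out <- apply_inclusion_threshold(pots, cfg)
  expect_equal(out$at_inc_uv, cfg$at_inc_noise_factor * bands)
  # noise 0 -> threshold 0, everything included
  expect_true(out$included[1])
  # noise 12.5 -> threshold 100 > p2t 99 -> excluded
  expect_false(out$included[5])
  expect_equal(out$exclusion_reason[5], "below_at_inc")
  # undefined noise band excludes the potential
  und <- apply_inclusion_threshold(
    data.frame(p2t_uv = 500, noise_band_uv = NA_real_), cfg)
  expect_false(und$included)
  expect_equal(und$exclusion_reason, "noisy_block")
})

test_that("noisy-block rules fire exactly as stated", {
  cfg <- pipeline_config()
  run_case <- function(at_inc) {
    pots <- potential_table(c(1, 2, 3), at_inc_uv = at_inc)
    exclude_noisy_blocks(pots, duration_s = 5, cfg)
  }
  a <- run_case(c(120, 130, 50))
  expect_true(a$blocks$excluded[1])
  expect_equal(a$blocks$rule_fired[1], "half_above_atexc")
  expect_false(any(a$potentials$included))

  b <- run_case(c(50, 60, 210))
  expect_true(b$blocks$excluded[1])
  expect_equal(b$blocks$rule_fired[1], "any_above_double")

  c3 <- run_case(c(50, 60, 110))
  expect_false(c3$blocks$excluded[1])
  expect_true(all(c3$potentials$included))

  # empty blocks are never excluded; a short final block keeps its length
  empty <- exclude_noisy_blocks(potential_table(numeric(0)), 12, cfg)
  expect_equal(nrow(empty$blocks), 3)
  expect_equal(empty$blocks$end_s[3], 12)
  expect_false(any(empty$blocks$excluded))
})

test_that("raising injected noise never lowers the excluded-block count", {
  counts <- vapply(c(5, 20, 40), function(noise_sd) {
    fx <- generate_recording(synth_params(
      duration_s = 20, seed = 33, fasciculation_rate_per_min = 60,
      noise_sd_uv = noise_sd))
    cfg <- pipeline_config()
    rec <- bandpass_notch(trim_to_central_grid(fx$recording), cfg)
    sum(detect_potentials(rec, cfg)$noise_blocks$excluded)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[1], 0)
  expect_gt(counts[3], 0)
})
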