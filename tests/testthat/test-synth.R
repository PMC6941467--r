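# The generator runs at a reduced sampling rate where only spike timing (not
# waveform detail) matters, to keep the suite fast.

test_that("identical parameters and seed reproduce the recording exactly", {
  p <- synth_params(duration_s = 10, sampling_rate = 512, seed = 5,
                    n_voluntary_units = 1,
                    voluntary_epochs = list(c(2, 6)))
  a <- generate_recording(p)
  b <- generate_recording(p)
  expect_identical(a$recording$signal, b$recording$signal)
  expect_identical(a$truth$spikes, b$truth$spikes)
})

test_that("fasciculation counts follow the Poisson mean", {
  p <- synth_params(duration_s = 600, sampling_rate = 128,
                    fasciculation_rate_per_min = 40,
                    line_noise_uv = 0, drift_uv = 0, seed = 11)
  fx <- generate_recording(p)
  n <- nrow(fx$truth$spikes)
  expect_gt(n, 400 - 3 * sqrt(400))
  expect_lt(n, 400 + 3 * sqrt(400))
})

test_that("inter-spike intervals beyond the refractory period are exponential", {
  rate_s <- 40 / 60
  passes <- 0L
  for (seed in 1:20) {
    p <- synth_params(duration_s = 600, sampling_rate = 128,
                      fasciculation_rate_per_min = 40, seed = seed,
                      line_noise_uv = 0, drift_uv = 0)
    fx <- generate_recording(p)
    isi <- diff(fx$truth$spikes$time_s) - p$refractory_ms / 1000
    ks <- suppressWarnings(stats::ks.test(isi, "pexp", rate = rate_s))
    if (ks$p.value > 0.01) passes <- passes + 1L
  }
  expect_gte(passes, 18L)
})

test_that("per-unit firing respects the refractory period", {
  p <- synth_params(duration_s = 60, sampling_rate = 256, seed = 2,
                    fasciculation_rate_per_min = 120,
                    n_voluntary_units = 2, voluntary_rate_hz = 10,
                    voluntary_epochs = list(c(5, 55)))
  fx <- generate_recording(p)
  for (u in unique(fx$truth$spikes$unit_id)) {
    tu <- fx$truth$spikes$time_s[fx$truth$spikes$unit_id == u]
    if (length(tu) > 1) {
      expect_gte(min(diff(tu)) * 1000, p$refractory_ms - 1e-9)
    }
  }
})

test_that("every spike reaches at least 10 channels above quarter amplitude", {
  for (seed in 1:5) {
    p <- synth_params(duration_s = 1, sampling_rate = 1024, seed = seed,
                      fasciculation_rate_per_min = 60, noise_sd_uv = 0,
                      line_noise_uv = 0, drift_uv = 0)
    fx <- generate_recording(p)
    for (i in seq_len(nrow(fx$truth$spikes))) {
      at <- round(fx$truth$spikes$time_s[i] * 1024) + 1
      amps <- abs(fx$recording$signal[at, ])
      expect_gte(sum(amps >= max(amps) / 4), 10)
    }
  }
})

test_that("generated voluntary trains satisfy the train predicate in their epochs", {
  cfg <- pipeline_config()
  for (seed in 1:10) {
    p <- synth_params(duration_s = 40, sampling_rate = 128, seed = seed,
                      fasciculation_rate_per_min = 0,
                      n_voluntary_units = 1,
                      voluntary_rate_hz = runif(1, 5, 10),
                      voluntary_epochs = list(c(5, 20), c(25, 35)))
    fx <- generate_recording(p)
    sp <- fx$truth$spikes
    for (e in seq_len(nrow(fx$truth$voluntary_epochs))) {
      tt <- sp$time_s[sp$time_s >= fx$truth$voluntary_epochs$start_s[e] &
                        sp$time_s < fx$truth$voluntary_epochs$end_s[e]]
      expect_true(contains_voluntary_train(tt, cfg))
    }
  }
})

test_that("multiplet partners trail their parent at the configured gap", {
  p <- synth_params(duration_s = 120, sampling_rate = 128, seed = 4,
                    fasciculation_rate_per_min = 10,
                    multiplet_rate_per_min = 10, multiplet_gap_ms = 30)
  fx <- generate_recording(p)
  sec <- fx$truth$spikes[fx$truth$spikes$kind == "multiplet_secondary", ]
  expect_gt(nrow(sec), 0)
  for (i in seq_len(nrow(sec))) {
    par <- fx$truth$spikes[fx$truth$spikes$unit_id == sec$unit_id[i] &
                             fx$truth$spikes$kind == "fasciculation", ]
    expect_equal(sec$time_s[i] - par$time_s[1], 0.030, tolerance = 1e-9)
  }
})

test_that("parameter validation guards epochs, rates and footprint", {
  expect_error(synth_params(voluntary_epochs = list(c(10, 70)),
                            duration_s = 60, n_voluntary_units = 1),
               "epochs")
  expect_error(synth_params(n_voluntary_units = 1, voluntary_rate_hz = 3),
               "4, 12")
  expect_error(synth_params(multiplet_gap_ms = 60), "50 ms")
  expect_error(synth_params(spike_channel_footprint = 4), "10 channels")
})

test_that("fixture presets mirror their manual categories", {
  rel <- make_fixture_suite("relaxed", duration_s = 5, seed = 1)
  expect_equal(sum(rel$truth$spikes$kind == "voluntary"), 0)
  pr <- make_fixture_suite("partially_relaxed", duration_s = 30, seed = 1)
  cov <- sum(pr$truth$voluntary_epochs$end_s - pr$truth$voluntary_epochs$start_s)
  expect_gt(cov, 0)
  expect_lt(cov, 30)
  expect_error(make_fixture_suite("bogus"), "arg")
})
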