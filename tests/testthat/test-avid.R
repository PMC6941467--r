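test_that("train detection matches an exhaustive run-scan oracle", {
  cfg <- pipeline_config()
  expect_true(contains_voluntary_train(c(0, 0.2, 0.4, 0.6), cfg))
  expect_false(contains_voluntary_train(c(0, 0.3, 0.6, 0.9), cfg))
  expect_true(contains_voluntary_train(c(0, 0.1, 0.2, 0.6, 0.7, 0.8, 0.9), cfg))
  expect_false(contains_voluntary_train(c(0, 0.1, 0.2), cfg))

  # brute-force oracle: scan every window of 4 consecutive potentials
  oracle <- function(times, k = 4, thr = 0.250) {
    if (length(times) < k) return(FALSE)
    for (i in seq_len(length(times) - k + 1)) {
      if (all(diff(times[i:(i + k - 1)]) < thr)) return(TRUE)
    }
    FALSE
  }
  set.seed(42)
  for (rep in 1:200) {
    times <- sort(runif(sample(2:12, 1), 0, 3))
    expect_identical(contains_voluntary_train(times, cfg), oracle(times))
  }
})

test_that("block labelling flags trains within blocks only", {
  cfg <- pipeline_config()
  # sparse Poisson firing at 10/min almost never yields 4 spikes per block
  set.seed(1)
  sparse <- sort(runif(10, 0, 60))
  lb <- label_blocks(sparse, 60, 10, cfg)
  expect_equal(sum(lb$flagged), 0)

  # sustained 7 Hz train covering 15-30 s
  train <- train_times(15, 30, 7)
  lb10 <- label_blocks(train, 60, 10, cfg)
  covered <- vapply(seq_len(nrow(lb10)), function(b) {
    sum(train >= lb10$start_s[b] & train < lb10$end_s[b]) >= 4
  }, logical(1))
  expect_identical(lb10$flagged, covered)
  expect_gte(sum(lb10$flagged), 1)

  # 1 s blocks: only blocks holding >= 4 train spikes are flagged
  lb1 <- label_blocks(train, 60, 1, cfg)
  n_in <- vapply(seq_len(nrow(lb1)), function(b) {
    sum(train >= lb1$start_s[b] & train < lb1$end_s[b])
  }, numeric(1))
  expect_true(all(!lb1$flagged[n_in < 4]))
  # a 7 Hz train puts exactly 7 spikes in interior seconds
  expect_true(any(lb1$flagged))
  # no block anywhere is ever flagged with fewer than 4 potentials
  expect_true(all(lb1$n_potentials[lb1$flagged] >= 4))
})

test_that("interval features equal an independent statistics oracle", {
  cfg <- pipeline_config()
  # constant 100 ms intervals: 11 potentials over 10 s
  fe <- extract_interval_features(seq(0, 1, by = 0.1), 10, cfg)
  expect_equal(fe$median_ms, 100)
  expect_equal(fe$mean_ms, 100)
  expect_equal(fe$mode_ms, 100)
  expect_equal(fe$sd_ms, 0)
  expect_equal(fe$iqr_ms, 0)
  expect_equal(fe$freq_per_min, 66)
  expect_equal(fe$prop_band, 1)
  expect_equal(fe$kurtosis_band, 3)  # degenerate in-band spread

  # intervals outside the 84-250 ms band contribute nothing to prop_band
  fe2 <- extract_interval_features(cumsum(c(0, 0.3, 0.4, 0.5)), 10, cfg)
  expect_equal(fe2$prop_band, 0)

  # frozen values recomputed with textbook formulas
  ints <- c(90, 110, 130, 170, 210, 400) / 1000
  fe3 <- extract_interval_features(cumsum(c(0, ints)), 10, cfg)
  expect_equal(fe3$median_ms, 150)
  expect_equal(fe3$mean_ms, 185)
  expect_equal(fe3$mode_ms, 90)   # all bins tied; shortest interval wins
  expect_equal(fe3$sd_ms, 113.7980668, tolerance = 1e-8)
  expect_equal(fe3$iqr_ms, 85)
  expect_equal(fe3$freq_per_min, 42)
  expect_equal(fe3$kurtosis_band, 1.763674197, tolerance = 1e-8)
  expect_equal(fe3$prop_band, 5 / 6)

  # fewer than two potentials: undefined
  expect_null(extract_interval_features(0.5, 10, cfg))
})

test_that("the bagged classifier separates well-separated interval clusters", {
  cfg <- pipeline_config(rng_seed = 7L)
  d <- sep_clusters(200)
  clf <- train_classifier(d$features, d$labels, cfg)
  expect_gte(clf$cv$accuracy_pct, 95)
  expect_equal(clf$model$ntree, 30)

  # chance level under label permutation
  set.seed(99)
  perm <- train_classifier(d$features, sample(d$labels), cfg)
  expect_gt(perm$cv$accuracy_pct, 40)
  expect_lt(perm$cv$accuracy_pct, 60)
})

test_that("training is seeded and prediction deterministic", {
  cfg <- pipeline_config(rng_seed = 11L)
  d <- sep_clusters(60, seed = 3)
  held <- sep_clusters(20, seed = 4)
  c1 <- train_classifier(d$features, d$labels, cfg)
  c2 <- train_classifier(d$features, d$labels, cfg)
  expect_identical(predict(c1, held$features), predict(c2, held$features))
  expect_identical(c1$cv, c2$cv)
})

test_that("degenerate training sets are rejected", {
  d <- sep_clusters(60)
  cfg <- pipeline_config()
  expect_error(train_classifier(d$features[1:30, ], d$labels[1:30], cfg),
               "at least 50")
  one_class <- factor(rep("voluntary", nrow(d$features)),
                      levels = c("false_positive", "voluntary"))
  expect_error(train_classifier(d$features, one_class, cfg), "two classes")
})

test_that("strategies exclude blocks as specified", {
  cfg <- pipeline_config()
  # a 12 s voluntary train at 8 Hz over [14, 26) plus sparse background
  set.seed(5)
  times <- sort(c(train_times(14, 26, 8), runif(10, 0, 60)))
  pots <- potential_table(times)

  s0 <- apply_strategy(pots, 60, "0", cfg)
  expect_equal(s0$excluded_time_s, 0)
  expect_identical(s0$potentials$included, pots$included)

  s1a <- apply_strategy(pots, 60, "1A", cfg)
  expect_gte(s1a$excluded_time_s, 10)
  expect_lte(s1a$excluded_time_s, 30)
  expect_true(all(s1a$blocks$final_excluded == s1a$blocks$flagged))

  s2 <- apply_strategy(pots, 60, "2", cfg)
  expect_lte(s2$excluded_time_s, 14)
  expect_gte(s2$excluded_time_s, 1)

  # excluded potentials gain the voluntary reason
  out <- s1a$potentials
  expect_true(any(out$exclusion_reason == "avid_voluntary", na.rm = TRUE))
  expect_true(all(!out$included[!is.na(out$exclusion_reason) &
                                  out$exclusion_reason == "avid_voluntary"]))
})

test_that("classifier rescue can only return blocks to the pool", {
  cfg <- pipeline_config(rng_seed = 13L)
  tr <- simulate_training_blocks(75, cfg)
  clf <- train_classifier(tr$features, tr$labels, cfg)
  expect_gte(clf$cv$accuracy_pct, 70)

  set.seed(6)
  times <- sort(c(train_times(14, 26, 8), runif(40, 0, 60)))
  pots <- potential_table(times)
  s1a <- apply_strategy(pots, 60, "1A", cfg)
  s1b <- apply_strategy(pots, 60, "1B", cfg, classifier = clf)
  # 1B never excludes a block 1A kept
  expect_true(all(!s1b$blocks$final_excluded | s1b$blocks$flagged))
  expect_lte(s1b$excluded_time_s, s1a$excluded_time_s)
  expect_error(apply_strategy(pots, 60, "1B", cfg), "classifier")
})

test_that("interval histograms count consecutive pairs and drop split pairs", {
  h <- interval_histogram(c(1.0, 1.15), range_ms = 400, bin_ms = 10)
  expect_equal(h$count[h$bin_start_ms == 150], 1)
  expect_equal(sum(h$count), 1)

  train <- train_times(10, 20, 7)
  h7 <- interval_histogram(train, 400, 10)
  expect_equal(h7$bin_start_ms[which.max(h7$count)], 140)  # 1/7 s = 142.9 ms
  # conservation: every in-range consecutive pair lands in exactly one bin
  ints <- diff(train) * 1000
  expect_equal(sum(h7$count), sum(ints < 400))

  # an interval spanning an excluded epoch is dropped
  hx <- interval_histogram(c(1.0, 1.15), 400, 10,
                           excluded_epochs = data.frame(start_s = 1.05,
                                                        end_s = 1.10))
  expect_equal(sum(hx$count), 0)
})

test_that("strategy recommendation reads the histogram deterministically", {
  # exponential-decay histogram with no voluntary peak
  bins <- seq(0, 390, by = 10)
  flat <- data.frame(bin_start_ms = bins, bin_end_ms = bins + 10,
                     count = round(200 * exp(-bins / 300)))
  r0 <- recommend_strategy(flat)
  expect_equal(r0$strategy, "0")

  peaked <- flat
  peaked$count[peaked$bin_start_ms == 140] <- 1000
  rp <- recommend_strategy(peaked)
  expect_false(rp$strategy == "0")
  expect_identical(rp, recommend_strategy(peaked))

  expect_equal(recommend_strategy(flat[0, ])$strategy, "0")
  expect_equal(recommend_strategy(peaked, flagged_fraction = 0.5)$strategy, "1B")
  expect_equal(recommend_strategy(peaked, flagged_fraction = 0.9)$strategy, "2")
})
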