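#' Does a spike sequence contain a voluntary train?
#'
#' A voluntary train is a run of at least `train_min_potentials` consecutive
#' potentials in which every consecutive inter-spike interval is strictly
#' below `train_max_isi_ms` (defaults: >= 4 potentials, < 250 ms, the
#' signature of motor-unit firing at >= 4 Hz).
#'
#' @param potential_times sorted spike times in seconds.
#' @param config a [pipeline_config()].
#' @return `TRUE` if any qualifying run exists.
#' @examples
#' contains_voluntary_train(c(0, 0.2, 0.4, 0.6))   # TRUE
#' contains_voluntary_train(c(0, 0.3, 0.6, 0.9))   # FALSE
#' @export
contains_voluntary_train <- function(potential_times,
                                     config = pipeline_config()) {
  k <- config$train_min_potentials
  if (length(potential_times) < k) return(FALSE)
  short <- round(diff(potential_times) * 1000, 6) < config$train_max_isi_ms
  r <- rle(short)
  any(r$values & r$lengths >= k - 1L)
}

## half-open [start, end) tiling of [0, duration)
tile_blocks <- function(duration_s, block_s) {
  starts <- seq(0, duration_s, by = block_s)
  if (tail(starts, 1L) >= duration_s) starts <- head(starts, -1L)
  data.frame(start_s = starts, end_s = pmin(starts + block_s, duration_s))
}

#' Label blocks by voluntary-train content
#'
#' Tiles the recording into fixed-duration blocks and flags each block whose
#' own potentials (peak time within the block) contain a voluntary train.
#' Trains are evaluated strictly within blocks: runs never stitch across a
#' block boundary, which is what makes short blocks specific and long blocks
#' sensitive.
#'
#' @param potential_times sorted times (s) of the included potentials.
#' @param duration_s recording duration in seconds.
#' @param block_duration_s block length in seconds (1 s specific, 10 s
#'   sensitive).
#' @param config a [pipeline_config()].
#' @return Data frame: `start_s`, `end_s`, `n_potentials`, `flagged`.
#' @export
label_blocks <- function(potential_times, duration_s, block_duration_s,
                         config = pipeline_config()) {
  blocks <- tile_blocks(duration_s, block_duration_s)
  blocks$n_potentials <- 0L
  blocks$flagged <- FALSE
  for (b in seq_len(nrow(blocks))) {
    t_in <- potential_times[potential_times >= blocks$start_s[b] &
                              potential_times < blocks$end_s[b]]
    blocks$n_potentials[b] <- length(t_in)
    blocks$flagged[b] <- contains_voluntary_train(t_in, config)
  }
  blocks
}

#' Interval features of one block
#'
#' The eight inter-spike-interval statistics fed to the block classifier.
#' Six are computed over the full interval range: median, mean, mode (10 ms
#' binning, ties toward the shorter interval), standard deviation,
#' inter-quartile range (all ms) and firing frequency (potentials per
#' minute). Two are restricted to intervals within the 84--250 ms band
#' (4--12 Hz firing): Pearson (non-excess) kurtosis of the in-band intervals
#' (recorded as the Gaussian reference value 3 when fewer than 4 intervals
#' fall in band) and the proportion of all intervals inside the band.
#'
#' @param potential_times sorted spike times in seconds (>= 2 required).
#' @param block_duration_s block length in seconds, used to normalise the
#'   frequency feature.
#' @param config a [pipeline_config()].
#' @return One-row data frame with columns `median_ms`, `mean_ms`,
#'   `mode_ms`, `sd_ms`, `iqr_ms`, `freq_per_min`, `kurtosis_band`,
#'   `prop_band`, or `NULL` when fewer than two potentials are available
#'   (such a block is treated as non-voluntary without classification).
#' @export
extract_interval_features <- function(potential_times, block_duration_s,
                                      config = pipeline_config()) {
  if (length(potential_times) < 2L) return(NULL)
  # round away float jitter from time subtraction (well below 1 ns)
  ints <- round(diff(sort(potential_times)) * 1000, 6)
  bin <- config$mode_bin_ms
  idx <- round(ints / bin)
  vals <- sort(unique(idx))
  cnt <- vapply(vals, function(v) sum(idx == v), numeric(1))
  mode_ms <- vals[which.max(cnt)] * bin  # ties break toward the shorter interval
  band <- config$feature_band_ms
  inb <- ints >= band[1L] & ints <= band[2L]
  kurt <- if (sum(inb) >= 4L) pearson_kurtosis(ints[inb]) else 3
  data.frame(
    median_ms = median(ints),
    mean_ms = mean(ints),
    mode_ms = mode_ms,
    sd_ms = sd(ints),
    iqr_ms = IQR(ints),
    freq_per_min = length(potential_times) / block_duration_s * 60,
    kurtosis_band = kurt,
    prop_band = mean(inb)
  )
}

## population (non-excess) kurtosis m4 / m2^2
pearson_kurtosis <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 < 1e-12) return(3)  # degenerate spread: Gaussian reference value
  mean((x - mean(x))^4) / m2^2
}

#' Train the voluntary-block classifier
#'
#' A bagged ensemble of `n_trees` (default 30) decision trees over the eight
#' interval features, with no dimensionality reduction, distinguishing true
#' voluntary blocks from falsely flagged ones. Predictive ability is
#' estimated by stratified `cv_folds`-fold cross-validation (accuracy,
#' positive predictive value, negative predictive value, in percent).
#' Training is seeded by `config$rng_seed` and fully reproducible.
#'
#' @param feature_table data frame of [extract_interval_features()] rows.
#' @param labels two-level factor (or character) per row; the level named
#'   `"voluntary"` (else the second level) is the positive class.
#' @param config a [pipeline_config()].
#' @return An object of class `fq_classifier` with the fitted ensemble, the
#'   fold assignment and `cv` metrics.
#' @export
train_classifier <- function(feature_table, labels,
                             config = pipeline_config()) {
  feature_table <- as.data.frame(feature_table)
  labels <- factor(labels)
  if (nrow(feature_table) < 50L) {
    stop("need at least 50 labelled blocks to train", call. = FALSE)
  }
  if (nlevels(labels) != 2L || any(table(labels) == 0L)) {
    stop("labels must contain two classes", call. = FALSE)
  }
  stopifnot(nrow(feature_table) == length(labels),
            all(complete.cases(feature_table)))
  positive <- if ("voluntary" %in% levels(labels)) "voluntary" else levels(labels)[2L]

  set.seed(config$rng_seed)
  folds <- integer(length(labels))
  for (lv in levels(labels)) {
    i <- which(labels == lv)
    folds[i] <- sample(rep_len(seq_len(config$cv_folds), length(i)))
  }

  fit_bag <- function(x, y) {
    randomForest::randomForest(x = x, y = y, ntree = config$n_trees,
                               mtry = ncol(x))  # mtry = p: pure bagging
  }

  pred <- factor(rep(levels(labels)[1L], length(labels)),
                 levels = levels(labels))
  for (k in seq_len(config$cv_folds)) {
    tr <- folds != k
    fit <- fit_bag(feature_table[tr, , drop = FALSE], labels[tr])
    pred[!tr] <- predict(fit, feature_table[!tr, , drop = FALSE])
  }
  tp <- sum(pred == positive & labels == positive)
  tn <- sum(pred != positive & labels != positive)
  fp <- sum(pred == positive & labels != positive)
  fn <- sum(pred != positive & labels == positive)
  cv <- list(
    accuracy_pct = 100 * (tp + tn) / length(labels),
    ppv_pct = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
    npv_pct = if (tn + fn > 0) 100 * tn / (tn + fn) else NA_real_
  )

  model <- fit_bag(feature_table, labels)
  structure(list(model = model, cv = cv, folds = folds,
                 feature_names = names(feature_table),
                 levels = levels(labels), positive = positive,
                 seed = config$rng_seed),
            class = "fq_classifier")
}

#' @export
print.fq_classifier <- function(x, ...) {
  cat(sprintf("<fq_classifier> %d bagged trees; CV accuracy %.1f%%, PPV %.1f%%, NPV %.1f%%\n",
              x$model$ntree, x$cv$accuracy_pct, x$cv$ppv_pct, x$cv$npv_pct))
  invisible(x)
}

#' Predict with the voluntary-block classifier
#'
#' @param object an `fq_classifier`.
#' @param newdata data frame of interval features.
#' @param type `"prob"` for the positive-class probability (fraction of the
#'   bag voting voluntary), `"class"` for the majority-vote label.
#' @param ... unused.
#' @return Numeric probabilities or a factor of labels.
#' @export
predict.fq_classifier <- function(object, newdata,
                                  type = c("prob", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)[, object$feature_names, drop = FALSE]
  if (type == "prob") {
    pr <- predict(object$model, newdata, type = "prob")
    as.numeric(pr[, object$positive])
  } else {
    predict(object$model, newdata)
  }
}

#' Simulate a labelled training set for the block classifier
#'
#' Generates flagged 10-second blocks of both kinds: true voluntary blocks
#' (a regular motor-unit train at 5--10 Hz with jittered intervals over a
#' Poisson fasciculation background) and false positives (pure Poisson
#' fasciculation firing dense enough that a chance run of four sub-250 ms
#' intervals triggers the flag; blocks are rejection-sampled until flagged).
#'
#' @param n_per_class blocks per class.
#' @param config a [pipeline_config()].
#' @param seed integer seed.
#' @return List with `features` (data frame) and `labels` (factor with
#'   levels `false_positive`, `voluntary`).
#' @export
simulate_training_blocks <- function(n_per_class = 150,
                                     config = pipeline_config(),
                                     seed = config$rng_seed) {
  set.seed(seed)
  block_s <- config$avid_block_sensitive_s

  vol_block <- function() {
    rate <- runif(1, 5, 10)
    t <- voluntary_times(c(0, block_s), rate, 0.12, 0.01)
    bg <- poisson_times(runif(1, 10, 60) / 60, block_s, 0.01)
    sort(c(t, bg))
  }
  fp_block <- function() {
    repeat {
      t <- poisson_times(runif(1, 30, 120) / 60, block_s, 0.01)
      if (contains_voluntary_train(t, config)) return(t)
    }
  }
  feats <- list()
  labels <- character(0)
  for (i in seq_len(n_per_class)) {
    feats[[length(feats) + 1L]] <- extract_interval_features(vol_block(), block_s, config)
    labels <- c(labels, "voluntary")
    feats[[length(feats) + 1L]] <- extract_interval_features(fp_block(), block_s, config)
    labels <- c(labels, "false_positive")
  }
  list(features = do.call(rbind, feats),
       labels = factor(labels, levels = c("false_positive", "voluntary")))
}

#' Apply a voluntary-exclusion strategy
#'
#' Strategy `"0"` disables voluntary exclusion; `"1A"` excludes every flagged
#' 10 s block (sensitive); `"1B"` keeps the 1A flags but lets the classifier
#' return falsely flagged blocks to the analysable pool (a flagged block is
#' excluded only when the classifier's voluntary probability reaches 0.5);
#' `"2"` excludes flagged 1 s blocks (specific). The classifier can only
#' un-flag: `final_excluded` implies `flagged`.
#'
#' @param potentials per-potential table (with `included` and
#'   `peak_time_s`); only included potentials drive the labelling.
#' @param duration_s recording duration in seconds.
#' @param strategy one of `"0"`, `"1A"`, `"1B"`, `"2"`.
#' @param config a [pipeline_config()].
#' @param classifier an [train_classifier()] object, required for `"1B"`.
#' @param noise_intervals optional data frame (`start_s`, `end_s`) of
#'   already-excluded noisy blocks; voluntary excluded time is counted net of
#'   the overlap so total time accounting stays exact.
#' @return List with `blocks` (`start_s`, `end_s`, `n_potentials`,
#'   `flagged`, `classifier_prob`, `final_excluded`), updated `potentials`
#'   (excluded ones gain reason `avid_voluntary`) and `excluded_time_s`.
#' @export
apply_strategy <- function(potentials, duration_s,
                           strategy = c("0", "1A", "1B", "2"),
                           config = pipeline_config(), classifier = NULL,
                           noise_intervals = NULL) {
  strategy <- match.arg(as.character(strategy), c("0", "1A", "1B", "2"))
  if (strategy == "1B" && !inherits(classifier, "fq_classifier")) {
    stop("strategy 1B requires a trained classifier", call. = FALSE)
  }
  block_s <- switch(strategy,
                    "0" = config$avid_block_sensitive_s,
                    "1A" = config$avid_block_sensitive_s,
                    "1B" = config$avid_block_sensitive_s,
                    "2" = config$avid_block_specific_s)
  inc_times <- potentials$peak_time_s[potentials$included]
  blocks <- label_blocks(inc_times, duration_s, block_s, config)
  blocks$classifier_prob <- NA_real_
  blocks$final_excluded <- FALSE

  if (strategy %in% c("1A", "2")) {
    blocks$final_excluded <- blocks$flagged
  } else if (strategy == "1B") {
    for (b in which(blocks$flagged)) {
      t_in <- inc_times[inc_times >= blocks$start_s[b] &
                          inc_times < blocks$end_s[b]]
      fe <- extract_interval_features(t_in, block_s, config)
      if (is.null(fe)) next
      p <- predict(classifier, fe, type = "prob")
      blocks$classifier_prob[b] <- p
      blocks$final_excluded[b] <- p >= 0.5
    }
  }

  excluded_time <- 0
  if (any(blocks$final_excluded)) {
    for (b in which(blocks$final_excluded)) {
      len <- blocks$end_s[b] - blocks$start_s[b]
      if (!is.null(noise_intervals) && nrow(noise_intervals)) {
        ov <- pmin(blocks$end_s[b], noise_intervals$end_s) -
          pmax(blocks$start_s[b], noise_intervals$start_s)
        len <- len - sum(pmax(ov, 0))
      }
      excluded_time <- excluded_time + max(len, 0)
    }
    hit <- potentials$included &
      block_of(potentials$peak_time_s, blocks) %in% which(blocks$final_excluded)
    potentials$included[hit] <- FALSE
    potentials$exclusion_reason[hit] <- "avid_voluntary"
  }
  list(blocks = blocks, potentials = potentials,
       excluded_time_s = excluded_time)
}

block_of <- function(times, blocks) findInterval(times, blocks$start_s)

#' Inter-potential interval histogram
#'
#' Counts consecutive inter-potential intervals in fixed-width bins over
#' `[0, range_ms)`. Intervals spanning an excluded epoch are dropped, since
#' the two potentials are no longer consecutive in analysable time.
#'
#' @param potential_times sorted spike times in seconds.
#' @param range_ms histogram upper edge (default 400 ms).
#' @param bin_ms bin width (default 10 ms).
#' @param excluded_epochs optional data frame (`start_s`, `end_s`).
#' @return Data frame: `bin_start_ms`, `bin_end_ms`, `count`.
#' @export
interval_histogram <- function(potential_times, range_ms = 400, bin_ms = 10,
                               excluded_epochs = NULL) {
  edges <- seq(0, range_ms, by = bin_ms)
  counts <- integer(length(edges) - 1L)
  if (length(potential_times) >= 2L) {
    t1 <- head(potential_times, -1L)
    t2 <- tail(potential_times, -1L)
    keep <- rep(TRUE, length(t1))
    if (!is.null(excluded_epochs) && nrow(excluded_epochs)) {
      for (i in seq_len(nrow(excluded_epochs))) {
        keep <- keep & !(excluded_epochs$start_s[i] < t2 &
                           excluded_epochs$end_s[i] > t1)
      }
    }
    ints <- round((t2 - t1)[keep] * 1000, 6)
    ints <- ints[ints < range_ms]
    bin <- floor(ints / bin_ms) + 1L
    tab <- tabulate(bin, nbins = length(counts))
    counts <- tab
  }
  data.frame(bin_start_ms = head(edges, -1L), bin_end_ms = tail(edges, -1L),
             count = counts)
}

#' Advisory strategy recommendation
#'
#' Reads the inter-potential interval histogram the way a reviewer would: if
#' no bin within the voluntary firing range (100--200 ms) rises above `k`
#' times the median bin count of the 250--400 ms tail, no voluntary activity
#' is indicated and strategy `"0"` is suggested. Otherwise the sensitive
#' strategy `"1A"` is suggested, escalating to `"1B"` (classifier rescue)
#' when a moderate fraction of blocks is flagged and to `"2"` (specific)
#' when flagging is so widespread that 1A would discard most of the
#' recording. The output is advisory only; the thresholds are declared
#' heuristics and the caller confirms the strategy explicitly.
#'
#' @param histogram an [interval_histogram()] data frame covering >= 0--400 ms.
#' @param flagged_fraction optional fraction of sensitive blocks flagged.
#' @param k peak-over-tail ratio regarded as a voluntary peak (default 3).
#' @return List with `strategy` and human-readable `rationale`.
#' @export
recommend_strategy <- function(histogram, flagged_fraction = NULL, k = 3) {
  if (is.null(histogram) || nrow(histogram) == 0L || sum(histogram$count) == 0L) {
    return(list(strategy = "0",
                rationale = "empty histogram: no potentials, nothing to exclude"))
  }
  vol <- histogram$count[histogram$bin_start_ms >= 100 & histogram$bin_end_ms <= 200]
  ref <- histogram$count[histogram$bin_start_ms >= 250 & histogram$bin_end_ms <= 400]
  ref_med <- if (length(ref)) median(ref) else 0
  peak <- if (length(vol)) max(vol) else 0
  if (peak <= k * max(ref_med, 1)) {
    return(list(strategy = "0",
                rationale = sprintf(
                  "no interval peak in the voluntary firing range (100-200 ms): max bin %d vs tail median %.1f", peak, ref_med)))
  }
  if (is.null(flagged_fraction) || flagged_fraction <= 0.3) {
    list(strategy = "1A",
         rationale = "voluntary-range interval peak present; sensitive 10 s block exclusion suggested")
  } else if (flagged_fraction <= 0.6) {
    list(strategy = "1B",
         rationale = sprintf(
           "voluntary-range peak with %.0f%% of blocks flagged; classifier rescue of false positives suggested", 100 * flagged_fraction))
  } else {
    list(strategy = "2",
         rationale = sprintf(
           "voluntary-range peak with %.0f%% of blocks flagged; specific 1 s blocks preserve analysable time", 100 * flagged_fraction))
  }
}
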