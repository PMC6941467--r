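#' Pipeline configuration
#'
#' Collects every tunable constant of the detection and voluntary-exclusion
#' pipeline in one validated object. Defaults are the operating values of the
#' published pipeline: a 20--500 Hz band-pass with 50 Hz notch, perimeter
#' trimming to the central 6x6 grid, an extreme-amplitude screen occupying
#' less than 2% of samples per channel, an amplitude inclusion threshold of
#' 8x the local noise band, an amplitude exclusion threshold of 100 uV driving
#' 5-second noisy-block rejection, voluntary trains defined as >= 4 potentials
#' with consecutive inter-spike intervals < 250 ms, sensitive (10 s) and
#' specific (1 s) block strategies, an 84--250 ms interval feature band
#' (4--12 Hz firing), and a 30-tree bagged classifier assessed by stratified
#' 5-fold cross-validation.
#'
#' @param bandpass_low_hz,bandpass_high_hz band-pass corner frequencies in Hz.
#' @param notch_hz mains notch frequency in Hz.
#' @param perimeter_trim discard the outer perimeter of grid channels before
#'   analysis (8x8 -> central 6x6).
#' @param common_average_reference re-reference each sample to the mean across
#'   retained channels before filtering. Off by default: exported recordings
#'   are normally already amplified against the common average in hardware.
#' @param qc_before_filtering run channel quality control on the unfiltered
#'   signal (so baseline drift remains visible to the spectral metric).
#' @param extreme_occupancy_fraction total fraction of samples per channel that
#'   the extreme-amplitude screen may occupy (default 0.02, i.e. < 2%).
#' @param occupancy_split fraction of the occupancy budget assigned to the
#'   positive threshold (default 0.5: 1% positive + 1% negative).
#' @param event_pad_ms padding applied to each screened event before merging
#'   events within and across channels, in ms.
#' @param at_inc_noise_factor multiplier mapping the local noise band to the
#'   amplitude inclusion threshold (default 8).
#' @param at_exc_uv amplitude exclusion threshold in uV driving noisy-block
#'   rejection (default 100).
#' @param noise_block_s duration of the noisy-block tiling in seconds.
#' @param noise_window_s width of each flanking noise-band window in seconds.
#' @param avid_strategy voluntary-exclusion strategy: `"0"` (disabled),
#'   `"1A"` (sensitive, 10 s blocks), `"1B"` (1A plus classifier rescue of
#'   false positives) or `"2"` (specific, 1 s blocks).
#' @param avid_block_sensitive_s,avid_block_specific_s block durations of the
#'   sensitive and specific strategies, in seconds.
#' @param train_min_potentials minimum run length of a voluntary train.
#' @param train_max_isi_ms strict upper bound on each consecutive inter-spike
#'   interval within a voluntary train, in ms.
#' @param feature_band_ms closed interval band, in ms, for the two band-limited
#'   interval features (default 84--250 ms, i.e. 4--12 Hz firing).
#' @param mode_bin_ms bin width used for the interval mode feature, in ms.
#' @param n_trees number of bagged trees in the block classifier.
#' @param cv_folds folds of the stratified cross-validation.
#' @param null_channel_sd_uv channels with standard deviation below this are
#'   treated as null (no electrical contact).
#' @param qc_z z-score bound of the per-metric channel exclusion interval
#'   (1.96 ~ a 95% interval).
#' @param rng_seed single integer seed governing classifier bagging and any
#'   simulation launched from this configuration; echoed in every summary.
#'
#' @return An object of class `fq_config` (a validated named list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$at_inc_noise_factor
#' @export
pipeline_config <- function(bandpass_low_hz = 20,
                            bandpass_high_hz = 500,
                            notch_hz = 50,
                            perimeter_trim = TRUE,
                            common_average_reference = FALSE,
                            qc_before_filtering = TRUE,
                            extreme_occupancy_fraction = 0.02,
                            occupancy_split = 0.5,
                            event_pad_ms = 10,
                            at_inc_noise_factor = 8,
                            at_exc_uv = 100,
                            noise_block_s = 5,
                            noise_window_s = 1,
                            avid_strategy = c("0", "1A", "1B", "2"),
                            avid_block_sensitive_s = 10,
                            avid_block_specific_s = 1,
                            train_min_potentials = 4,
                            train_max_isi_ms = 250,
                            feature_band_ms = c(84, 250),
                            mode_bin_ms = 10,
                            n_trees = 30,
                            cv_folds = 5,
                            null_channel_sd_uv = 0.01,
                            qc_z = 1.96,
                            rng_seed = 1L) {
  avid_strategy <- match.arg(as.character(avid_strategy), c("0", "1A", "1B", "2"))
  cfg <- list(
    bandpass_low_hz = as.numeric(bandpass_low_hz),
    bandpass_high_hz = as.numeric(bandpass_high_hz),
    notch_hz = as.numeric(notch_hz),
    perimeter_trim = isTRUE(perimeter_trim),
    common_average_reference = isTRUE(common_average_reference),
    qc_before_filtering = isTRUE(qc_before_filtering),
    extreme_occupancy_fraction = as.numeric(extreme_occupancy_fraction),
    occupancy_split = as.numeric(occupancy_split),
    event_pad_ms = as.numeric(event_pad_ms),
    at_inc_noise_factor = as.numeric(at_inc_noise_factor),
    at_exc_uv = as.numeric(at_exc_uv),
    noise_block_s = as.numeric(noise_block_s),
    noise_window_s = as.numeric(noise_window_s),
    avid_strategy = avid_strategy,
    avid_block_sensitive_s = as.numeric(avid_block_sensitive_s),
    avid_block_specific_s = as.numeric(avid_block_specific_s),
    train_min_potentials = as.integer(train_min_potentials),
    train_max_isi_ms = as.numeric(train_max_isi_ms),
    feature_band_ms = as.numeric(feature_band_ms),
    mode_bin_ms = as.numeric(mode_bin_ms),
    n_trees = as.integer(n_trees),
    cv_folds = as.integer(cv_folds),
    null_channel_sd_uv = as.numeric(null_channel_sd_uv),
    qc_z = as.numeric(qc_z),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "fq_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  num_pos <- c("bandpass_low_hz", "bandpass_high_hz", "notch_hz",
               "extreme_occupancy_fraction", "event_pad_ms",
               "at_inc_noise_factor", "at_exc_uv",
               "noise_block_s", "noise_window_s", "avid_block_sensitive_s",
               "avid_block_specific_s", "train_min_potentials",
               "train_max_isi_ms", "mode_bin_ms", "n_trees", "cv_folds",
               "qc_z")
  for (f in num_pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("config field '", f, "' must be a single strictly positive number",
           call. = FALSE)
    }
  }
  if (cfg$bandpass_low_hz >= cfg$bandpass_high_hz) {
    stop("bandpass_low_hz must be below bandpass_high_hz", call. = FALSE)
  }
  if (length(cfg$feature_band_ms) != 2L || cfg$feature_band_ms[1] >= cfg$feature_band_ms[2]) {
    stop("feature_band_ms must be an increasing pair", call. = FALSE)
  }
  if (cfg$occupancy_split <= 0 || cfg$occupancy_split >= 1) {
    stop("occupancy_split must lie strictly between 0 and 1", call. = FALSE)
  }
  if (cfg$null_channel_sd_uv < 0) stop("null_channel_sd_uv must be >= 0", call. = FALSE)
  invisible(cfg)
}

#' @export
print.fq_config <- function(x, ...) {
  cat("<fq_config>\n")
  cat(sprintf("  band-pass %g-%g Hz, notch %g Hz\n",
              x$bandpass_low_hz, x$bandpass_high_hz, x$notch_hz))
  cat(sprintf("  inclusion threshold %gx noise band; exclusion threshold %g uV over %g s blocks\n",
              x$at_inc_noise_factor, x$at_exc_uv, x$noise_block_s))
  cat(sprintf("  voluntary strategy %s (train >= %d potentials, ISI < %g ms)\n",
              x$avid_strategy, x$train_min_potentials, x$train_max_isi_ms))
  cat(sprintf("  seed %d\n", x$rng_seed))
  invisible(x)
}

#' Write / read a configuration as JSON
#'
#' The on-disk representation round-trips exactly: every field is restored
#' with its original type and value.
#'
#' @param config an [pipeline_config()] object.
#' @param path file path.
#' @return `read_config()` returns an `fq_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "fq_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}
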