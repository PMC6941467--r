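#' Run the full fasciculation-quantification pipeline
#'
#' Executes, in order: optional common-average re-referencing, perimeter
#' trimming, automated bad-channel exclusion, band-pass/notch filtering,
#' potential detection (screening, super-channel, noise bands, inclusion
#' threshold), 5-second noisy-block exclusion, the configured
#' voluntary-exclusion strategy, and summary metrics. The run is
#' deterministic given `config$rng_seed` (which is echoed in the summary).
#'
#' The stage order is fixed: noisy-block exclusion runs before voluntary
#' labelling, so artefact spikes cannot form spurious "trains"; the
#' voluntary stage sees only the surviving potentials.
#'
#' @param recording a [grid_recording()].
#' @param config a [pipeline_config()].
#' @param classifier an [train_classifier()] object (required when
#'   `config$avid_strategy == "1B"`).
#' @return An object of class `fq_result`: list with `summary` (one-row data
#'   frame), `potentials`, `noise_blocks`, `avid_blocks`, `quality` (channel
#'   QC report), `config`.
#' @examples
#' \donttest{
#' fx <- make_fixture_suite("relaxed", duration_s = 20, seed = 1)
#' res <- run_pipeline(fx$recording, pipeline_config(avid_strategy = "0"))
#' res$summary$fasciculation_frequency_per_min
#' }
#' @export
run_pipeline <- function(recording, config = pipeline_config(),
                         classifier = NULL) {
  stopifnot(inherits(recording, "grid_recording"))
  validate_config(config)
  if (config$avid_strategy == "1B" && !inherits(classifier, "fq_classifier")) {
    stop("strategy 1B requires a trained classifier", call. = FALSE)
  }

  rec <- recording
  if (config$common_average_reference) rec <- common_average_reference(rec)
  if (config$perimeter_trim && rec$grid_rows >= 3 && rec$grid_cols >= 3) {
    rec <- trim_to_central_grid(rec)
  }

  quality <- NULL
  if (config$qc_before_filtering) {
    qc <- exclude_bad_channels(rec, config)
    rec <- qc$recording
    quality <- qc$report
    rec <- bandpass_notch(rec, config)
  } else {
    rec <- bandpass_notch(rec, config)
    qc <- exclude_bad_channels(rec, config)
    rec <- qc$recording
    quality <- qc$report
  }

  det <- detect_potentials(rec, config)
  pots <- det$potentials
  noise_blocks <- det$noise_blocks

  noise_intervals <- noise_blocks[noise_blocks$excluded,
                                  c("start_s", "end_s"), drop = FALSE]
  av <- apply_strategy(pots, rec$duration_s, config$avid_strategy, config,
                       classifier = classifier,
                       noise_intervals = noise_intervals)
  pots <- av$potentials

  dur_min <- rec$duration_s / 60
  t_noise_min <- sum(noise_intervals$end_s - noise_intervals$start_s) / 60
  t_avid_min <- av$excluded_time_s / 60
  t_analysed_min <- dur_min - t_noise_min - t_avid_min
  n_inc <- sum(pots$included)

  summary <- data.frame(
    time_analysed_min = t_analysed_min,
    time_excluded_noise_min = t_noise_min,
    time_excluded_avid_min = t_avid_min,
    n_potentials_included = n_inc,
    fasciculation_frequency_per_min = fasciculation_frequency(n_inc, t_analysed_min),
    median_noise_band_uv = suppressWarnings(median_noise(pots)),
    n_channels_excluded = sum(quality$excluded),
    strategy_used = config$avid_strategy,
    rng_seed = config$rng_seed
  )
  structure(list(summary = summary, potentials = pots,
                 noise_blocks = noise_blocks, avid_blocks = av$blocks,
                 quality = quality, config = config),
            class = "fq_result")
}

#' @export
print.fq_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<fq_result> strategy %s\n", s$strategy_used))
  cat(sprintf("  analysed %.2f min (noise-excluded %.2f, voluntary-excluded %.2f)\n",
              s$time_analysed_min, s$time_excluded_noise_min,
              s$time_excluded_avid_min))
  cat(sprintf("  %d potentials included -> %.1f per min; median noise %.2f uV; %d channels excluded\n",
              s$n_potentials_included, s$fasciculation_frequency_per_min,
              s$median_noise_band_uv, s$n_channels_excluded))
  invisible(x)
}
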