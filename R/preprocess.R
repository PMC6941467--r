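#' Band-pass and notch filtering
#'
#' Applies a 20--500 Hz band-pass (4th-order Butterworth high-pass and
#' low-pass, each run forward--backward for zero phase) and a 50 Hz IIR notch
#' of quality factor 30 to every channel. Zero-phase filtering guarantees no
#' systematic shift of spike times.
#'
#' @param recording a [grid_recording()].
#' @param config a [pipeline_config()].
#' @return The filtered recording (same shape and metadata).
#' @export
bandpass_notch <- function(recording, config = pipeline_config()) {
  stopifnot(inherits(recording, "grid_recording"))
  fs <- recording$sampling_rate
  if (fs <= 2 * config$bandpass_high_hz) {
    stop("sampling rate ", fs, " Hz is too low for a band-pass up to ",
         config$bandpass_high_hz, " Hz", call. = FALSE)
  }
  hp <- signal::butter(4, config$bandpass_low_hz / (fs / 2), type = "high")
  lp <- signal::butter(4, config$bandpass_high_hz / (fs / 2), type = "low")
  nt <- notch_coefficients(config$notch_hz, fs, q = 30)
  sig <- recording$signal
  for (j in seq_len(ncol(sig))) {
    x <- signal::filtfilt(hp, sig[, j])
    x <- signal::filtfilt(lp, x)
    x <- signal::filtfilt(nt, x)
    sig[, j] <- x
  }
  out <- recording
  out$signal <- sig
  out
}

## Standard biquad notch (RBJ audio-EQ cookbook design).
notch_coefficients <- function(f0, fs, q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b = b / a[1], a = a / a[1])
}

#' Re-reference to the common average
#'
#' Subtracts, at each sample, the mean across all retained channels. Optional:
#' grid amplifiers normally reference against the average of all connected
#' unipolar inputs in hardware, so this is off by default in the pipeline.
#'
#' @param recording a [grid_recording()].
#' @return The re-referenced recording.
#' @export
common_average_reference <- function(recording) {
  stopifnot(inherits(recording, "grid_recording"))
  out <- recording
  out$signal <- recording$signal - rowMeans(recording$signal)
  out
}

#' Discard the outer perimeter of grid channels
#'
#' Perimeter electrodes often suffer poor skin contact, so the pipeline keeps
#' only the interior of the grid: channels with grid row in `[2, rows - 1]`
#' and column in `[2, cols - 1]` (1-based). An 8x8 grid reduces to the central
#' 36 channels (6x6).
#'
#' @param recording a [grid_recording()].
#' @return The trimmed recording; channel ids are preserved.
#' @export
trim_to_central_grid <- function(recording) {
  stopifnot(inherits(recording, "grid_recording"))
  if (recording$grid_rows < 3 || recording$grid_cols < 3) {
    stop("grid must be at least 3x3 to trim its perimeter", call. = FALSE)
  }
  pos <- recording$channel_positions
  keep <- pos$channel[pos$row >= 2 & pos$row <= recording$grid_rows - 1 &
                        pos$col >= 2 & pos$col <= recording$grid_cols - 1]
  subset_channels(recording, keep)
}

#' Automated bad-channel exclusion
#'
#' Flags channels that are null (flat, absent contact) or whose FFT
#' area-under-the-curve or amplitude range is an outlier among the channels.
#' The AUC is the sum of the one-sided FFT magnitude spectrum over the
#' analysis band (`bandpass_low_hz`--`bandpass_high_hz`); a channel is
#' excluded when either metric falls outside mean +/- `qc_z` * SD across the
#' non-null channels (1.96 ~ the 95% interval), or when its standard
#' deviation is below `null_channel_sd_uv`.
#'
#' @param recording a [grid_recording()] (normally unfiltered, so drift and
#'   line interference stay visible to the spectral metric).
#' @param config a [pipeline_config()].
#' @return A list with `recording` (surviving channels, original ids kept)
#'   and `report`, a data frame with one row per input channel: `channel`,
#'   `row`, `col`, `fft_auc`, `amplitude_range_uv`, `excluded`, `reason`
#'   (`null_channel`, `range_outlier` or `fft_auc_outlier`).
#' @export
exclude_bad_channels <- function(recording, config = pipeline_config()) {
  stopifnot(inherits(recording, "grid_recording"))
  sig <- recording$signal
  nch <- ncol(sig)
  if (nch < 8) {
    stop("channel quality control needs at least 8 channels", call. = FALSE)
  }
  fs <- recording$sampling_rate
  n <- nrow(sig)
  freqs <- (seq_len(n) - 1) * fs / n
  band <- freqs >= config$bandpass_low_hz & freqs <= config$bandpass_high_hz

  fft_auc <- numeric(nch)
  rng <- numeric(nch)
  sds <- numeric(nch)
  for (j in seq_len(nch)) {
    x <- sig[, j]
    fft_auc[j] <- sum(Mod(fft(x))[band])
    rng[j] <- max(x) - min(x)
    sds[j] <- sd(x)
  }
  is_null <- sds < config$null_channel_sd_uv

  zscore <- function(v) {
    ref <- v[!is_null]
    if (length(ref) < 2L || sd(ref) == 0) return(rep(0, length(v)))
    (v - mean(ref)) / sd(ref)
  }
  z_auc <- zscore(fft_auc)
  z_rng <- zscore(rng)

  reason <- rep(NA_character_, nch)
  reason[abs(z_auc) > config$qc_z] <- "fft_auc_outlier"
  reason[abs(z_rng) > config$qc_z] <- "range_outlier"
  reason[is_null] <- "null_channel"
  excluded <- !is.na(reason)
  if (all(excluded)) stop("recording unanalysable: all channels excluded",
                          call. = FALSE)

  pos <- recording$channel_positions
  report <- data.frame(
    channel = pos$channel, row = pos$row, col = pos$col,
    fft_auc = fft_auc, amplitude_range_uv = rng,
    excluded = excluded, reason = reason
  )
  list(recording = subset_channels(recording, pos$channel[!excluded]),
       report = report)
}
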