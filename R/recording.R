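#' Grid surface-EMG recording
#'
#' Container for a multichannel grid EMG signal. Amplitudes are stored in
#' microvolts as a samples x channels matrix together with the sampling rate,
#' the electrode-grid geometry and a (possibly partial, if channels were
#' dropped) map from channel id to grid position.
#'
#' @param signal numeric matrix, one row per sample, one column per channel,
#'   amplitudes in uV. All values must be finite.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param grid_rows,grid_cols electrode grid dimensions.
#' @param channel_positions data frame with columns `channel`, `row`, `col`
#'   (1-based grid coordinates), one row per signal column, in column order.
#'   Defaults to row-major numbering of the full grid.
#' @param meta free-form list of acquisition annotations.
#'
#' @return An object of class `grid_recording` with fields `signal`,
#'   `sampling_rate`, `grid_rows`, `grid_cols`, `channel_positions`,
#'   `duration_s` and `meta`.
#' @examples
#' rec <- grid_recording(matrix(rnorm(2048 * 4), ncol = 4), 2048, 2, 2)
#' rec$duration_s
#' @export
grid_recording <- function(signal, sampling_rate, grid_rows, grid_cols,
                           channel_positions = NULL, meta = list()) {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (nrow(signal) == 0L || ncol(signal) == 0L) {
    stop("recording must contain at least one sample and one channel", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number", call. = FALSE)
  }
  bad <- which(!is.finite(signal))
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(signal))
    stop(sprintf("non-finite amplitude at sample %d, channel %d",
                 ij[1L], ij[2L]), call. = FALSE)
  }
  if (is.null(channel_positions)) {
    if (ncol(signal) != grid_rows * grid_cols) {
      stop("channel count does not match grid_rows x grid_cols; ",
           "supply channel_positions for a partial grid", call. = FALSE)
    }
    channel_positions <- data.frame(
      channel = seq_len(grid_rows * grid_cols),
      row = rep(seq_len(grid_rows), each = grid_cols),
      col = rep(seq_len(grid_cols), times = grid_rows)
    )
  }
  channel_positions <- as.data.frame(channel_positions)
  stopifnot(all(c("channel", "row", "col") %in% names(channel_positions)))
  if (nrow(channel_positions) != ncol(signal)) {
    stop("channel_positions must have one row per signal column", call. = FALSE)
  }
  colnames(signal) <- sprintf("ch%03d", channel_positions$channel)
  structure(
    list(
      signal = signal,
      sampling_rate = sampling_rate,
      grid_rows = as.integer(grid_rows),
      grid_cols = as.integer(grid_cols),
      channel_positions = channel_positions,
      duration_s = nrow(signal) / sampling_rate,
      meta = meta
    ),
    class = "grid_recording"
  )
}

#' @export
print.grid_recording <- function(x, ...) {
  cat(sprintf("<grid_recording> %d channels (%dx%d grid), %.3f s at %g Hz\n",
              ncol(x$signal), x$grid_rows, x$grid_cols, x$duration_s,
              x$sampling_rate))
  invisible(x)
}

n_samples <- function(rec) nrow(rec$signal)
n_channels <- function(rec) ncol(rec$signal)

## Restrict a recording to a subset of channel ids, preserving ids.
subset_channels <- function(rec, keep_channels) {
  sel <- rec$channel_positions$channel %in% keep_channels
  if (!any(sel)) stop("no channels left after subsetting", call. = FALSE)
  grid_recording(rec$signal[, sel, drop = FALSE], rec$sampling_rate,
                 rec$grid_rows, rec$grid_cols,
                 rec$channel_positions[sel, , drop = FALSE], rec$meta)
}

unit_scale <- function(units) {
  switch(tolower(units),
         "uv" = , "µv" = , "μv" = 1,
         "mv" = 1e3,
         "v"  = 1e6,
         stop("unknown amplitude units '", units, "'", call. = FALSE))
}

#' Read a grid recording from disk
#'
#' Two formats are supported: a documented plain matrix format (a single-line
#' JSON header followed by a tab-separated body, one row per sample) and
#' continuous 16-bit EDF. Amplitudes are converted to uV using the units
#' declared in the header.
#'
#' @param path input file.
#' @param format_hint `"auto"` (sniff the first byte), `"matrix"` or `"edf"`.
#' @return A [grid_recording()].
#' @export
read_recording <- function(path, format_hint = c("auto", "matrix", "edf")) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format_hint == "auto") {
    first <- readBin(path, "raw", n = 1L)
    format_hint <- if (length(first) && rawToChar(first) == "{") "matrix" else "edf"
  }
  switch(format_hint,
         matrix = read_recording_matrix(path),
         edf = read_recording_edf(path))
}

#' Write a grid recording to disk
#'
#' The matrix format is lossless (full double precision); EDF quantises to
#' 16 bits over each channel's amplitude range, as acquisition hardware does.
#'
#' @param recording a [grid_recording()].
#' @param path output file.
#' @param format `"matrix"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, format = c("matrix", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(recording, "grid_recording"))
  switch(format,
         matrix = write_recording_matrix(recording, path),
         edf = write_recording_edf(recording, path))
  invisible(path)
}

## ---- matrix format: JSON header line + TSV body -------------------------

read_recording_matrix <- function(path) {
  con <- file(path, "r")
  header_line <- readLines(con, n = 1L)
  close(con)
  hdr <- tryCatch(jsonlite::fromJSON(header_line),
                  error = function(e) stop("unreadable matrix header: ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(hdr$sampling_rate)) stop("header is missing sampling_rate", call. = FALSE)
  body <- data.table::fread(path, skip = 1L, header = FALSE, sep = "\t")
  sig <- as.matrix(body)
  scale <- unit_scale(if (is.null(hdr$units)) "uV" else hdr$units)
  sig <- sig * scale
  pos <- as.data.frame(hdr$channels)
  grid_recording(sig, hdr$sampling_rate, hdr$grid_rows, hdr$grid_cols,
                 channel_positions = pos,
                 meta = if (is.null(hdr$meta)) list() else as.list(hdr$meta))
}

write_recording_matrix <- function(rec, path) {
  hdr <- list(
    format = "gridemg-matrix", version = 1L,
    sampling_rate = rec$sampling_rate,
    grid_rows = rec$grid_rows, grid_cols = rec$grid_cols,
    units = "uV",
    channels = rec$channel_positions,
    meta = rec$meta
  )
  header_line <- jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA,
                                  dataframe = "columns")
  writeLines(as.character(header_line), path)
  data.table::fwrite(data.table::as.data.table(rec$signal), path,
                     append = TRUE, sep = "\t", col.names = FALSE)
  invisible(path)
}

## ---- EDF: minimal continuous reader/writer ------------------------------
## Fixed-layout 256-byte header + 256 bytes per signal, 16-bit little-endian
## samples. One data record holding the whole signal keeps arbitrary
## durations legal. Grid geometry travels in the 44-byte reserved field.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too wide: '", x, "'", call. = FALSE)
  formatC(x, width = -width, flag = " ")
}

write_recording_edf <- function(rec, path) {
  ns <- n_channels(rec)
  n <- n_samples(rec)
  pmin <- apply(rec$signal, 2, min)
  pmax <- apply(rec$signal, 2, max)
  flat <- pmax - pmin < 1e-9
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  fmt8 <- function(v) vapply(v, function(z) {
    s <- formatC(z, format = "g", digits = 6, width = -1)
    if (nchar(s) > 8) s <- formatC(z, format = "g", digits = 3, width = -1)
    s
  }, character(1))
  pmin_s <- fmt8(pmin); pmax_s <- fmt8(pmax)
  pmin_v <- as.numeric(pmin_s); pmax_v <- as.numeric(pmax_s)
  pmin_v <- pmin(pmin_v, pmin); pmax_v <- pmax(pmax_v, pmax)
  pmin_s <- fmt8(pmin_v); pmax_s <- fmt8(pmax_v)
  pmin_v <- as.numeric(pmin_s); pmax_v <- as.numeric(pmax_s)

  dig_min <- -32768L; dig_max <- 32767L
  header_bytes <- 256L + 256L * ns
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edf_pad(x, width), con, nchars = width, eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)
  wr("Startdate 01-JAN-2026 X fasctools synthetic", 80)
  wr("01.01.26", 8)
  wr("00.00.00", 8)
  wr(header_bytes, 8)
  wr(sprintf("grid %dx%d", rec$grid_rows, rec$grid_cols), 44)
  wr("1", 8)                                   # one data record
  wr(formatC(rec$duration_s, format = "g", digits = 7, width = -1), 8)
  wr(ns, 4)
  pos <- rec$channel_positions
  for (i in seq_len(ns)) wr(sprintf("c%03d r%02dc%02d", pos$channel[i], pos$row[i], pos$col[i]), 16)
  for (i in seq_len(ns)) wr("synthetic grid EMG", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(pmin_s[i], 8)
  for (i in seq_len(ns)) wr(pmax_s[i], 8)
  for (i in seq_len(ns)) wr(dig_min, 8)
  for (i in seq_len(ns)) wr(dig_max, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(n, 8)
  for (i in seq_len(ns)) wr("", 32)
  for (i in seq_len(ns)) {
    x <- rec$signal[, i]
    dig <- round((x - pmin_v[i]) / (pmax_v[i] - pmin_v[i]) *
                   (dig_max - dig_min) + dig_min)
    writeBin(as.integer(dig), con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  reserved <- rd(44)
  n_records <- as.integer(rd(8))
  record_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("unreadable EDF header", call. = FALSE)
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  units <- vapply(seq_len(ns), function(i) rd(8), character(1))
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  nsamp <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)

  total <- sum(nsamp)
  sig <- matrix(0, nrow = nsamp[1L], ncol = ns)
  if (length(unique(nsamp)) != 1L) {
    stop("EDF signals with differing sampling rates are not supported", call. = FALSE)
  }
  sig <- matrix(0, nrow = nsamp[1L] * n_records, ncol = ns)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = nsamp[i], size = 2L,
                     endian = "little", signed = TRUE)
      phys <- (dig - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i]) + pmin[i]
      sig[(r - 1L) * nsamp[i] + seq_len(nsamp[i]), i] <- phys
    }
  }
  fs <- nsamp[1L] / record_dur
  for (i in seq_len(ns)) sig[, i] <- sig[, i] * unit_scale(units[i])

  gm <- regmatches(reserved, regexec("grid ([0-9]+)x([0-9]+)", reserved))[[1L]]
  lm_ <- regmatches(labels, regexec("c([0-9]+) r([0-9]+)c([0-9]+)", labels))
  parsed <- all(lengths(lm_) == 4L)
  if (length(gm) == 3L && parsed) {
    pos <- data.frame(
      channel = as.integer(vapply(lm_, `[`, character(1), 2L)),
      row = as.integer(vapply(lm_, `[`, character(1), 3L)),
      col = as.integer(vapply(lm_, `[`, character(1), 4L))
    )
    grid_recording(sig, fs, as.integer(gm[2L]), as.integer(gm[3L]),
                   channel_positions = pos)
  } else {
    # foreign EDF: fall back to a 1 x ns "grid"
    grid_recording(sig, fs, 1L, ns)
  }
}
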