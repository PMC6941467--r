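#' Per-channel extreme-amplitude screening
#'
#' Places, on each channel, a positive threshold at the `1 - f * split`
#' amplitude quantile and a negative threshold at the `f * (1 - split)`
#' quantile (with `f` the extreme-occupancy fraction, default 2% split
#' equally), so that strictly supra-/sub-threshold samples occupy less than
#' `f` of the channel. Contiguous threshold-crossing runs are merged into
#' candidate events when their 10 ms-padded spans touch.
#'
#' @param recording a filtered [grid_recording()].
#' @param config a [pipeline_config()].
#' @return A data frame of candidate events: `channel`, `start`, `end`
#'   (half-open 1-based sample interval). Thresholds per channel are attached
#'   as attribute `"thresholds"`.
#' @export
screen_potentials <- function(recording, config = pipeline_config()) {
  stopifnot(inherits(recording, "grid_recording"))
  sig <- recording$signal
  fs <- recording$sampling_rate
  f <- config$extreme_occupancy_fraction
  pad <- round(config$event_pad_ms / 1000 * fs)
  pos <- recording$channel_positions$channel
  out <- vector("list", ncol(sig))
  thr <- data.frame(channel = pos, pos_uv = NA_real_, neg_uv = NA_real_)
  for (j in seq_len(ncol(sig))) {
    x <- sig[, j]
    if (max(x) == min(x)) {
      warning("channel ", pos[j], " is constant; no events screened",
              call. = FALSE)
      next
    }
    ## type-1 (inverse-CDF) quantiles guarantee that strict crossings occupy
    ## at most the budgeted fraction of samples
    hi <- quantile(x, 1 - f * config$occupancy_split, names = FALSE, type = 1)
    lo <- quantile(x, f * (1 - config$occupancy_split), names = FALSE, type = 1)
    thr$pos_uv[j] <- hi
    thr$neg_uv[j] <- lo
    supra <- x > hi | x < lo
    if (!any(supra)) next
    runs <- run_bounds(supra)
    merged <- merge_spans(runs$start, runs$end, gap = 2L * pad)
    out[[j]] <- data.frame(channel = pos[j],
                           start = merged$start, end = merged$end)
  }
  ev <- do.call(rbind, out)
  if (is.null(ev)) ev <- data.frame(channel = integer(0), start = integer(0),
                                    end = integer(0))
  attr(ev, "thresholds") <- thr
  ev
}

## start/end (half-open) of TRUE runs in a logical vector
run_bounds <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  list(start = starts[keep], end = ends[keep] + 1L)
}

## merge half-open spans whose gaps are below `gap` samples
merge_spans <- function(start, end, gap) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1L]; me <- end[1L]
  outs <- integer(0); oute <- integer(0)
  for (i in seq_along(start)[-1L]) {
    if (start[i] - me < gap) {
      me <- max(me, end[i])
    } else {
      outs <- c(outs, ms); oute <- c(oute, me)
      ms <- start[i]; me <- end[i]
    }
  }
  list(start = c(outs, ms), end = c(oute, me))
}

#' Assemble the super-channel
#'
#' Collapses per-channel candidate events into a single-dimensional sequence
#' of potentials. Assembly is seeded by amplitude: the as-yet-unclaimed event
#' with the greatest peak-trough amplitude anchors a potential, claims every
#' event whose 10 ms-padded span overlaps its own (the same discharge seen on
#' other channels, including long filter-tail events on low-threshold
#' channels), and the process repeats with the next-largest unclaimed event.
#' Claiming is deliberately non-transitive — events are only merged through a
#' dominant seed, never chained event-to-event — so coincidental noise
#' crossings on many independent channels cannot coalesce into arbitrarily
#' long pseudo-potentials. Each potential is sourced from the contributing
#' channel with the greatest peak-trough amplitude within its span.
#'
#' @param recording the filtered [grid_recording()] the events came from.
#' @param events candidate events from [screen_potentials()].
#' @param config a [pipeline_config()].
#' @return An object of class `superchannel`: a list with `potentials` (a
#'   data frame with `peak_time_s`, `span_start`, `span_end`, `channel`,
#'   `peak_uv`, `trough_uv`, `p2t_uv`, ordered by time with non-overlapping
#'   spans) and `duration_s`.
#' @export
build_superchannel <- function(recording, events, config = pipeline_config()) {
  stopifnot(inherits(recording, "grid_recording"))
  fs <- recording$sampling_rate
  pad <- round(config$event_pad_ms / 1000 * fs)
  n <- n_samples(recording)
  empty <- data.frame(peak_time_s = numeric(0), span_start = integer(0),
                      span_end = integer(0), channel = integer(0),
                      peak_uv = numeric(0), trough_uv = numeric(0),
                      p2t_uv = numeric(0))
  if (is.null(events) || nrow(events) == 0L) {
    return(structure(list(potentials = empty,
                          duration_s = recording$duration_s),
                     class = "superchannel"))
  }
  ev <- events
  ev$end <- pmin(ev$end, n + 1L)
  chan_idx <- match(ev$channel, recording$channel_positions$channel)

  ## per-event peak-trough amplitude on the event's own channel
  ev$p2t <- vapply(seq_len(nrow(ev)), function(i) {
    x <- recording$signal[ev$start[i]:(ev$end[i] - 1L), chan_idx[i]]
    max(x) - min(x)
  }, numeric(1))

  ## deterministic seed order: amplitude, then time, then channel
  ord <- order(-ev$p2t, ev$start, ev$channel)
  active <- rep(TRUE, nrow(ev))
  starts <- ev$start; ends <- ev$end
  out <- vector("list", nrow(ev))
  n_out <- 0L
  for (i in ord) {
    if (!active[i]) next
    ## the seed's claim anchor is its quarter-amplitude core around the peak,
    ## not its full suprathreshold run: a large discharge stays suprathreshold
    ## for ~100 ms through its filter tails, and anchoring on the full run
    ## would swallow a separate neighbouring discharge
    x <- recording$signal[starts[i]:(ends[i] - 1L), chan_idx[i]]
    ax <- abs(x)
    pk <- which.max(ax)
    quarter <- ax[pk] / 4
    cs <- pk; while (cs > 1L && ax[cs - 1L] >= quarter) cs <- cs - 1L
    ce <- pk; while (ce < length(ax) && ax[ce + 1L] >= quarter) ce <- ce + 1L
    cs <- starts[i] + cs - 1L           # core start (sample index)
    ce <- starts[i] + ce                # core end, half-open
    claim <- which(active & starts < ce + 2L * pad & ends > cs - 2L * pad)
    active[claim] <- FALSE
    ## span: core extended by claimed events but never past the core's padded
    ## neighbourhood (distant tails are claimed and consumed, not concatenated)
    span_s <- max(min(c(starts[claim], cs)), cs - 2L * pad, 1L)
    span_e <- min(max(c(ends[claim], ce)), ce + 2L * pad, n + 1L)
    n_out <- n_out + 1L
    out[[n_out]] <- list(span_s, span_e, sort(unique(chan_idx[claim])))
  }
  out <- out[seq_len(n_out)]

  ## time order + clip any residual span overlap from tail extensions
  out <- out[order(vapply(out, `[[`, numeric(1), 1L))]
  prev_end <- 0L
  pots <- vector("list", length(out))
  for (k in seq_along(out)) {
    s <- max(out[[k]][[1L]], prev_end)
    e <- out[[k]][[2L]]
    if (e <= s) next
    prev_end <- e
    chans <- out[[k]][[3L]]
    seg <- recording$signal[s:(e - 1L), chans, drop = FALSE]
    p2t <- apply(seg, 2, function(v) max(v) - min(v))
    best <- chans[which.max(p2t)]
    x <- recording$signal[s:(e - 1L), best]
    peak_at <- s - 1L + which.max(abs(x))
    pots[[k]] <- data.frame(peak_time_s = (peak_at - 1L) / fs,
                            span_start = s, span_end = e,
                            channel = recording$channel_positions$channel[best],
                            peak_uv = max(x), trough_uv = min(x),
                            p2t_uv = max(p2t))
  }
  pots <- do.call(rbind, pots)
  pots <- pots[order(pots$peak_time_s), , drop = FALSE]
  rownames(pots) <- NULL
  structure(list(potentials = pots, duration_s = recording$duration_s),
            class = "superchannel")
}

#' @export
print.superchannel <- function(x, ...) {
  cat(sprintf("<superchannel> %d candidate potentials over %.1f s\n",
              nrow(x$potentials), x$duration_s))
  invisible(x)
}

#' Local noise band around one potential
#'
#' The noise band is the mean positive amplitude minus the mean negative
#' amplitude over the one-second windows immediately before and after the
#' potential's span, on its source channel. Windows are truncated at the
#' recording edges, samples falling inside any other potential's span are
#' removed, and an empty sign class contributes zero. If the whole window is
#' empty the noise band is undefined (`NA`).
#'
#' @param recording the filtered [grid_recording()].
#' @param span_start,span_end the potential's half-open sample span.
#' @param channel source channel id.
#' @param other_spans optional two-column matrix/data frame of other
#'   potentials' `span_start`, `span_end` to mask out.
#' @param config a [pipeline_config()].
#' @return Noise band in uV (>= 0), or `NA` if undefined.
#' @export
compute_noise_band <- function(recording, span_start, span_end, channel,
                               other_spans = NULL,
                               config = pipeline_config()) {
  mask <- logical(n_samples(recording))
  if (!is.null(other_spans) && nrow(other_spans) > 0L) {
    for (i in seq_len(nrow(other_spans))) {
      s <- max(1L, other_spans[[1L]][i])
      e <- min(n_samples(recording) + 1L, other_spans[[2L]][i])
      if (s < e) mask[s:(e - 1L)] <- TRUE
    }
    mask[span_start:(span_end - 1L)] <- FALSE
  }
  noise_band_from_mask(recording, span_start, span_end, channel, mask, config)
}

noise_band_from_mask <- function(recording, span_start, span_end, channel,
                                 mask, config) {
  w <- round(config$noise_window_s * recording$sampling_rate)
  n <- n_samples(recording)
  pre <- seq.int(max(1L, span_start - w), span_start - 1L)
  pre <- pre[pre >= 1L & pre <= n]
  post <- seq.int(span_end, min(n, span_end + w - 1L))
  post <- post[post >= span_end]
  idx <- c(pre, post)
  idx <- idx[!mask[idx]]
  if (!length(idx)) return(NA_real_)
  j <- match(channel, recording$channel_positions$channel)
  x <- recording$signal[idx, j]
  mp <- if (any(x > 0)) mean(x[x > 0]) else 0
  mn <- if (any(x < 0)) mean(x[x < 0]) else 0
  mp - mn
}

#' Annotate every potential with its noise band
#'
#' Vectorised driver of [compute_noise_band()] over a super-channel: a global
#' span mask is built once and each potential's flanking windows exclude all
#' other potentials' spans.
#'
#' @param recording the filtered [grid_recording()].
#' @param superchannel a [build_superchannel()] result.
#' @param config a [pipeline_config()].
#' @return The `superchannel` with a `noise_band_uv` column added.
#' @export
annotate_noise_bands <- function(recording, superchannel,
                                 config = pipeline_config()) {
  pots <- superchannel$potentials
  mask <- logical(n_samples(recording))
  for (i in seq_len(nrow(pots))) {
    mask[pots$span_start[i]:(pots$span_end[i] - 1L)] <- TRUE
  }
  nb <- numeric(nrow(pots))
  for (i in seq_len(nrow(pots))) {
    s <- pots$span_start[i]; e <- pots$span_end[i]
    own <- s:(e - 1L)
    mask[own] <- FALSE
    nb[i] <- noise_band_from_mask(recording, s, e, pots$channel[i], mask, config)
    mask[own] <- TRUE
  }
  superchannel$potentials$noise_band_uv <- nb
  superchannel
}

#' Median noise output of a recording
#'
#' The median of all defined per-potential noise bands; the median (not the
#' mean) is used because occasional large positive outliers would otherwise
#' dominate. With an even count the usual midpoint convention applies.
#'
#' @param potentials data frame with a `noise_band_uv` column.
#' @return Median noise band in uV, or `NA` if no potential has a defined
#'   noise band (a warning is raised).
#' @export
median_noise <- function(potentials) {
  nb <- potentials$noise_band_uv
  nb <- nb[!is.na(nb)]
  if (!length(nb)) {
    warning("no potentials with a defined noise band; median noise undefined",
            call. = FALSE)
    return(NA_real_)
  }
  median(nb)
}

#' Noise-responsive inclusion threshold
#'
#' Each potential's amplitude inclusion threshold is
#' `at_inc_noise_factor` (default 8) times its local noise band; the
#' potential is included when its peak-trough amplitude reaches the
#' threshold. Potentials with an undefined noise band are excluded.
#'
#' @param potentials data frame with `p2t_uv` and `noise_band_uv` columns.
#' @param config a [pipeline_config()].
#' @return The data frame with `at_inc_uv`, `included` and
#'   `exclusion_reason` columns added.
#' @export
apply_inclusion_threshold <- function(potentials, config = pipeline_config()) {
  at_inc <- config$at_inc_noise_factor * potentials$noise_band_uv
  undefined <- is.na(potentials$noise_band_uv)
  included <- !undefined & potentials$p2t_uv >= at_inc
  reason <- rep(NA_character_, nrow(potentials))
  reason[!undefined & !included] <- "below_at_inc"
  reason[undefined] <- "noisy_block"
  potentials$at_inc_uv <- at_inc
  potentials$included <- included
  potentials$exclusion_reason <- reason
  potentials
}

#' Five-second noisy-block exclusion
#'
#' Tiles the recording into blocks of `noise_block_s` seconds (the final
#' block may be shorter) and excludes a block when (a) the inclusion
#' threshold exceeded the exclusion threshold `at_exc_uv` for more than half
#' of the block's potentials, or (b) at least one inclusion threshold
#' exceeded double the exclusion threshold. An excluded block contributes its
#' actual duration to the excluded time and all its potentials are removed
#' from the analysis.
#'
#' @param potentials data frame from [apply_inclusion_threshold()].
#' @param duration_s recording duration in seconds.
#' @param config a [pipeline_config()].
#' @return A list with `blocks` (data frame: `index`, `start_s`, `end_s`,
#'   `n_potentials`, `excluded`, `rule_fired`) and the updated `potentials`.
#' @export
exclude_noisy_blocks <- function(potentials, duration_s,
                                 config = pipeline_config()) {
  starts <- seq(0, duration_s, by = config$noise_block_s)
  if (tail(starts, 1L) >= duration_s) starts <- head(starts, -1L)
  ends <- pmin(starts + config$noise_block_s, duration_s)
  nb <- length(starts)
  excluded <- logical(nb)
  rule <- rep(NA_character_, nb)
  npot <- integer(nb)
  bidx <- findInterval(potentials$peak_time_s, starts)
  for (b in seq_len(nb)) {
    in_b <- which(bidx == b)
    npot[b] <- length(in_b)
    at <- potentials$at_inc_uv[in_b]
    at <- at[!is.na(at)]
    if (!length(at)) next
    if (sum(at > config$at_exc_uv) > length(at) / 2) {
      excluded[b] <- TRUE
      rule[b] <- "half_above_atexc"
    } else if (any(at > 2 * config$at_exc_uv)) {
      excluded[b] <- TRUE
      rule[b] <- "any_above_double"
    }
  }
  if (any(excluded)) {
    hit <- bidx %in% which(excluded)
    potentials$included[hit] <- FALSE
    potentials$exclusion_reason[hit] <- "noisy_block"
  }
  blocks <- data.frame(index = seq_len(nb), start_s = starts, end_s = ends,
                       n_potentials = npot, excluded = excluded,
                       rule_fired = rule)
  list(blocks = blocks, potentials = potentials)
}

#' Full detection stage
#'
#' Runs screening, super-channel assembly, noise-band annotation, the
#' noise-responsive inclusion threshold and noisy-block exclusion in order.
#'
#' @param recording a filtered [grid_recording()].
#' @param config a [pipeline_config()].
#' @return A list with `potentials` (full per-potential table),
#'   `noise_blocks` and the `superchannel`.
#' @export
detect_potentials <- function(recording, config = pipeline_config()) {
  ev <- screen_potentials(recording, config)
  sc <- build_superchannel(recording, ev, config)
  sc <- annotate_noise_bands(recording, sc, config)
  pots <- apply_inclusion_threshold(sc$potentials, config)
  nz <- exclude_noisy_blocks(pots, recording$duration_s, config)
  list(potentials = nz$potentials, noise_blocks = nz$blocks,
       superchannel = sc)
}
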