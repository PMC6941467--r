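#' Parameters of the synthetic grid-EMG generator
#'
#' The generator emulates the signal content the detection pipeline must cope
#' with: fasciculation potentials firing as a homogeneous Poisson process
#' (thinned by an absolute refractory period, so inter-spike intervals are a
#' refractory-shifted exponential), voluntary motor units firing regularly at
#' 4--12 Hz inside declared epochs, optional multiplet discharges (a partner
#' spike trailing its parent by < 50 ms with identical morphology), additive
#' Gaussian noise, 50 Hz line interference, slow baseline drift and dead
#' channels. Each spike is a ~15 ms triphasic Hanning-windowed template
#' scaled across the grid by exponential spatial decay from a random
#' epicentre, reaching at least `spike_channel_footprint` channels above a
#' quarter of its peak amplitude.
#'
#' @param duration_s recording length in seconds.
#' @param sampling_rate sampling rate in Hz.
#' @param grid_rows,grid_cols electrode grid dimensions.
#' @param fasciculation_rate_per_min mean Poisson rate of fasciculation
#'   potentials, per minute.
#' @param refractory_ms absolute refractory period applied to the pooled
#'   fasciculation process and to each voluntary unit, in ms.
#' @param n_voluntary_units number of voluntary motor units.
#' @param voluntary_rate_hz mean firing rate of each voluntary unit (4--12 Hz
#'   is the physiological range at low force).
#' @param voluntary_isi_cv coefficient of variation of the multiplicative
#'   Gaussian jitter on voluntary inter-spike intervals.
#' @param voluntary_epochs list of `c(start, end)` second pairs (half-open)
#'   inside which the voluntary units fire.
#' @param multiplet_rate_per_min Poisson rate of multiplet parent discharges.
#' @param multiplet_gap_ms interval between a multiplet parent and its partner
#'   spike (must be < 50 ms).
#' @param spike_amp_uv median spike peak amplitude in uV; per-unit amplitudes
#'   scatter log-normally (sdlog `amp_sdlog`) around it.
#' @param amp_sdlog log-normal scatter of unit amplitudes.
#' @param spike_channel_footprint minimum number of channels that must see
#'   each spike above a quarter of its peak amplitude.
#' @param quarter_amp_radius grid distance (in electrode pitches) at which the
#'   spatial decay reaches a quarter of the peak; 3 guarantees a >= 10 channel
#'   footprint anywhere on an 8x8 grid.
#' @param noise_sd_uv standard deviation of the per-channel Gaussian noise.
#' @param line_noise_uv amplitude of the common 50 Hz line component.
#' @param drift_uv,drift_hz amplitude and frequency of the slow baseline
#'   drift component.
#' @param dead_channels integer channel ids to zero out (absent contact).
#' @param seed integer seed; the same parameters and seed reproduce the
#'   recording and ground truth exactly.
#'
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(duration_s = 60,
                         sampling_rate = 2048,
                         grid_rows = 8, grid_cols = 8,
                         fasciculation_rate_per_min = 40,
                         refractory_ms = 10,
                         n_voluntary_units = 0,
                         voluntary_rate_hz = 8,
                         voluntary_isi_cv = 0.12,
                         voluntary_epochs = list(),
                         multiplet_rate_per_min = 0,
                         multiplet_gap_ms = 30,
                         spike_amp_uv = 300,
                         amp_sdlog = 0.3,
                         spike_channel_footprint = 10,
                         quarter_amp_radius = 3,
                         noise_sd_uv = 2,
                         line_noise_uv = 5,
                         drift_uv = 20,
                         drift_hz = 0.5,
                         dead_channels = integer(0),
                         seed = 1L) {
  p <- as.list(environment())
  if (p$duration_s <= 0 || p$sampling_rate <= 0) {
    stop("duration_s and sampling_rate must be positive", call. = FALSE)
  }
  if (p$fasciculation_rate_per_min < 0 || p$multiplet_rate_per_min < 0) {
    stop("rates must be >= 0", call. = FALSE)
  }
  if (p$n_voluntary_units > 0 &&
      (p$voluntary_rate_hz < 4 || p$voluntary_rate_hz > 12)) {
    stop("voluntary_rate_hz must lie in [4, 12] Hz", call. = FALSE)
  }
  if (p$multiplet_gap_ms >= 50) stop("multiplet_gap_ms must be < 50 ms", call. = FALSE)
  if (p$spike_channel_footprint < 10) {
    stop("spike_channel_footprint must be >= 10 channels", call. = FALSE)
  }
  for (ep in p$voluntary_epochs) {
    if (length(ep) != 2L || ep[1] < 0 || ep[2] > p$duration_s || ep[1] >= ep[2]) {
      stop("voluntary epochs must be increasing pairs inside [0, duration_s]",
           call. = FALSE)
    }
  }
  class(p) <- "synth_params"
  p
}

## Triphasic Hanning-windowed polynomial spike template, ~15 ms, peak = 1.
spike_template <- function(sampling_rate, duration_ms = 15) {
  half <- max(3L, round(duration_ms / 1000 * sampling_rate / 2))
  u <- seq(-1, 1, length.out = 2L * half + 1L)
  w <- (1 - 6 * u^2) * 0.5 * (1 + cos(pi * u))
  w / max(abs(w))
}

## Exponential spatial decay from an epicentre over the grid, one value per
## channel, ordered like channel_positions of a full row-major grid.
spatial_profile <- function(grid_rows, grid_cols, epi_row, epi_col,
                            quarter_amp_radius) {
  rows <- rep(seq_len(grid_rows), each = grid_cols)
  cols <- rep(seq_len(grid_cols), times = grid_rows)
  d <- sqrt((rows - epi_row)^2 + (cols - epi_col)^2)
  lambda <- quarter_amp_radius / log(4)
  exp(-d / lambda)
}

## Homogeneous Poisson event times on [0, dur) thinned so that consecutive
## kept events are separated by at least refractory_s. The waiting time from
## the end of each dead time is exponential, so kept ISIs minus the
## refractory period remain exactly exponential with the raw rate.
poisson_times <- function(rate_per_s, dur_s, refractory_s) {
  n <- rpois(1L, rate_per_s * dur_s)
  if (n == 0L) return(numeric(0))
  t <- sort(runif(n, 0, dur_s))
  if (refractory_s <= 0 || length(t) < 2L) return(t)
  keep <- t[1L]
  last <- t[1L]
  for (x in t[-1L]) {
    if (x - last >= refractory_s) {
      keep <- c(keep, x)
      last <- x
    }
  }
  keep
}

## Regular voluntary firing inside one epoch: ISI = (1/rate) * (1 + cv * z),
## floored at the refractory period.
voluntary_times <- function(epoch, rate_hz, cv, refractory_s) {
  t <- epoch[1] + runif(1, 0, 1 / rate_hz)  # random phase into the epoch
  out <- numeric(0)
  while (t < epoch[2]) {
    out <- c(out, t)
    isi <- (1 / rate_hz) * (1 + cv * rnorm(1))
    t <- t + max(isi, refractory_s)
  }
  out
}

#' Generate a synthetic grid recording with ground truth
#'
#' @param params a [synth_params()] object.
#' @return A list with elements `recording` (a [grid_recording()]) and
#'   `truth`, a `synth_truth` object holding `spikes` (data frame of
#'   `time_s`, `unit_id`, `kind`), `voluntary_epochs` (data frame of
#'   `start_s`, `end_s`) and the injected per-channel noise parameters.
#' @examples
#' fx <- generate_recording(synth_params(duration_s = 5, seed = 42))
#' nrow(fx$truth$spikes)
#' @export
generate_recording <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  set.seed(p$seed)
  fs <- p$sampling_rate
  n <- round(p$duration_s * fs)
  nch <- p$grid_rows * p$grid_cols
  refr_s <- p$refractory_ms / 1000

  spikes <- list()
  unit_counter <- 0L

  add_unit <- function(times, kind) {
    if (!length(times)) return(NULL)
    unit_counter <<- unit_counter + 1L
    data.frame(time_s = times, unit_id = unit_counter, kind = kind,
               epi_row = runif(1, 1, p$grid_rows),
               epi_col = runif(1, 1, p$grid_cols),
               amp_uv = p$spike_amp_uv * rlnorm(1, 0, p$amp_sdlog))
  }

  ## fasciculations: pooled Poisson process, each discharge its own unit
  fasc_t <- poisson_times(p$fasciculation_rate_per_min / 60, p$duration_s, refr_s)
  fasc <- lapply(fasc_t, function(t) add_unit(t, "fasciculation"))

  ## multiplets: parent fasciculation + identical-morphology partner
  mult <- list()
  if (p$multiplet_rate_per_min > 0) {
    par_t <- poisson_times(p$multiplet_rate_per_min / 60, p$duration_s, refr_s)
    mult <- lapply(par_t, function(t) {
      u <- add_unit(t, "fasciculation")
      t2 <- t + p$multiplet_gap_ms / 1000
      if (t2 < p$duration_s) {
        u <- rbind(u, transform(u[1L, ], time_s = t2, kind = "multiplet_secondary"))
      }
      u
    })
  }

  ## voluntary units: regular trains inside each epoch
  vol <- list()
  if (p$n_voluntary_units > 0 && length(p$voluntary_epochs)) {
    for (i in seq_len(p$n_voluntary_units)) {
      times <- unlist(lapply(p$voluntary_epochs, voluntary_times,
                             rate_hz = p$voluntary_rate_hz,
                             cv = p$voluntary_isi_cv, refractory_s = refr_s))
      vol[[i]] <- add_unit(sort(times), "voluntary")
    }
  }

  all_spikes <- do.call(rbind, c(fasc, mult, vol))
  if (is.null(all_spikes)) {
    all_spikes <- data.frame(time_s = numeric(0), unit_id = integer(0),
                             kind = character(0), epi_row = numeric(0),
                             epi_col = numeric(0), amp_uv = numeric(0))
  }
  all_spikes <- all_spikes[order(all_spikes$time_s), , drop = FALSE]
  rownames(all_spikes) <- NULL

  ## assemble the signal
  template <- spike_template(fs)
  half <- (length(template) - 1L) %/% 2L
  sig <- matrix(rnorm(n * nch, sd = p$noise_sd_uv), nrow = n, ncol = nch)
  tt <- seq_len(n) / fs
  line_phase <- runif(1, 0, 2 * pi)
  drift_phase <- runif(1, 0, 2 * pi)
  if (p$line_noise_uv > 0) {
    sig <- sig + p$line_noise_uv * sin(2 * pi * 50 * tt + line_phase)
  }
  if (p$drift_uv > 0) {
    sig <- sig + p$drift_uv * sin(2 * pi * p$drift_hz * tt + drift_phase)
  }

  if (nrow(all_spikes)) {
    ## one spatial profile per unit, identical morphology per discharge
    units <- unique(all_spikes[c("unit_id", "epi_row", "epi_col", "amp_uv")])
    profiles <- lapply(seq_len(nrow(units)), function(i) {
      spatial_profile(p$grid_rows, p$grid_cols,
                      units$epi_row[i], units$epi_col[i], p$quarter_amp_radius)
    })
    names(profiles) <- units$unit_id
    for (i in seq_len(nrow(all_spikes))) {
      centre <- round(all_spikes$time_s[i] * fs) + 1L
      lo <- max(1L, centre - half)
      hi <- min(n, centre + half)
      if (lo > hi) next
      tpl <- template[(lo - centre + half + 1L):(hi - centre + half + 1L)]
      prof <- profiles[[as.character(all_spikes$unit_id[i])]]
      sig[lo:hi, ] <- sig[lo:hi, ] +
        tcrossprod(tpl, prof * all_spikes$amp_uv[i])
    }
  }

  if (length(p$dead_channels)) sig[, p$dead_channels] <- 0

  rec <- grid_recording(sig, fs, p$grid_rows, p$grid_cols,
                        meta = list(source = "fasctools synthetic",
                                    seed = p$seed))
  epochs <- if (length(p$voluntary_epochs)) {
    data.frame(start_s = vapply(p$voluntary_epochs, `[`, numeric(1), 1L),
               end_s = vapply(p$voluntary_epochs, `[`, numeric(1), 2L))
  } else {
    data.frame(start_s = numeric(0), end_s = numeric(0))
  }
  truth <- structure(
    list(spikes = all_spikes[c("time_s", "unit_id", "kind")],
         units = all_spikes[!duplicated(all_spikes$unit_id),
                            c("unit_id", "kind", "epi_row", "epi_col", "amp_uv")],
         voluntary_epochs = epochs,
         noise = list(noise_sd_uv = p$noise_sd_uv,
                      line_noise_uv = p$line_noise_uv,
                      drift_uv = p$drift_uv,
                      dead_channels = p$dead_channels)),
    class = "synth_truth"
  )
  list(recording = rec, truth = truth, params = p)
}

#' Canned synthetic fixtures
#'
#' Presets mirroring the manual categories a reader would apply to one-minute
#' samples: fully relaxed, partially relaxed, voluntarily active, too noisy to
#' analyse, and a mixed case with multiplets.
#'
#' @param preset one of `"relaxed"`, `"partially_relaxed"`, `"voluntary"`,
#'   `"noisy"`, `"mixed"`.
#' @param duration_s fixture length (default 60 s, kept short for test speed).
#' @param seed integer seed.
#' @return As [generate_recording()]: list with `recording`, `truth`, `params`.
#' @export
make_fixture_suite <- function(preset = c("relaxed", "partially_relaxed",
                                          "voluntary", "noisy", "mixed"),
                               duration_s = 60, seed = 1L) {
  preset <- match.arg(preset)
  p <- switch(preset,
    relaxed = synth_params(duration_s = duration_s, seed = seed,
                           fasciculation_rate_per_min = 40),
    partially_relaxed = synth_params(
      duration_s = duration_s, seed = seed,
      fasciculation_rate_per_min = 20,
      n_voluntary_units = 1, voluntary_rate_hz = 8,
      voluntary_epochs = list(c(duration_s / 3, 2 * duration_s / 3))),
    voluntary = synth_params(
      duration_s = duration_s, seed = seed,
      fasciculation_rate_per_min = 10,
      n_voluntary_units = 2, voluntary_rate_hz = 8,
      voluntary_epochs = list(c(0, duration_s))),
    noisy = synth_params(duration_s = duration_s, seed = seed,
                         fasciculation_rate_per_min = 40, noise_sd_uv = 40),
    mixed = synth_params(
      duration_s = duration_s, seed = seed,
      fasciculation_rate_per_min = 30,
      n_voluntary_units = 1, voluntary_rate_hz = 7,
      voluntary_epochs = list(c(duration_s * 0.25, duration_s * 0.5)),
      multiplet_rate_per_min = 5)
  )
  generate_recording(p)
}
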