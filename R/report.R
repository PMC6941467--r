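#' Assemble a report bundle from a pipeline run
#'
#' Collects the readouts a reviewer uses to choose and audit a strategy: the
#' timeline of potentials (included and excluded), the excluded epochs
#' (noisy blocks and voluntary blocks), the inter-potential interval
#' histogram of the included potentials, and the one-row summary table.
#'
#' @param result an [run_pipeline()] `fq_result`.
#' @param range_ms,bin_ms histogram range and bin width in ms.
#' @return An object of class `fq_report`: list of plain data frames
#'   `timeline`, `excluded_epochs`, `histogram`, `summary`.
#' @export
build_report <- function(result, range_ms = 400, bin_ms = 10) {
  stopifnot(inherits(result, "fq_result"))
  pots <- result$potentials
  timeline <- data.frame(
    time_s = pots$peak_time_s,
    p2t_uv = pots$p2t_uv,
    included = pots$included,
    exclusion_reason = pots$exclusion_reason
  )
  noise_ep <- result$noise_blocks[result$noise_blocks$excluded,
                                  c("start_s", "end_s"), drop = FALSE]
  avid_ep <- result$avid_blocks[result$avid_blocks$final_excluded,
                                c("start_s", "end_s"), drop = FALSE]
  excluded_epochs <- rbind(
    if (nrow(noise_ep)) cbind(noise_ep, kind = "noise") else NULL,
    if (nrow(avid_ep)) cbind(avid_ep, kind = "voluntary") else NULL
  )
  if (is.null(excluded_epochs)) {
    excluded_epochs <- data.frame(start_s = numeric(0), end_s = numeric(0),
                                  kind = character(0))
  }
  hist <- interval_histogram(pots$peak_time_s[pots$included],
                             range_ms = range_ms, bin_ms = bin_ms,
                             excluded_epochs = excluded_epochs)
  structure(list(timeline = timeline, excluded_epochs = excluded_epochs,
                 histogram = hist, summary = result$summary),
            class = "fq_report")
}

#' Write / rebuild a report as CSV files
#'
#' `write_report_csv()` persists the four report tables as
#' `timeline.csv`, `excluded_epochs.csv`, `histogram.csv` and `summary.csv`
#' in `dir`; `read_report_csv()` rebuilds the identical `fq_report` from
#' them, so regeneration round-trips byte-for-byte.
#'
#' @param report an `fq_report`.
#' @param dir output directory (created if needed).
#' @return `write_report_csv()` returns `dir` invisibly; `read_report_csv()`
#'   returns an `fq_report`.
#' @export
write_report_csv <- function(report, dir) {
  stopifnot(inherits(report, "fq_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("timeline", "excluded_epochs", "histogram", "summary")) {
    data.table::fwrite(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                       na = "NA")
  }
  invisible(dir)
}

#' @rdname write_report_csv
#' @export
read_report_csv <- function(dir) {
  rd <- function(nm) {
    as.data.frame(data.table::fread(file.path(dir, paste0(nm, ".csv"))))
  }
  structure(list(timeline = rd("timeline"),
                 excluded_epochs = rd("excluded_epochs"),
                 histogram = rd("histogram"), summary = rd("summary")),
            class = "fq_report")
}

#' Per-strategy comparison table
#'
#' Runs the pipeline once per requested strategy on the same recording and
#' tabulates time analysed, time excluded (noise and voluntary), detected
#' potentials and the resulting fasciculation frequency — the side-by-side
#' view used to judge which strategy is optimal.
#'
#' @param recording a [grid_recording()].
#' @param config a [pipeline_config()]; its `avid_strategy` is overridden.
#' @param strategies character vector of strategies to compare.
#' @param classifier classifier for strategy `"1B"` (dropped from the
#'   comparison, with a warning, when absent).
#' @return Data frame with one row per strategy.
#' @export
strategy_comparison <- function(recording, config = pipeline_config(),
                                strategies = c("0", "1A", "1B", "2"),
                                classifier = NULL) {
  if ("1B" %in% strategies && !inherits(classifier, "fq_classifier")) {
    warning("no classifier supplied; dropping strategy 1B from the comparison",
            call. = FALSE)
    strategies <- setdiff(strategies, "1B")
  }
  rows <- lapply(strategies, function(s) {
    cfg <- config
    cfg$avid_strategy <- s
    res <- run_pipeline(recording, cfg, classifier = classifier)
    res$summary
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot the potential timeline
#'
#' Included potentials as vertical green ticks, excluded potentials in
#' orange (below threshold / noisy block) or purple (voluntary), with
#' excluded epochs shaded.
#'
#' @param report an `fq_report`.
#' @return A ggplot object.
#' @export
plot_timeline <- function(report) {
  stopifnot(inherits(report, "fq_report"))
  tl <- report$timeline
  tl$status <- ifelse(tl$included, "included",
                      ifelse(tl$exclusion_reason == "avid_voluntary",
                             "voluntary", "excluded"))
  p <- ggplot2::ggplot()
  if (nrow(report$excluded_epochs)) {
    p <- p + ggplot2::geom_rect(
      data = report$excluded_epochs,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf, fill = .data$kind),
      alpha = 0.2)
  }
  p +
    ggplot2::geom_segment(
      data = tl,
      ggplot2::aes(x = .data$time_s, xend = .data$time_s,
                   y = 0, yend = .data$p2t_uv, colour = .data$status),
      linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(included = "forestgreen",
                                            excluded = "darkorange",
                                            voluntary = "purple")) +
    ggplot2::labs(x = "time (s)", y = "peak-trough amplitude (uV)",
                  colour = "potential", fill = "excluded epoch") +
    ggplot2::theme_minimal()
}

#' Plot the inter-potential interval histogram
#'
#' @param report an `fq_report` (or an [interval_histogram()] data frame).
#' @return A ggplot object.
#' @export
plot_interval_histogram <- function(report) {
  hist <- if (inherits(report, "fq_report")) report$histogram else report
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$bin_start_ms + diff(c(
    hist$bin_start_ms[1], hist$bin_end_ms[1])) / 2, y = .data$count)) +
    ggplot2::geom_col(width = hist$bin_end_ms[1] - hist$bin_start_ms[1],
                      fill = "steelblue") +
    ggplot2::labs(x = "inter-potential interval (ms)", y = "count") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
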