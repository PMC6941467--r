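#' Fasciculation frequency
#'
#' Total number of analysable (included) fasciculation potentials divided by
#' the time remaining after all excluded epochs, in potentials per minute.
#'
#' @param n_included count of included potentials.
#' @param analysed_time_min analysable time in minutes.
#' @return Rate per minute, or `NA` when no analysable time remains.
#' @examples
#' fasciculation_frequency(100, 25)  # 4
#' @export
fasciculation_frequency <- function(n_included, analysed_time_min) {
  if (!is.finite(analysed_time_min) || analysed_time_min <= 0) {
    return(NA_real_)
  }
  n_included / analysed_time_min
}

#' Block-level evaluation against ground truth
#'
#' Compares automated block flags with generator ground truth. A block is
#' truth-voluntary when it contains at least `min_spikes` ground-truth
#' voluntary spike times (the same >= 4 rule that defines a train). True/
#' false positives and negatives are counted over the blocks and turned into
#' sensitivity, specificity, PPV and NPV percentages.
#'
#' @param blocks data frame with `start_s`, `end_s` and a logical flag
#'   column (`flag_col`).
#' @param truth_voluntary_times ground-truth voluntary spike times (s).
#' @param min_spikes voluntary spikes needed for a block to be
#'   truth-voluntary.
#' @param flag_col name of the logical prediction column (default
#'   `"flagged"`).
#' @return An object of class `fq_evaluation`: list with `tp`, `tn`, `fp`,
#'   `fn`, `sensitivity_pct`, `specificity_pct`, `ppv_pct`, `npv_pct`,
#'   `n_blocks`.
#' @export
evaluate_blocks <- function(blocks, truth_voluntary_times, min_spikes = 4L,
                            flag_col = "flagged") {
  if (is.null(blocks) || nrow(blocks) == 0L) {
    stop("no blocks to evaluate", call. = FALSE)
  }
  pred <- as.logical(blocks[[flag_col]])
  truth <- vapply(seq_len(nrow(blocks)), function(b) {
    sum(truth_voluntary_times >= blocks$start_s[b] &
          truth_voluntary_times < blocks$end_s[b]) >= min_spikes
  }, logical(1))
  tp <- sum(pred & truth); tn <- sum(!pred & !truth)
  fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(list(
    tp = tp, tn = tn, fp = fp, fn = fn, n_blocks = nrow(blocks),
    sensitivity_pct = pct(tp, tp + fn),
    specificity_pct = pct(tn, tn + fp),
    ppv_pct = pct(tp, tp + fp),
    npv_pct = pct(tn, tn + fn)
  ), class = "fq_evaluation")
}

#' @export
print.fq_evaluation <- function(x, ...) {
  cat(sprintf(
    "<fq_evaluation> %d blocks: tp %d, fp %d, tn %d, fn %d | sens %.1f%%, spec %.1f%%\n",
    x$n_blocks, x$tp, x$fp, x$tn, x$fn,
    x$sensitivity_pct, x$specificity_pct))
  invisible(x)
}

#' Median-over-recordings evaluation
#'
#' Evaluation percentages are naturally computed per recording sample and
#' then summarised by the median across samples; the pooled confusion matrix
#' is returned alongside.
#'
#' @param evaluations list of `fq_evaluation` objects.
#' @return List with `median` (median sensitivity/specificity/ppv/npv, %) and
#'   `pooled` (an `fq_evaluation` over the summed confusion counts).
#' @export
summarise_evaluations <- function(evaluations) {
  stopifnot(length(evaluations) > 0L,
            all(vapply(evaluations, inherits, logical(1), "fq_evaluation")))
  g <- function(f) vapply(evaluations, `[[`, numeric(1), f)
  med <- list(
    sensitivity_pct = median(g("sensitivity_pct"), na.rm = TRUE),
    specificity_pct = median(g("specificity_pct"), na.rm = TRUE),
    ppv_pct = median(g("ppv_pct"), na.rm = TRUE),
    npv_pct = median(g("npv_pct"), na.rm = TRUE)
  )
  tp <- sum(g("tp")); tn <- sum(g("tn")); fp <- sum(g("fp")); fn <- sum(g("fn"))
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  pooled <- structure(list(
    tp = tp, tn = tn, fp = fp, fn = fn, n_blocks = tp + tn + fp + fn,
    sensitivity_pct = pct(tp, tp + fn), specificity_pct = pct(tn, tn + fp),
    ppv_pct = pct(tp, tp + fp), npv_pct = pct(tn, tn + fn)
  ), class = "fq_evaluation")
  list(median = med, pooled = pooled)
}

#' Correlation between fasciculation frequency and data quality
#'
#' Ordinary least-squares coefficient of determination (r-squared) and
#' slope-test p-value of fasciculation frequency against each data-quality
#' readout: the recording's median noise band and its excluded-channel
#' count.
#'
#' @param summaries data frame of recording summaries (as produced by
#'   [run_pipeline()]), needing columns `fasciculation_frequency_per_min`,
#'   `median_noise_band_uv`, `n_channels_excluded`.
#' @return Data frame with one row per readout: `readout`, `r_squared`,
#'   `p_value`, `slope`.
#' @export
correlate_quality <- function(summaries) {
  summaries <- as.data.frame(summaries)
  if (nrow(summaries) < 3L) {
    stop("need at least 3 recording summaries", call. = FALSE)
  }
  one <- function(xname) {
    x <- summaries[[xname]]
    y <- summaries$fasciculation_frequency_per_min
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 2L || var(x) == 0 || var(y) == 0) {
      warning("zero variance in ", xname, "; correlation undefined",
              call. = FALSE)
      return(data.frame(readout = xname, r_squared = NA_real_,
                        p_value = NA_real_, slope = NA_real_))
    }
    if (length(x) == 2L) {
      warning("only two points for ", xname, "; r-squared degenerate at 1",
              call. = FALSE)
    }
    fit <- lm(y ~ x)
    sm <- suppressWarnings(summary(fit))  # silence perfect-fit chatter
    p <- if (nrow(sm$coefficients) > 1L && sm$df[2L] > 0) {
      sm$coefficients[2L, 4L]
    } else NA_real_
    data.frame(readout = xname, r_squared = sm$r.squared, p_value = p,
               slope = coef(fit)[[2L]])
  }
  out <- rbind(one("median_noise_band_uv"), one("n_channels_excluded"))
  rownames(out) <- NULL
  out
}

#' @importFrom stats var
NULL
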