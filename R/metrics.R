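# Trace metrics: area under the curve, peak detection, peak frequency and
# mean peak height, per session and per behaviour class.

#' Area under the dF/F curve
#'
#' The AUC is the summed area between the x-axis and the trace: positive
#' samples contribute `dff * dt`, negative excursions contribute zero (the
#' baseline correction exists precisely to lift the trace above the axis).
#' With an epoch set, each state's AUC is the sum over samples falling in
#' that state's epochs, normalized by the state's summed epoch duration, so
#' per-state values are in dF/F units. Sample membership uses half-open
#' intervals `[start, end)`.
#'
#' @param trace a [dff_trace()].
#' @param epochs optional [epoch_set()]; when `NULL` only the whole-session
#'   AUC is computed.
#' @param method `"rectangle"` (default; sample value times frame period) or
#'   `"trapezoid"` applied to the positive part.
#' @return list with `auc_total` (dF/F * s), `auc_per_state` (named, dF/F
#'   units; `NA` for a state with no retained epochs) and `state_durations`.
#' @export
compute_auc <- function(trace, epochs = NULL,
                        method = c("rectangle", "trapezoid")) {
  method <- match.arg(method)
  dt <- grid_dt(trace$time_s)
  pos <- pmax(trace$dff, 0)
  auc_total <- if (method == "rectangle") sum(pos) * dt else
    sum((pos[-1] + pos[-length(pos)]) / 2) * dt
  out <- list(auc_total = auc_total, auc_per_state = NULL,
              state_durations = NULL)
  if (!is.null(epochs)) {
    ep <- epochs$epochs
    durs <- state_durations(epochs)
    states <- names(durs)
    per_state <- stats::setNames(rep(NA_real_, length(states)), states)
    for (s in states) {
      if (durs[[s]] <= 0) next
      sel <- rep(FALSE, length(trace$time_s))
      rows <- which(ep$state == s)
      for (r in rows) {
        sel <- sel | (trace$time_s >= ep$start_s[r] & trace$time_s < ep$end_s[r])
      }
      # per-state areas are always rectangle sums: epochs need not be
      # contiguous, so a trapezoid across gaps would be ill-defined
      per_state[[s]] <- sum(pos[sel]) * dt / durs[[s]]
    }
    out$auc_per_state <- per_state
    out$state_durations <- durs
  }
  out
}

#' Detect calcium transient peaks
#'
#' The detection threshold is the session median plus two standard
#' deviations of the whole dF/F trace. Peaks are samples strictly greater
#' than both neighbours and above threshold; candidates closer than
#' `min_peak_gap_s` to a larger accepted peak are discarded (larger peaks
#' win). Peak height is the absolute dF/F value at the maximum.
#'
#' @param trace a [dff_trace()] with at least 3 samples.
#' @param min_peak_gap_s minimum separation between accepted peaks (s).
#'   Default 1 s — the above-threshold span of a moderate GCaMP7f transient
#'   (decay tau about 0.6 s) at the median + 2 SD threshold, so noisy
#'   samples on a decay flank are not counted as second peaks; 0 disables
#'   the gap.
#' @return object of class `peak_set`: `peak_times_s`, `peak_heights`,
#'   `threshold`.
#' @export
detect_peaks <- function(trace, min_peak_gap_s = 1) {
  x <- trace$dff
  if (length(x) < 3L) stop("detect_peaks: need at least 3 samples", call. = FALSE)
  thr <- stats::median(x) + 2 * stats::sd(x)
  n <- length(x)
  cand <- which(x[-c(1, 2)] < x[-c(1, n)] & x[-c(n - 1, n)] < x[-c(1, n)]) + 1L
  cand <- cand[x[cand] > thr]
  if (length(cand) && min_peak_gap_s > 0) {
    ord <- cand[order(x[cand], decreasing = TRUE)]
    kept <- numeric(0)
    kept_t <- numeric(0)
    for (i in ord) {
      ti <- trace$time_s[i]
      if (!length(kept_t) || all(abs(kept_t - ti) >= min_peak_gap_s)) {
        kept <- c(kept, i)
        kept_t <- c(kept_t, ti)
      }
    }
    cand <- sort(kept)
  }
  structure(list(peak_times_s = trace$time_s[cand], peak_heights = x[cand],
                 threshold = thr),
            class = "peak_set")
}

#' Peak frequency per behaviour state
#'
#' Counts the detected peaks whose time falls inside a state's epochs
#' (half-open intervals) and divides by the state's summed epoch duration.
#' Peaks in excluded short bouts count toward no state.
#'
#' @param peaks a [detect_peaks()] result.
#' @param epochs an [epoch_set()].
#' @return named numeric vector of peaks/s per state (`NA` for zero-duration
#'   states).
#' @export
peak_frequency <- function(peaks, epochs) {
  durs <- state_durations(epochs)
  ep <- epochs$epochs
  out <- stats::setNames(rep(NA_real_, length(durs)), names(durs))
  for (s in names(durs)) {
    if (durs[[s]] <= 0) next
    rows <- which(ep$state == s)
    count <- 0L
    for (r in rows) {
      count <- count + sum(peaks$peak_times_s >= ep$start_s[r] &
                             peaks$peak_times_s < ep$end_s[r])
    }
    out[[s]] <- count / durs[[s]]
  }
  out
}

#' Mean peak height
#'
#' Arithmetic mean of the detected peak heights (absolute dF/F at each
#' maximum); `NA` when no peaks were detected.
#'
#' @param peaks a [detect_peaks()] result.
#' @return numeric scalar or `NA`.
#' @export
mean_peak_height <- function(peaks) {
  if (length(peaks$peak_heights) == 0L) return(NA_real_)
  mean(peaks$peak_heights)
}

#' All trace metrics for one session
#'
#' Convenience wrapper computing whole-session and per-state AUC, peak
#' frequency per state, and mean peak height.
#'
#' @param trace a [dff_trace()].
#' @param epochs an [epoch_set()].
#' @param min_peak_gap_s passed to [detect_peaks()].
#' @return list with `auc_total`, `auc_per_state`, `peak_frequency_per_state`,
#'   `mean_peak_height`, `n_peaks`, `threshold`.
#' @export
trace_metrics <- function(trace, epochs, min_peak_gap_s = 1) {
  auc <- compute_auc(trace, epochs)
  peaks <- detect_peaks(trace, min_peak_gap_s = min_peak_gap_s)
  list(auc_total = auc$auc_total,
       auc_per_state = auc$auc_per_state,
       peak_frequency_per_state = peak_frequency(peaks, epochs),
       mean_peak_height = mean_peak_height(peaks),
       n_peaks = length(peaks$peak_times_s),
       threshold = peaks$threshold)
}
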