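# Synchronizing behaviour with the photometry time base and building the
# filtered epoch structure used by the trace metrics.

#' Label each photometry sample with the nearest behaviour state
#'
#' Each sample of the photometry grid takes the state of the behaviour
#' sample with minimum absolute timestamp difference; exact ties go to the
#' earlier behaviour sample. The behaviour clock is shifted by `offset_s`
#' before matching — set it to the time of the first TTL pulse on the
#' photometry clock, since the tracking software starts its own clock at
#' zero when the TTL is emitted.
#'
#' @param track a [behavior_track()].
#' @param time_s photometry time grid (s).
#' @param offset_s shift added to behaviour timestamps to move them onto the
#'   photometry clock (default 0 = same clock).
#' @return object of class `aligned_labels`: `time_s`, `state` (one per
#'   photometry sample), `source_time_s` (matched behaviour timestamp).
#' @export
align_behavior <- function(track, time_s, offset_s = 0) {
  bt <- track$time_s + offset_s
  if (min(bt) > max(time_s) || max(bt) < min(time_s)) {
    stop("align_behavior: behaviour and photometry time ranges are disjoint",
         call. = FALSE)
  }
  n_b <- length(bt)
  lo <- findInterval(time_s, bt)
  j_left <- pmax(lo, 1L)
  j_right <- pmin(lo + 1L, n_b)
  d_left <- abs(time_s - bt[j_left])
  d_right <- abs(bt[j_right] - time_s)
  # ties go to the earlier behaviour sample; the 1 ns slack keeps exact
  # midpoints (common with commensurate clock rates) from being decided by
  # floating-point representation error
  idx <- ifelse(lo == 0L, 1L,
                ifelse(d_left <= d_right + 1e-9, j_left, j_right))
  structure(list(time_s = as.numeric(time_s), state = track$state[idx],
                 source_time_s = bt[idx]),
            class = "aligned_labels")
}

#' Construct an epoch set
#'
#' @param epochs data.frame with columns `start_s`, `end_s`, `state`;
#'   non-overlapping and ordered.
#' @param min_bout_s the minimum bout duration the epochs satisfy.
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, min_bout_s = 2) {
  stopifnot(all(c("start_s", "end_s", "state") %in% names(epochs)))
  if (nrow(epochs) > 1L) {
    if (any(diff(epochs$start_s) <= 0) ||
        any(epochs$start_s[-1] < epochs$end_s[-nrow(epochs)] - 1e-9)) {
      stop("epoch_set: epochs must be ordered and non-overlapping", call. = FALSE)
    }
  }
  structure(list(epochs = epochs, min_bout_s = min_bout_s), class = "epoch_set")
}

#' Extract behaviour epochs surviving the minimum-bout filter
#'
#' Maximal runs of constant state in the aligned labels become candidate
#' epochs; runs shorter than `min_bout_s` are dropped (leaving gaps — short
#' bouts are excluded, not reassigned to a neighbour). A run of `n` samples
#' starting at time `t` spans `[t, t + n * dt)`, i.e. its duration is the
#' sample count times the frame period, so a run exactly at the threshold is
#' retained.
#'
#' @param labels an `aligned_labels` object from [align_behavior()].
#' @param min_bout_s minimum bout duration in seconds (default 2; kept
#'   configurable because freezing is sometimes scored with a 1 s
#'   criterion).
#' @return an [epoch_set()].
#' @export
extract_epochs <- function(labels, min_bout_s = 2) {
  time_s <- labels$time_s
  dt <- grid_dt(time_s)
  r <- rle(labels$state)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  start_s <- time_s[starts_i]
  dur <- r$lengths * dt
  keep <- dur >= min_bout_s - 1e-9
  epoch_set(
    data.frame(start_s = start_s[keep], end_s = start_s[keep] + dur[keep],
               state = r$values[keep], stringsAsFactors = FALSE),
    min_bout_s = min_bout_s
  )
}

# Summed duration per state of an epoch set, as a named vector.
state_durations <- function(epochs) {
  ep <- epochs$epochs
  states <- unique(ep$state)
  vapply(states, function(s) sum(ep$end_s[ep$state == s] - ep$start_s[ep$state == s]),
         numeric(1))
}
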