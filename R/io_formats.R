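# Readers/writers for the pipeline's file dialects, plus deinterleaving of
# the two-LED recording into aligned channel streams.

#' Construct a raw photometry session
#'
#' Frame-interleaved two-channel recording: each frame carries a timestamp,
#' the active LED (415 nm isosbestic or 470 nm signal) and a fluorescence
#' value. Invariants are enforced: timestamps strictly increasing, LED state
#' alternating between consecutive frames, TTL events within the recording
#' span.
#'
#' @param frames data.frame with columns `frame`, `timestamp_s`, `led_state`
#'   (415/470) and `fluorescence`.
#' @param ttl_events_s numeric vector of TTL pulse timestamps (s).
#' @return object of class `raw_photometry_session`.
#' @export
raw_photometry_session <- function(frames, ttl_events_s = numeric(0)) {
  needed <- c("frame", "timestamp_s", "led_state", "fluorescence")
  miss <- setdiff(needed, names(frames))
  if (length(miss)) {
    stop(sprintf("photometry frames missing column '%s'", miss[1]), call. = FALSE)
  }
  ts <- frames$timestamp_s
  if (any(diff(ts) <= 0)) {
    stop("photometry integrity error: timestamps must be strictly increasing",
         call. = FALSE)
  }
  if (!all(frames$led_state %in% c(415L, 470L))) {
    stop("photometry frames: led_state must be 415 or 470", call. = FALSE)
  }
  if (length(frames$led_state) > 1L &&
      any(diff(as.integer(frames$led_state)) == 0L)) {
    stop("photometry integrity error: LED state must alternate between frames",
         call. = FALSE)
  }
  if (length(ttl_events_s) &&
      (min(ttl_events_s) < ts[1] || max(ttl_events_s) > ts[length(ts)])) {
    stop("photometry integrity error: TTL events outside recording span",
         call. = FALSE)
  }
  structure(list(frames = frames, ttl_events_s = as.numeric(ttl_events_s)),
            class = "raw_photometry_session")
}

#' @export
print.raw_photometry_session <- function(x, ...) {
  n <- nrow(x$frames)
  cat(sprintf("raw_photometry_session: %d frames, %.1f s, %d TTL event(s)\n",
              n, diff(range(x$frames$timestamp_s)), length(x$ttl_events_s)))
  invisible(x)
}

#' Write a photometry session as frame-interleaved CSV
#'
#' Columns: `FrameCounter`, `Timestamp`, `LedState`, `Fluorescence`, `TTL`
#' (0/1 marker on the frame nearest each TTL pulse). `LedState` is written
#' either as nanometre literals (415/470) or as the common 1/2 flag dialect
#' (1 = 415 nm, 2 = 470 nm).
#'
#' @param session a `raw_photometry_session`.
#' @param path output file path.
#' @param dialect `"nm"` (default) or `"flag"`.
#' @return `path`, invisibly.
#' @export
write_photometry_csv <- function(session, path, dialect = c("nm", "flag")) {
  dialect <- match.arg(dialect)
  fr <- session$frames
  led <- if (dialect == "nm") fr$led_state else ifelse(fr$led_state == 415L, 1L, 2L)
  ttl_col <- integer(nrow(fr))
  for (tt in session$ttl_events_s) {
    ttl_col[which.min(abs(fr$timestamp_s - tt))] <- 1L
  }
  out <- data.frame(FrameCounter = fr$frame, Timestamp = fr$timestamp_s,
                    LedState = led, Fluorescence = fr$fluorescence, TTL = ttl_col)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a frame-interleaved photometry CSV
#'
#' Expects columns `FrameCounter`, `Timestamp`, `LedState`, `Fluorescence`
#' and optionally `TTL`. `LedState` may use nanometre literals (415/470) or
#' the 1/2 flag dialect; the mapping is configurable via `led_map`.
#'
#' @param path file path.
#' @param led_map named vector mapping raw LedState values to 415/470;
#'   default accepts both dialects.
#' @return a [raw_photometry_session()].
#' @export
read_photometry_csv <- function(path, led_map = c("1" = 415, "2" = 470,
                                                  "415" = 415, "470" = 470)) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path)
  for (col in c("FrameCounter", "Timestamp", "LedState", "Fluorescence")) {
    if (!col %in% names(df)) {
      stop(sprintf("photometry format error: missing column '%s'", col),
           call. = FALSE)
    }
  }
  raw_led <- as.character(df$LedState)
  if (!all(raw_led %in% names(led_map))) {
    bad <- setdiff(unique(raw_led), names(led_map))
    stop(sprintf("photometry format error: unknown LedState value '%s'", bad[1]),
         call. = FALSE)
  }
  led <- as.integer(led_map[raw_led])
  ttl <- if ("TTL" %in% names(df)) df$Timestamp[df$TTL == 1] else numeric(0)
  raw_photometry_session(
    data.frame(frame = df$FrameCounter, timestamp_s = df$Timestamp,
               led_state = led, fluorescence = df$Fluorescence),
    ttl_events_s = ttl
  )
}

#' Split an interleaved session into aligned 470/415 channel streams
#'
#' The common time grid is taken from the 470 nm (signal) frames; each 470
#' frame is paired with the nearest preceding 415 frame, so the effective
#' per-channel rate is half the acquisition rate. A leading 470 frame with no
#' preceding 415 frame, or a trailing unpaired 415 frame, is dropped.
#'
#' @param session a `raw_photometry_session`.
#' @return object of class `channel_pair`: list with `time_s`, `f470`,
#'   `f415`.
#' @export
deinterleave <- function(session) {
  fr <- session$frames
  is470 <- fr$led_state == 470L
  if (!any(is470) || all(is470)) {
    stop("deinterleave: both channels must contain at least one frame",
         call. = FALSE)
  }
  t470 <- fr$timestamp_s[is470]
  f470 <- fr$fluorescence[is470]
  t415 <- fr$timestamp_s[!is470]
  f415 <- fr$fluorescence[!is470]
  pair_idx <- findInterval(t470, t415)
  keep <- pair_idx >= 1L
  structure(list(time_s = t470[keep], f470 = f470[keep],
                 f415 = f415[pair_idx[keep]]),
            class = "channel_pair")
}

#' Construct a behaviour track
#'
#' Time-stamped binary behaviour states, the shape of an automated
#' video-tracking export (nondecreasing timestamps, states `"freezing"` /
#' `"moving"`).
#'
#' @param time_s numeric timestamps (s), nondecreasing.
#' @param state character vector of states.
#' @return object of class `behavior_track`.
#' @export
behavior_track <- function(time_s, state) {
  if (length(time_s) != length(state)) {
    stop("behavior track: time and state lengths differ", call. = FALSE)
  }
  if (length(time_s) == 0L) stop("behavior track: empty", call. = FALSE)
  if (any(diff(time_s) < 0)) {
    stop("behavior track: timestamps must be nondecreasing", call. = FALSE)
  }
  if (!all(state %in% c("freezing", "moving"))) {
    stop("behavior track: states must be 'freezing' or 'moving'", call. = FALSE)
  }
  structure(list(time_s = as.numeric(time_s), state = as.character(state)),
            class = "behavior_track")
}

#' Write a behaviour track as CSV
#'
#' Columns `Time` and `Freezing` (1 = freezing, 0 = moving).
#'
#' @param track a [behavior_track()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_behavior_csv <- function(track, path) {
  utils::write.csv(
    data.frame(Time = track$time_s,
               Freezing = as.integer(track$state == "freezing")),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Read a behaviour CSV
#'
#' Expects columns `Time` and `Freezing` with values 0/1.
#'
#' @param path file path.
#' @return a [behavior_track()].
#' @export
read_behavior_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- tryCatch(utils::read.csv(path), error = function(e) {
    stop(sprintf("behavior format error: %s", conditionMessage(e)), call. = FALSE)
  })
  if (nrow(df) == 0L) stop("behavior format error: empty file", call. = FALSE)
  for (col in c("Time", "Freezing")) {
    if (!col %in% names(df)) {
      stop(sprintf("behavior format error: missing column '%s'", col),
           call. = FALSE)
    }
  }
  bad <- which(!(df$Freezing %in% c(0, 1)))
  if (length(bad)) {
    stop(sprintf("behavior format error: unparseable Freezing value at row %d",
                 bad[1]), call. = FALSE)
  }
  behavior_track(df$Time, ifelse(df$Freezing == 1, "freezing", "moving"))
}

#' Write an image stack as plain-text CSV planes
#'
#' Serializes an [image_stack()] to a directory containing one CSV per
#' z-plane plus a JSON sidecar with the pixel calibration. A plain-text
#' stand-in for a calibrated multi-page TIFF, used so fixtures stay
#' text-only.
#'
#' @param stack an [image_stack()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_image_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(stack$voxels)
  for (z in seq_len(d[3])) {
    utils::write.table(stack$voxels[, , z],
                       file.path(dir, sprintf("plane_%03d.csv", z)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(list(um_per_px = stack$um_per_px,
                            z_step_um = stack$z_step_um, n_z = d[3]),
                       file.path(dir, "calibration.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param dir directory containing `plane_*.csv` files and
#'   `calibration.json`.
#' @return an [image_stack()].
#' @export
read_image_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "calibration.json"),
                              simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^plane_\\d+\\.csv$", full.names = TRUE))
  if (length(files) == 0L) stop("image stack: no plane files found", call. = FALSE)
  planes <- lapply(files, function(f) {
    as.matrix(utils::read.table(f, sep = ",", header = FALSE))
  })
  vox <- array(0, dim = c(nrow(planes[[1]]), ncol(planes[[1]]), length(planes)))
  for (z in seq_along(planes)) vox[, , z] <- planes[[z]]
  image_stack(vox, um_per_px = meta$um_per_px, z_step_um = meta$z_step_um)
}
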