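# Ground-truthed synthetic data generators.
#
# Four generators emulate the four input kinds the pipeline consumes:
# frame-interleaved two-channel photometry, behaviour (freezing/moving)
# tracks, WFA-labelled perineuronal-net image stacks, and two-group sample
# vectors. Every generator records the ground truth of what it injected so
# downstream recovery can be checked exactly.

#' Configuration for the photometry session simulator
#'
#' Bundles and validates all parameters of [simulate_session()]. Fluorescence
#' is in arbitrary detector units; the default bleach offset of 100 units sets
#' the scale, so a dF/F-level quantity `q` corresponds to roughly `100 * q`
#' fluorescence units.
#'
#' @param duration_s recording duration in seconds.
#' @param frame_rate_hz interleaved acquisition rate (frames/s). Must be even:
#'   two LEDs alternate frame by frame, so each channel runs at
#'   `frame_rate_hz / 2`.
#' @param event_rate_hz mean rate of calcium transients (events/s). The
#'   realized count is Poisson unless `n_events` is given.
#' @param n_events optional fixed number of transients (overrides the Poisson
#'   draw; times are still uniform over the session).
#' @param event_amplitude_dff peak amplitude of each transient in dF/F units
#'   (multiplicative on the bleach curve).
#' @param tau_rise_s,tau_decay_s rise/decay time constants (s) of the
#'   difference-of-exponentials transient kernel.
#' @param bleach_amp1,bleach_tau1_s,bleach_amp2,bleach_tau2_s,bleach_offset
#'   biexponential photobleaching parameters of the 470 nm channel:
#'   `F(t) = a1 exp(-t/tau1) + a2 exp(-t/tau2) + c`.
#' @param bleach415_amp1,bleach415_tau1_s,bleach415_amp2,bleach415_tau2_s,bleach415_offset
#'   bleach parameters of the 415 nm isosbestic channel. Default: the 470
#'   parameters scaled by 0.8 (the channels bleach similarly but not
#'   identically).
#' @param artifact_rate_hz rate of shared motion artifacts (events/s).
#' @param artifact_amplitude peak amplitude of each artifact bump
#'   (fluorescence units); the sign of each bump is random.
#' @param artifact_width_s full duration of the raised-cosine artifact bump
#'   (s). Motion artifacts are smooth on the head-movement timescale
#'   (hundreds of ms), so both alternately-sampled channels see essentially
#'   the same artifact value despite their half-frame timing offset.
#' @param shared_gain gain with which artifacts appear in the 415 channel
#'   relative to the 470 channel (1 = identical additive amplitude, which is
#'   what isosbestic subtraction can cancel).
#' @param noise_sd additive white-noise SD per frame (fluorescence units).
#' @param ttl_time_s time of the behaviour-sync TTL pulse (s); snapped to the
#'   nearest frame so sessions survive a CSV round trip exactly.
#' @param seed integer seed; identical seeds give bit-identical sessions.
#' @return a validated list of class `photom_sim_config`.
#' @export
photom_sim_config <- function(duration_s = 300,
                              frame_rate_hz = 40,
                              event_rate_hz = 0.1,
                              n_events = NULL,
                              event_amplitude_dff = 0.05,
                              tau_rise_s = 0.05,
                              tau_decay_s = 0.6,
                              bleach_amp1 = 20, bleach_tau1_s = 40,
                              bleach_amp2 = 30, bleach_tau2_s = 500,
                              bleach_offset = 100,
                              bleach415_amp1 = 0.8 * bleach_amp1,
                              bleach415_tau1_s = bleach_tau1_s,
                              bleach415_amp2 = 0.8 * bleach_amp2,
                              bleach415_tau2_s = bleach_tau2_s,
                              bleach415_offset = 0.8 * bleach_offset,
                              artifact_rate_hz = 0.05,
                              artifact_amplitude = 10,
                              artifact_width_s = 0.4,
                              shared_gain = 1,
                              noise_sd = 1,
                              ttl_time_s = 0,
                              seed = NULL) {
  check_positive_scalar(duration_s, "duration_s")
  check_positive_scalar(frame_rate_hz, "frame_rate_hz")
  if (frame_rate_hz %% 2 != 0) {
    stop("invalid config: 'frame_rate_hz' must be even (two alternating channels)",
         call. = FALSE)
  }
  check_nonneg_scalar(event_rate_hz, "event_rate_hz")
  check_nonneg_scalar(event_amplitude_dff, "event_amplitude_dff")
  check_positive_scalar(tau_rise_s, "tau_rise_s")
  check_positive_scalar(tau_decay_s, "tau_decay_s")
  if (tau_decay_s <= tau_rise_s) {
    stop("invalid config: 'tau_decay_s' must exceed 'tau_rise_s'", call. = FALSE)
  }
  for (nm in c("bleach_tau1_s", "bleach_tau2_s", "bleach415_tau1_s", "bleach415_tau2_s")) {
    check_positive_scalar(get(nm), nm)
  }
  check_nonneg_scalar(artifact_rate_hz, "artifact_rate_hz")
  check_nonneg_scalar(artifact_amplitude, "artifact_amplitude")
  check_positive_scalar(artifact_width_s, "artifact_width_s")
  check_nonneg_scalar(noise_sd, "noise_sd")
  check_nonneg_scalar(ttl_time_s, "ttl_time_s")
  if (!is.null(n_events)) check_nonneg_scalar(n_events, "n_events")
  structure(list(
    duration_s = duration_s, frame_rate_hz = frame_rate_hz,
    event_rate_hz = event_rate_hz, n_events = n_events,
    event_amplitude_dff = event_amplitude_dff,
    tau_rise_s = tau_rise_s, tau_decay_s = tau_decay_s,
    bleach_amp1 = bleach_amp1, bleach_tau1_s = bleach_tau1_s,
    bleach_amp2 = bleach_amp2, bleach_tau2_s = bleach_tau2_s,
    bleach_offset = bleach_offset,
    bleach415_amp1 = bleach415_amp1, bleach415_tau1_s = bleach415_tau1_s,
    bleach415_amp2 = bleach415_amp2, bleach415_tau2_s = bleach415_tau2_s,
    bleach415_offset = bleach415_offset,
    artifact_rate_hz = artifact_rate_hz,
    artifact_amplitude = artifact_amplitude,
    artifact_width_s = artifact_width_s,
    shared_gain = shared_gain,
    noise_sd = noise_sd, ttl_time_s = ttl_time_s, seed = seed
  ), class = "photom_sim_config")
}

# Normalized difference-of-exponentials transient kernel, peak value 1 at
# t* = tr*td/(td-tr) * log(td/tr).
transient_kernel <- function(dt, tau_rise_s, tau_decay_s) {
  t_star <- tau_rise_s * tau_decay_s / (tau_decay_s - tau_rise_s) *
    log(tau_decay_s / tau_rise_s)
  peak <- exp(-t_star / tau_decay_s) - exp(-t_star / tau_rise_s)
  out <- numeric(length(dt))
  pos <- dt >= 0
  out[pos] <- (exp(-dt[pos] / tau_decay_s) - exp(-dt[pos] / tau_rise_s)) / peak
  out
}

biexp_curve <- function(t, a1, tau1, a2, tau2, c) {
  a1 * exp(-t / tau1) + a2 * exp(-t / tau2) + c
}

#' Simulate a frame-interleaved two-channel photometry session
#'
#' Generates a [raw_photometry_session()] in which frames alternate between
#' the 415 nm isosbestic channel (first frame) and the 470 nm signal channel.
#' The 470 stream is `bleach470(t) * (1 + sum of transients) + artifacts +
#' noise`; the 415 stream is `bleach415(t) + shared_gain * artifacts + noise`
#' (no transients). Motion artifacts are square pulses injected additively
#' into both channels at the same times, which is exactly the component an
#' isosbestic subtraction can cancel.
#'
#' @param config a [photom_sim_config()].
#' @return a list with elements `session` (a `raw_photometry_session`) and
#'   `truth` (list: `event_times_s`, `event_amplitudes`, `artifact_times_s`,
#'   `artifact_signs`, `bleach470`, `bleach415` parameter vectors).
#' @examples
#' sim <- simulate_session(photom_sim_config(duration_s = 20, seed = 1))
#' length(sim$truth$event_times_s)
#' @export
simulate_session <- function(config) {
  if (!inherits(config, "photom_sim_config")) config <- do.call(photom_sim_config, config)
  with_seed(config$seed, {
    n_frames <- round(config$duration_s * config$frame_rate_hz)
    ts <- (seq_len(n_frames) - 1) / config$frame_rate_hz
    led <- rep_len(c(415L, 470L), n_frames)

    n_ev <- if (!is.null(config$n_events)) as.integer(config$n_events) else
      stats::rpois(1L, config$event_rate_hz * config$duration_s)
    ev_t <- sort(stats::runif(n_ev, 0, config$duration_s))
    ev_a <- rep(config$event_amplitude_dff, n_ev)

    n_art <- stats::rpois(1L, config$artifact_rate_hz * config$duration_s)
    art_t <- sort(stats::runif(n_art, 0, config$duration_s))
    art_sign <- if (n_art > 0) sample(c(-1, 1), n_art, replace = TRUE) else numeric(0)

    transient_sum <- function(t) {
      s <- numeric(length(t))
      for (k in seq_len(n_ev)) {
        s <- s + ev_a[k] * transient_kernel(t - ev_t[k], config$tau_rise_s,
                                            config$tau_decay_s)
      }
      s
    }
    artifact_sum <- function(t) {
      a <- numeric(length(t))
      w <- config$artifact_width_s
      for (k in seq_len(n_art)) {
        inside <- t >= art_t[k] & t < art_t[k] + w
        phase <- (t[inside] - art_t[k]) / w
        a[inside] <- a[inside] + art_sign[k] * config$artifact_amplitude *
          0.5 * (1 - cos(2 * pi * phase))
      }
      a
    }

    is470 <- led == 470L
    t470 <- ts[is470]
    t415 <- ts[!is470]
    f <- numeric(n_frames)
    b470 <- biexp_curve(t470, config$bleach_amp1, config$bleach_tau1_s,
                        config$bleach_amp2, config$bleach_tau2_s, config$bleach_offset)
    b415 <- biexp_curve(t415, config$bleach415_amp1, config$bleach415_tau1_s,
                        config$bleach415_amp2, config$bleach415_tau2_s,
                        config$bleach415_offset)
    f[is470] <- b470 * (1 + transient_sum(t470)) + artifact_sum(t470) +
      stats::rnorm(length(t470), 0, config$noise_sd)
    f[!is470] <- b415 + config$shared_gain * artifact_sum(t415) +
      stats::rnorm(length(t415), 0, config$noise_sd)

    ttl <- ts[which.min(abs(ts - config$ttl_time_s))]
    session <- raw_photometry_session(
      data.frame(frame = seq_len(n_frames) - 1L, timestamp_s = ts,
                 led_state = led, fluorescence = f),
      ttl_events_s = ttl
    )
    truth <- list(
      event_times_s = ev_t, event_amplitudes = ev_a,
      artifact_times_s = art_t, artifact_signs = art_sign,
      bleach470 = c(a1 = config$bleach_amp1, tau1 = config$bleach_tau1_s,
                    a2 = config$bleach_amp2, tau2 = config$bleach_tau2_s,
                    c = config$bleach_offset),
      bleach415 = c(a1 = config$bleach415_amp1, tau1 = config$bleach415_tau1_s,
                    a2 = config$bleach415_amp2, tau2 = config$bleach415_tau2_s,
                    c = config$bleach415_offset)
    )
    list(session = session, truth = truth)
  })
}

#' Simulate a freezing/moving behaviour track
#'
#' Alternating freezing and movement bouts with exponentially distributed
#' durations tile `[0, duration_s]`. The continuous bout process is sampled
#' onto a regular grid (as automated video tracking software would score it),
#' and the ground-truth bouts are the maximal constant-state runs of that
#' sampled track — i.e. the bout structure the exported track actually
#' encodes, including bouts shorter than any downstream filter.
#'
#' @param duration_s session duration (s).
#' @param bout_rate optional switching rate (1/s); if given, overrides
#'   `mean_bout_s` with `1/bout_rate`. `bout_rate = 0` yields a single bout
#'   covering the whole session.
#' @param mean_bout_s mean bout duration (s); default 8 s.
#' @param sample_rate_hz export sampling rate of the track (default 10 Hz,
#'   a typical video-scoring rate).
#' @param seed integer seed.
#' @return list with `track` (a [behavior_track()]) and `truth` (list with
#'   `true_bouts`: data.frame `start_s`, `end_s`, `state`).
#' @export
simulate_behavior <- function(duration_s, bout_rate = NULL, mean_bout_s = 8,
                              sample_rate_hz = 10, seed = NULL) {
  check_positive_scalar(duration_s, "duration_s")
  check_positive_scalar(sample_rate_hz, "sample_rate_hz")
  if (!is.null(bout_rate)) {
    check_nonneg_scalar(bout_rate, "bout_rate")
    mean_bout_s <- if (bout_rate > 0) 1 / bout_rate else Inf
  }
  if (!(is.numeric(mean_bout_s) && length(mean_bout_s) == 1L && mean_bout_s > 0)) {
    stop("invalid config: 'mean_bout_s' must be positive", call. = FALSE)
  }
  with_seed(seed, {
    states <- c("freezing", "moving")
    first <- sample(states, 1L)
    # continuous alternating bout boundaries covering [0, duration]
    bounds <- 0
    while (bounds[length(bounds)] < duration_s) {
      d <- if (is.finite(mean_bout_s)) stats::rexp(1L, 1 / mean_bout_s) else duration_s + 1
      bounds <- c(bounds, bounds[length(bounds)] + d)
    }
    dt <- 1 / sample_rate_hz
    n <- round(duration_s * sample_rate_hz)
    times <- (seq_len(n) - 1) * dt
    seg <- findInterval(times, bounds, rightmost.closed = FALSE)
    st <- states[((match(first, states) - 1L + (seg - 1L)) %% 2L) + 1L]
    track <- behavior_track(times, st)
    r <- rle(st)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    true_bouts <- data.frame(
      start_s = times[starts_i],
      end_s = times[starts_i] + r$lengths * dt,
      state = r$values,
      stringsAsFactors = FALSE
    )
    list(track = track, truth = list(true_bouts = true_bouts))
  })
}

#' Simulate a WFA-labelled perineuronal-net image stack
#'
#' Draws `n_rings` bright ring-shaped structures (stylized PNN surfaces seen
#' in a top-half maximum-intensity projection) into an image stack.
#' `fragmentation` removes that fraction of each ring's circumference, split
#' across `n_gaps` arcs, so the noise-free projected mask fragments into
#' separate arc components. Ground-truth contiguity is computed directly on
#' that noise-free mask with the package's connected-component labeller.
#'
#' @param n_rings number of PNNs to draw.
#' @param fragmentation fraction of each ring's circumference removed, in
#'   `[0, 1]`.
#' @param image_px side length of the square image (pixels).
#' @param um_per_px pixel size (micrometres).
#' @param n_z number of z-planes; ring intensity fades with depth so the
#'   top-half projection carries the structure.
#' @param z_step_um z-step (micrometres); default 0.37.
#' @param radius_um,ring_width_um ring radius and annulus width (micrometres).
#' @param fg_intensity,bg_intensity foreground/background intensity levels.
#' @param noise_sd additive Gaussian noise SD (0 gives the noise-free stack).
#' @param n_gaps number of arc gaps used when `fragmentation > 0`.
#' @param seed integer seed.
#' @return list with `stack` (an [image_stack()]), `truth` (list:
#'   `true_contiguity` per ring, `clean_mask` logical matrix, `centers`,
#'   `rois` list of ring-bounding polygons in pixel coordinates).
#' @export
simulate_pnn_image <- function(n_rings = 1, fragmentation = 0.25, image_px = 128,
                               um_per_px = 0.1, n_z = 8, z_step_um = 0.37,
                               radius_um = 3, ring_width_um = 0.6,
                               fg_intensity = 200, bg_intensity = 20,
                               noise_sd = 5, n_gaps = 3, seed = NULL) {
  check_positive_scalar(n_rings, "n_rings")
  if (!is.numeric(fragmentation) || fragmentation < 0 || fragmentation > 1) {
    stop("invalid config: 'fragmentation' must lie in [0, 1]", call. = FALSE)
  }
  check_positive_scalar(image_px, "image_px")
  check_positive_scalar(um_per_px, "um_per_px")
  with_seed(seed, {
    r_px <- radius_um / um_per_px
    w_px <- ring_width_um / um_per_px
    # ring centers on a jittered grid, kept clear of borders and each other
    n_side <- ceiling(sqrt(n_rings))
    cell <- image_px / n_side
    centers <- matrix(NA_real_, n_rings, 2)
    k <- 1L
    for (gy in seq_len(n_side)) {
      for (gx in seq_len(n_side)) {
        if (k > n_rings) break
        jit <- stats::runif(2, -0.1, 0.1) * cell
        centers[k, ] <- c((gx - 0.5) * cell + jit[1], (gy - 0.5) * cell + jit[2])
        k <- k + 1L
      }
    }
    yy <- matrix(seq_len(image_px), image_px, image_px)
    xx <- t(yy)
    clean <- matrix(FALSE, image_px, image_px)
    rois <- vector("list", n_rings)
    for (k in seq_len(n_rings)) {
      dx <- xx - centers[k, 1]
      dy <- yy - centers[k, 2]
      dist <- sqrt(dx^2 + dy^2)
      ring <- abs(dist - r_px) <= w_px / 2
      if (fragmentation > 0) {
        theta <- atan2(dy, dx) # (-pi, pi]
        gap_centers <- sort(stats::runif(n_gaps, -pi, pi))
        gap_half <- fragmentation * 2 * pi / n_gaps / 2
        in_gap <- matrix(FALSE, image_px, image_px)
        for (g in gap_centers) {
          dtheta <- abs(((theta - g + pi) %% (2 * pi)) - pi)
          in_gap <- in_gap | dtheta <= gap_half
        }
        ring <- ring & !in_gap
      }
      clean <- clean | ring
      ang <- seq(0, 2 * pi, length.out = 33)[-33]
      rr <- r_px + w_px
      rois[[k]] <- cbind(x = centers[k, 1] + rr * cos(ang),
                         y = centers[k, 2] + rr * sin(ang))
    }
    depth_gain <- exp(-(seq_len(n_z) - 1) / n_z)
    vox <- array(bg_intensity, dim = c(image_px, image_px, n_z))
    for (z in seq_len(n_z)) {
      plane <- vox[, , z]
      plane[clean] <- bg_intensity + fg_intensity * depth_gain[z]
      if (noise_sd > 0) plane <- plane + stats::rnorm(length(plane), 0, noise_sd)
      vox[, , z] <- plane
    }
    stack <- image_stack(vox, um_per_px = um_per_px, z_step_um = z_step_um)
    true_contig <- vapply(seq_len(n_rings), function(k) {
      sub <- clean & in_polygon_mask(image_px, image_px, rois[[k]])
      if (!any(sub)) return(NA_real_)
      contiguity(pnn_mask(sub))$fraction
    }, numeric(1))
    list(stack = stack,
         truth = list(true_contiguity = true_contig, clean_mask = clean,
                      centers = centers, rois = rois))
  })
}

#' Simulate two groups with a known standardized mean difference
#'
#' Group 1 is drawn from `Normal(0, 1)` and group 2 from `Normal(true_d, 1)`,
#' so `true_d` is the population Cohen's d.
#'
#' @param n1,n2 group sizes (each at least 2).
#' @param true_d population standardized mean difference.
#' @param seed integer seed.
#' @return list with numeric vectors `g1`, `g2` and `truth$true_effect_size`.
#' @export
simulate_two_groups <- function(n1, n2, true_d = 0, seed = NULL) {
  if (!is.numeric(n1) || !is.numeric(n2) || n1 < 2 || n2 < 2) {
    stop("invalid config: group sizes must be at least 2", call. = FALSE)
  }
  with_seed(seed, {
    list(g1 = stats::rnorm(n1, 0, 1),
         g2 = stats::rnorm(n2, true_d, 1),
         truth = list(true_effect_size = true_d))
  })
}
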