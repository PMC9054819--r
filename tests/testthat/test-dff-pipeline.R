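# dF/F pipeline: bleach fit, reference scaling, dF/F, baseline correction.

test_that("biexponential fit recovers an in-family noise-free curve", {
  t <- seq(0, 300, by = 0.05)
  f <- 1 * exp(-t / 10) + 0.5 * exp(-t / 100) + 0.2
  fit <- fit_biexponential(f, t)
  expect_lt(fit$sse, 1e-8)
  expect_equal(fit$tau1_s, 10, tolerance = 1e-3)
  expect_equal(fit$tau2_s, 100, tolerance = 1e-3)
  expect_equal(fit$c, 0.2, tolerance = 1e-4)
})

test_that("constant input yields zero amplitudes and c = mean", {
  fit <- fit_biexponential(rep(3, 50), seq_len(50))
  expect_equal(fit$c, 3)
  expect_equal(fit$a1, 0)
  expect_equal(fit$a2, 0)
  expect_equal(fit$sse, 0)
})

test_that("fit beats a 1000-draw random-parameter-search oracle on noisy data", {
  set.seed(42)
  t <- seq(0, 300, by = 0.1)
  f <- 15 * exp(-t / 30) + 25 * exp(-t / 400) + 90 + rnorm(length(t), 0, 0.5)
  fit <- fit_biexponential(f, t)
  expect_lte(fit$sse, oracle_biexp_sse(f, t) + 1e-8)
})

test_that("fitted bleach curve is nonincreasing for nonnegative amplitudes", {
  t <- seq(0, 200, by = 0.5)
  f <- 10 * exp(-t / 20) + 5 * exp(-t / 300) + 50
  fit <- fit_biexponential(f, t)
  curve <- predict(fit, t)
  if (fit$a1 >= 0 && fit$a2 >= 0) expect_true(all(diff(curve) <= 1e-12))
  expect_equal(curve, fit$fitted, tolerance = 1e-8)
})

test_that("scale_reference matches closed-form OLS", {
  ref <- c(1, 2, 3, 4, 5)
  expect_equal(scale_reference(ref, ref)$slope, 1)
  expect_equal(scale_reference(ref, ref)$intercept, 0)
  sc <- scale_reference(ref, 2 * ref + 5)
  expect_equal(sc$slope, 2)
  expect_equal(sc$intercept, 5)
  set.seed(1)
  x <- rnorm(100, 50, 5)
  y <- 1.3 * x + 4 + rnorm(100)
  sc <- scale_reference(x, y)
  o <- oracle_ols(x, y)
  expect_equal(sc$slope, o$slope, tolerance = 1e-10)
  expect_equal(sc$intercept, o$intercept, tolerance = 1e-10)
  expect_error(scale_reference(rep(2, 5), 1:5), "degenerate")
})

test_that("compute_dff implements (F - scaled)/scaled with guards", {
  t <- 1:10
  f <- rep(100, 10)
  expect_equal(compute_dff(f, f, t)$dff, rep(0, 10))
  expect_equal(compute_dff(1.05 * f, f, t)$dff, rep(0.05, 10))
  bad <- f
  bad[4] <- -1
  expect_error(compute_dff(f, bad, t), "index 4")
})

test_that("noise-free simulated transients are recovered at full amplitude", {
  # sparse transients (duty cycle ~1%) so the reference regression, which
  # sees the transients in f470, is not measurably inflated; 100 Hz
  # effective sampling keeps quantization loss at the kernel peak < 0.1%
  cfg <- photom_sim_config(duration_s = 200, frame_rate_hz = 200, n_events = 3,
                           artifact_rate_hz = 0, noise_sd = 0, seed = 8)
  sim <- simulate_session(cfg)
  tr <- process_dff(deinterleave(sim$session), reference = "fitted")
  t_star <- with(cfg, tau_rise_s * tau_decay_s / (tau_decay_s - tau_rise_s) *
                   log(tau_decay_s / tau_rise_s))
  peak_above_baseline <- function(trace, et) {
    sel <- trace$time_s >= et & trace$time_s <= et + 2 * t_star
    base <- stats::median(trace$dff[trace$time_s >= et - 5 & trace$time_s < et])
    max(trace$dff[sel]) - base
  }
  # amplitude above the local pre-event baseline: exact to < 1%
  peaks <- vapply(sim$truth$event_times_s, peak_above_baseline,
                  numeric(1), trace = tr)
  expect_equal(peaks, rep(0.05, 3), tolerance = 0.01)
  # absolute dff peaks carry the small uniform offset left by the reference
  # regression seeing the transients in f470 (~0.07% of baseline here,
  # i.e. ~1.3% of a 5% transient)
  abs_peaks <- vapply(sim$truth$event_times_s, function(et) {
    max(tr$dff[tr$time_s >= et & tr$time_s <= et + 2 * t_star])
  }, numeric(1))
  expect_equal(abs_peaks, rep(0.05, 3), tolerance = 0.025)
  # at 20 Hz per channel, sampling alone can shave ~1.5% off the peak
  sim40 <- simulate_session(photom_sim_config(duration_s = 200, n_events = 3,
                                              artifact_rate_hz = 0,
                                              noise_sd = 0, seed = 8))
  tr40 <- process_dff(deinterleave(sim40$session), reference = "fitted")
  peaks40 <- vapply(sim40$truth$event_times_s, function(et) {
    max(tr40$dff[tr40$time_s >= et & tr40$time_s <= et + 2 * t_star])
  }, numeric(1))
  expect_equal(peaks40, rep(0.05, 3), tolerance = 0.025)
})

test_that("isosbestic reference suppresses shared motion artifacts", {
  art_excess <- function(x, time_s, art_t, width) {
    r <- x - stats::runmed(x, 41)
    sel <- rep(FALSE, length(time_s))
    for (a in art_t) sel <- sel | (time_s >= a & time_s < a + width)
    max(mean(r[sel]^2) - mean(r[!sel]^2), 0)
  }
  for (s in 1:3) {
    cfg <- photom_sim_config(duration_s = 300, seed = s)
    sim <- simulate_session(cfg)
    pair <- deinterleave(sim$session)
    tr <- process_dff(pair) # default isosbestic reference
    naive <- (pair$f470 - mean(pair$f470)) / mean(pair$f470)
    red <- 1 - art_excess(tr$dff, tr$time_s, sim$truth$artifact_times_s,
                          cfg$artifact_width_s) /
      art_excess(naive, pair$time_s, sim$truth$artifact_times_s,
                 cfg$artifact_width_s)
    expect_gte(red, 0.8)
  }
})

test_that("baseline correction matches the printed formula and its limits", {
  # mean(hc) = 0, min(test) = 0: nothing to correct
  expect_equal(as.numeric(baseline_correct(c(0, 0.2), c(-1, 1))), c(0, 0.2))
  # forced minimum: corrected minimum equals the home-cage mean
  out <- baseline_correct(c(-0.5, 0.2), c(0.5, 1.5))
  expect_equal(as.numeric(out), c(1.0, 1.7))
  expect_equal(min(out), 1.0)
  # random vectors match the direct transcription of the formula
  set.seed(3)
  for (i in 1:20) {
    test <- rnorm(50, 0, 0.3)
    hc <- rnorm(200, 0.1, 0.2)
    expect_equal(as.numeric(baseline_correct(test, hc)),
                 oracle_baseline(test, hc), tolerance = 1e-14)
  }
})

test_that("baseline correction is a pure shift using the middle window only", {
  sim <- simulate_session(photom_sim_config(duration_s = 300, seed = 2))
  hc <- process_dff(deinterleave(sim$session))
  test <- dff_trace(seq(0, 10, by = 0.05),
                    rnorm(201, -0.05, 0.02))
  out <- baseline_correct(test, hc)
  expect_equal(stats::var(out$dff), stats::var(test$dff), tolerance = 1e-12)
  shift <- out$dff - test$dff
  expect_equal(max(shift) - min(shift), 0, tolerance = 1e-14)
  # offset derives from the 60-240 s window of the home-cage trace
  hc_mid <- mean(hc$dff[hc$time_s >= 60 & hc$time_s <= 240])
  expect_equal(out$baseline_offset, abs(hc_mid - min(test$dff)),
               tolerance = 1e-12)
  expect_error(baseline_correct(test, hc, hc_window = c(1000, 2000)),
               "empty")
})
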