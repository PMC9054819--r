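# dF/F pipeline: biexponential photobleaching fit on the isosbestic
# channel, linear scaling of the reference onto the signal channel, dF/F
# computation, and home-cage baseline correction.

# Profiled least squares: for fixed time constants the biexponential is
# linear in (a1, a2, c), so the nonlinear search runs over log-taus only.
biexp_sse <- function(log_taus, f, t0) {
  taus <- exp(log_taus)
  X <- cbind(exp(-t0 / taus[1]), exp(-t0 / taus[2]), 1)
  fit <- stats::lm.fit(X, f)
  list(sse = sum(fit$residuals^2), coef = unname(fit$coefficients), taus = taus)
}

#' Fit a biexponential photobleaching curve
#'
#' Fits `F(t) = a1 exp(-t/tau1) + a2 exp(-t/tau2) + c` by nonlinear least
#' squares, profiling the linear amplitudes and searching the two time
#' constants (on a log scale, Nelder-Mead from several starts). The
#' single-exponential special case (`a2 = 0`) is always evaluated as well;
#' if the biexponential search cannot beat it the single-exponential fit is
#' returned with `method = "single_fallback"`, so the reported `sse` never
#' exceeds the single-exponential `sse`. An all-constant input returns
#' `a1 = a2 = 0`, `c = mean(f)`.
#'
#' @param f fluorescence vector (typically the 415 nm isosbestic stream).
#' @param time_s matching time vector (s); at least 5 samples.
#' @return object of class `bleach_fit`: `a1`, `tau1_s`, `a2`, `tau2_s`,
#'   `c`, `sse`, `fitted` (curve on `time_s`), `method`.
#' @export
fit_biexponential <- function(f, time_s) {
  if (length(f) != length(time_s)) stop("f and time_s lengths differ", call. = FALSE)
  if (length(f) < 5L) stop("biexponential fit needs at least 5 samples", call. = FALSE)
  t0 <- time_s - time_s[1]
  span <- max(t0)
  make_fit <- function(a1, tau1, a2, tau2, c, sse, fitted, method) {
    structure(list(a1 = a1, tau1_s = tau1, a2 = a2, tau2_s = tau2, c = c,
                   sse = sse, fitted = fitted, method = method),
              class = "bleach_fit")
  }
  if (stats::sd(f) == 0) {
    return(make_fit(0, span, 0, span, mean(f), 0, rep(mean(f), length(f)),
                    "constant"))
  }
  # single-exponential special case, profiled over one log-tau
  sse1 <- function(log_tau) {
    X <- cbind(exp(-t0 / exp(log_tau)), 1)
    sum(stats::lm.fit(X, f)$residuals^2)
  }
  o1 <- stats::optimize(sse1, interval = log(c(span / 2000, span * 20)))
  tau_s <- exp(o1$minimum)
  X1 <- cbind(exp(-t0 / tau_s), 1)
  c1 <- unname(stats::lm.fit(X1, f)$coefficients)
  single <- make_fit(c1[1], tau_s, 0, span, c1[2], o1$objective,
                     as.numeric(X1 %*% c1), "single_fallback")

  starts <- list(log(c(span / 10, span)),
                 log(c(tau_s / 5, tau_s * 5)),
                 log(c(tau_s, span * 5)),
                 log(c(span / 50, span / 2)))
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      stats::optim(s, function(p) biexp_sse(p, f, t0)$sse,
                   method = "Nelder-Mead",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (!is.null(best) && best$value <= single$sse + 1e-12) {
    r <- biexp_sse(best$par, f, t0)
    co <- r$coef
    co[is.na(co)] <- 0
    ord <- order(r$taus)
    fitted <- as.numeric(cbind(exp(-t0 / r$taus[1]), exp(-t0 / r$taus[2]), 1) %*% co)
    if (any(!is.finite(fitted))) return(single)
    return(make_fit(co[ord[1]], r$taus[ord[1]], co[ord[2]], r$taus[ord[2]],
                    co[3], r$sse, fitted, "biexponential"))
  }
  single
}

#' Evaluate a bleach fit on an arbitrary time grid
#'
#' @param object a `bleach_fit`.
#' @param time_s time vector (s), on the same clock (and origin) as the data
#'   the fit was computed from.
#' @param t_origin time of the first fitted sample; defaults to `time_s[1]`.
#' @param ... unused.
#' @return numeric vector of fitted fluorescence values.
#' @export
predict.bleach_fit <- function(object, time_s, t_origin = time_s[1], ...) {
  t0 <- time_s - t_origin
  biexp_curve(t0, object$a1, object$tau1_s, object$a2, object$tau2_s, object$c)
}

#' Linearly scale a reference vector onto the signal channel
#'
#' Ordinary least squares of `f470` on the reference: the returned `scaled`
#' vector is `slope * reference + intercept`, the best linear rendering of
#' the reference in signal-channel units.
#'
#' @param reference reference vector (fitted bleach curve or raw isosbestic
#'   stream).
#' @param f470 signal-channel fluorescence, same length.
#' @return object of class `scaled_reference`: `slope`, `intercept`,
#'   `scaled`.
#' @export
scale_reference <- function(reference, f470) {
  if (length(reference) != length(f470)) {
    stop("scale_reference: vectors must have equal length", call. = FALSE)
  }
  if (stats::var(reference) == 0) {
    stop("scale_reference: degenerate regression (zero-variance reference)",
         call. = FALSE)
  }
  slope <- stats::cov(reference, f470) / stats::var(reference)
  intercept <- mean(f470) - slope * mean(reference)
  structure(list(slope = slope, intercept = intercept,
                 scaled = slope * reference + intercept),
            class = "scaled_reference")
}

#' Construct a dF/F trace
#'
#' @param time_s uniform time grid (s).
#' @param dff dimensionless dF/F vector, same length.
#' @param baseline_offset additive offset applied by baseline correction
#'   (0 until corrected).
#' @param provenance list of processing metadata (bleach fit, scaling,
#'   reference choice).
#' @return object of class `dff_trace`.
#' @export
dff_trace <- function(time_s, dff, baseline_offset = 0, provenance = list()) {
  if (length(time_s) != length(dff)) {
    stop("dff_trace: time and value lengths differ", call. = FALSE)
  }
  if (any(!is.finite(dff))) stop("dff_trace: non-finite dF/F values", call. = FALSE)
  structure(list(time_s = as.numeric(time_s), dff = as.numeric(dff),
                 baseline_offset = baseline_offset, provenance = provenance),
            class = "dff_trace")
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf("dff_trace: %d samples over %.1f s (offset %+.4f)\n",
              length(x$dff), diff(range(x$time_s)), x$baseline_offset))
  invisible(x)
}

#' Compute dF/F from the signal channel and a scaled reference
#'
#' `dff[i] = (f470[i] - scaled[i]) / scaled[i]`.
#'
#' @param f470 signal-channel fluorescence.
#' @param scaled a `scaled_reference` or a numeric vector of scaled
#'   reference values (all strictly positive).
#' @param time_s time grid for the returned trace.
#' @param provenance optional provenance list.
#' @return a [dff_trace()].
#' @export
compute_dff <- function(f470, scaled, time_s, provenance = list()) {
  sc <- if (inherits(scaled, "scaled_reference")) scaled$scaled else scaled
  if (length(sc) != length(f470)) {
    stop("compute_dff: vectors must have equal length", call. = FALSE)
  }
  bad <- which(sc <= 0)
  if (length(bad)) {
    stop(sprintf("compute_dff: scaled reference is non-positive at index %d",
                 bad[1]), call. = FALSE)
  }
  dff_trace(time_s, (f470 - sc) / sc, provenance = provenance)
}

#' Full channel-pair to dF/F transform
#'
#' Fits a biexponential bleach curve to the 415 nm isosbestic stream, maps a
#' reference vector onto the 470 nm stream by ordinary least squares, and
#' divides out the scaled reference. With `reference = "isosbestic"` (the
#' default) the raw 415 stream is the reference, so shared motion artifacts
#' present in both channels are subtracted out along with the bleach trend.
#' With `reference = "fitted"` only the smooth fitted bleach curve is
#' subtracted (pure debleaching; artifacts remain).
#'
#' @param pair a `channel_pair` from [deinterleave()].
#' @param reference `"isosbestic"` or `"fitted"`.
#' @return a [dff_trace()] with fit and scaling parameters in
#'   `$provenance`.
#' @export
process_dff <- function(pair, reference = c("isosbestic", "fitted")) {
  reference <- match.arg(reference)
  fit <- fit_biexponential(pair$f415, pair$time_s)
  ref <- if (reference == "fitted") fit$fitted else pair$f415
  sc <- scale_reference(ref, pair$f470)
  compute_dff(pair$f470, sc, pair$time_s,
              provenance = list(
                reference = reference,
                bleach_fit = fit[c("a1", "tau1_s", "a2", "tau2_s", "c",
                                   "sse", "method")],
                scaling = sc[c("slope", "intercept")]
              ))
}

#' Home-cage baseline correction of a test-session dF/F trace
#'
#' Computes the mean dF/F of the home-cage recording over `hc_window`
#' (default the middle 3 min of a 5-min baseline, chosen to avoid
#' handling-stress contamination at the edges) and adds the absolute
#' difference between that mean and the minimum of the test trace to every
#' test value. The shift lifts traces whose dF/F dropped below the x-axis:
#' whenever `min(test) <= mean(hc)`, the corrected minimum equals the
#' home-cage mean exactly.
#'
#' @param test dF/F of the test session (a [dff_trace()] or numeric vector).
#' @param hc dF/F of the home-cage recording (a [dff_trace()] or numeric
#'   vector).
#' @param hc_time_s time vector for `hc` when it is a bare numeric vector;
#'   taken from the trace otherwise. When `NULL` for a bare vector, the
#'   whole vector is used regardless of `hc_window`.
#' @param hc_window `(start_s, end_s)` window of the home-cage recording
#'   used for the baseline mean; default `c(60, 240)`.
#' @return the corrected [dff_trace()] (or numeric vector if `test` was
#'   one), with `baseline_offset` recorded.
#' @export
baseline_correct <- function(test, hc, hc_time_s = NULL,
                             hc_window = c(60, 240)) {
  hc_vals <- if (inherits(hc, "dff_trace")) hc$dff else as.numeric(hc)
  hc_t <- if (inherits(hc, "dff_trace")) hc$time_s else hc_time_s
  if (!is.null(hc_t)) {
    sel <- hc_t >= hc_window[1] & hc_t <= hc_window[2]
    if (!any(sel)) stop("baseline_correct: empty home-cage window", call. = FALSE)
    hc_vals <- hc_vals[sel]
  }
  if (length(hc_vals) == 0L) stop("baseline_correct: empty home-cage vector", call. = FALSE)
  test_vals <- if (inherits(test, "dff_trace")) test$dff else as.numeric(test)
  if (length(test_vals) == 0L) stop("baseline_correct: empty test vector", call. = FALSE)
  offset <- abs(mean(hc_vals) - min(test_vals))
  if (inherits(test, "dff_trace")) {
    out <- test
    out$dff <- test$dff + offset
    out$baseline_offset <- test$baseline_offset + offset
    out
  } else {
    structure(test_vals + offset, baseline_offset = offset)
  }
}
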