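# Independent oracles used by the unit and acceptance tests. Each one is a
# deliberately different algorithm from the implementation it checks.

# Connected-component contiguity by iterative minimum-label propagation
# (fixpoint over shifted copies of the label matrix) -- independent of the
# package's breadth-first-search labelling.
oracle_contiguity <- function(mask, connectivity = 8) {
  ny <- nrow(mask)
  nx <- ncol(mask)
  offs <- if (connectivity == 8) {
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  shifted <- function(m, dy, dx) {
    out <- matrix(Inf, ny, nx)
    ys <- seq_len(ny) - dy
    xs <- seq_len(nx) - dx
    oky <- ys >= 1 & ys <= ny
    okx <- xs >= 1 & xs <= nx
    out[oky, okx] <- m[ys[oky], xs[okx]]
    out
  }
  lab <- matrix(Inf, ny, nx)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    new <- lab
    for (o in offs) new <- pmin(new, shifted(lab, o[1], o[2]))
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  sizes <- table(lab[is.finite(lab)])
  list(fraction = max(sizes) / sum(mask), n_components = length(sizes))
}

# Direct transcription of the printed baseline-correction formula:
# corrected = test + | -mean(hc) - (-min(test)) |
oracle_baseline <- function(test, hc) {
  test + abs(-mean(hc) - (-min(test)))
}

# Closed-form OLS via the normal equations.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  list(intercept = beta[1], slope = beta[2])
}

# Brute-force per-sample AUC (positive part, rectangle rule).
oracle_auc <- function(dff, dt) {
  s <- 0
  for (v in dff) if (v > 0) s <- s + v * dt
  s
}

# Brute-force nearest-behaviour-sample index (all pairs; ties at clock
# resolution, 1 ns, go to the earlier sample).
oracle_nearest <- function(t, beh_t) {
  vapply(t, function(ti) {
    d <- abs(beh_t - ti)
    which(d <= min(d) + 1e-9)[1]
  }, integer(1))
}

# Random-parameter-search biexponential fit: 1000 log-uniform (tau1, tau2)
# draws with the linear part solved exactly; returns the best SSE found.
oracle_biexp_sse <- function(f, time_s, n = 1000, seed = 99) {
  t0 <- time_s - time_s[1]
  span <- max(t0)
  set.seed(seed)
  best <- Inf
  for (i in seq_len(n)) {
    taus <- exp(stats::runif(2, log(span / 500), log(span * 10)))
    X <- cbind(exp(-t0 / taus[1]), exp(-t0 / taus[2]), 1)
    sse <- sum(stats::lm.fit(X, f)$residuals^2)
    if (is.finite(sse) && sse < best) best <- sse
  }
  best
}

# Pooled-SD Cohen's d written out term by term.
oracle_cohen_d <- function(g1, g2) {
  n1 <- length(g1)
  n2 <- length(g2)
  s1 <- sum((g1 - mean(g1))^2) / (n1 - 1)
  s2 <- sum((g2 - mean(g2))^2) / (n2 - 1)
  sp <- sqrt(((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2))
  (mean(g2) - mean(g1)) / sp
}

# Random dF/F trace plus an epoch set tiling its span, for metric oracles.
random_trace_and_epochs <- function(seed, n = 200, fs = 20) {
  set.seed(seed)
  dt <- 1 / fs
  time_s <- (seq_len(n) - 1) * dt
  trace <- fiberpnn::dff_trace(time_s, stats::rnorm(n, 0.02, 0.05))
  # random run lengths tiling all n samples
  runs <- c()
  left <- n
  while (left > 0) {
    r <- min(left, sample(5:60, 1))
    runs <- c(runs, r)
    left <- left - r
  }
  states <- rep(c("freezing", "moving"), length.out = length(runs))
  if (sample(c(TRUE, FALSE), 1)) states <- rev(states)
  ends <- cumsum(runs)
  starts <- ends - runs + 1L
  # boundaries placed exactly on grid values so adjacent half-open epochs
  # partition the samples without floating-point double counting
  eps <- fiberpnn::epoch_set(
    data.frame(start_s = time_s[starts],
               end_s = c(time_s[starts[-1]], n * dt),
               state = states, stringsAsFactors = FALSE),
    min_bout_s = 0
  )
  list(trace = trace, epochs = eps, dt = dt)
}
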