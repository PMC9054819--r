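# Estimation statistics for two-group comparisons: Cohen's d with
# bias-corrected and accelerated (BCa) bootstrap confidence intervals.

#' Cohen's d (pooled standard deviation)
#'
#' `d = (mean(g2) - mean(g1)) / s_p` with
#' `s_p = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`. No
#' small-sample (Hedges) correction is applied unless requested.
#'
#' @param g1,g2 numeric sample vectors, each with at least 2 finite values.
#' @param hedges apply Hedges' small-sample correction factor
#'   `1 - 3 / (4 (n1 + n2) - 9)` (default `FALSE`).
#' @return the standardized mean difference (group 2 minus group 1).
#' @export
cohen_d <- function(g1, g2, hedges = FALSE) {
  n1 <- length(g1)
  n2 <- length(g2)
  if (n1 < 2L || n2 < 2L) stop("cohen_d: each group needs >= 2 values", call. = FALSE)
  sp2 <- ((n1 - 1) * stats::var(g1) + (n2 - 1) * stats::var(g2)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("cohen_d: zero pooled standard deviation", call. = FALSE)
  d <- (mean(g2) - mean(g1)) / sqrt(sp2)
  if (hedges) d <- d * (1 - 3 / (4 * (n1 + n2) - 9))
  d
}

# Cohen's d for B resamples at once. idx1: n1 x B matrix of indices into g1,
# idx2: n2 x B into g2. Returns a length-B vector (NA where the pooled SD of
# a resample is zero).
cohen_d_boot <- function(g1, g2, idx1, idx2) {
  n1 <- nrow(idx1)
  n2 <- nrow(idx2)
  x1 <- matrix(g1[idx1], n1)
  x2 <- matrix(g2[idx2], n2)
  m1 <- colMeans(x1)
  m2 <- colMeans(x2)
  v1 <- (colSums(x1^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(x2^2) - n2 * m2^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  out <- (m2 - m1) / sqrt(sp2)
  out[sp2 <= 0] <- NA_real_
  out
}

#' Bootstrap effect size with BCa confidence interval
#'
#' Resamples each group independently with replacement `n_resamples` times
#' and computes Cohen's d for each resample. The BCa interval uses the
#' bias-correction `z0 = qnorm(F)` where `F` is the fraction of resampled d
#' values below the observed d (exact ties counted as half), and the
#' acceleration `a` from the jackknife skewness of d over leave-one-out
#' deletions across both groups. Resamples with zero pooled variance are
#' skipped and counted; more than 50% degenerate resamples is an error.
#'
#' @param g1,g2 numeric sample vectors.
#' @param n_resamples number of bootstrap resamples (default 5000).
#' @param ci_level confidence level (default 0.95). A level of 0 collapses
#'   the interval to the bootstrap median when `z0 = 0`.
#' @param method `"BCa"` (default) or `"percentile"`.
#' @param seed integer seed for reproducible resampling.
#' @param keep_resamples retain the resampled d distribution in the result
#'   (for estimation plots).
#' @return object of class `two_group_effect`: `d`, `ci_low`, `ci_high`,
#'   `n_resamples`, `ci_level`, `method`, `seed`, `n_degenerate`, `z0`,
#'   `acceleration`, and optionally `resamples`.
#' @export
bootstrap_effect <- function(g1, g2, n_resamples = 5000, ci_level = 0.95,
                             method = c("BCa", "percentile"), seed = NULL,
                             keep_resamples = FALSE) {
  method <- match.arg(method)
  if (n_resamples < 1) stop("n_resamples must be >= 1", call. = FALSE)
  if (ci_level < 0 || ci_level >= 1) stop("ci_level must lie in [0, 1)", call. = FALSE)
  d_obs <- cohen_d(g1, g2)
  n1 <- length(g1)
  n2 <- length(g2)
  if (method == "BCa" && (n1 < 3L || n2 < 3L)) {
    stop("BCa needs >= 3 values per group for the jackknife; use method = 'percentile'",
         call. = FALSE)
  }
  with_seed(seed, {
    idx1 <- matrix(sample.int(n1, n1 * n_resamples, replace = TRUE), n1)
    idx2 <- matrix(sample.int(n2, n2 * n_resamples, replace = TRUE), n2)
    dstar <- cohen_d_boot(g1, g2, idx1, idx2)
    n_degen <- sum(is.na(dstar))
    if (n_degen > n_resamples / 2) {
      stop("bootstrap_effect: more than 50% of resamples degenerate", call. = FALSE)
    }
    dstar <- dstar[!is.na(dstar)]
    b <- length(dstar)

    if (method == "BCa") {
      frac <- (sum(dstar < d_obs) + 0.5 * sum(dstar == d_obs)) / b
      frac <- min(max(frac, 1 / (b + 1)), b / (b + 1)) # avoid infinite z0
      z0 <- stats::qnorm(frac)
      # jackknife over both groups' leave-one-out deletions
      theta <- c(
        vapply(seq_len(n1), function(i) cohen_d(g1[-i], g2), numeric(1)),
        vapply(seq_len(n2), function(i) cohen_d(g1, g2[-i]), numeric(1))
      )
      td <- mean(theta) - theta
      denom <- 6 * sum(td^2)^1.5
      a <- if (denom == 0) 0 else sum(td^3) / denom
      z_alpha <- stats::qnorm(c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2))
      adj <- stats::pnorm(z0 + (z0 + z_alpha) / (1 - a * (z0 + z_alpha)))
      ci <- stats::quantile(dstar, adj, names = FALSE, type = 7)
    } else {
      z0 <- NA_real_
      a <- NA_real_
      ci <- stats::quantile(dstar, c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2),
                            names = FALSE, type = 7)
    }
    structure(list(d = d_obs, ci_low = ci[1], ci_high = ci[2],
                   n_resamples = n_resamples, ci_level = ci_level,
                   method = method, seed = seed, n_degenerate = n_degen,
                   z0 = z0, acceleration = a,
                   resamples = if (keep_resamples) dstar else NULL),
              class = "two_group_effect")
  })
}

#' @export
print.two_group_effect <- function(x, ...) {
  cat(sprintf("Cohen's d = %.3f, %s %.0f%% CI [%.3f, %.3f] (%d resamples)\n",
              x$d, x$method, 100 * x$ci_level, x$ci_low, x$ci_high,
              x$n_resamples))
  invisible(x)
}

#' Multiple independent two-group comparisons
#'
#' Runs [bootstrap_effect()] independently for each labelled pair — pure
#' estimation, with no cross-pair pooling and no multiplicity adjustment.
#' Each pair's seed is derived deterministically from the master seed and
#' the pair's label, so results are invariant to pair ordering. A failing
#' pair is reported as an error entry without aborting the remaining pairs.
#'
#' @param pairs named list; each element a list with components `g1` and
#'   `g2`.
#' @param n_resamples,ci_level,method passed to [bootstrap_effect()].
#' @param seed master seed from which per-label seeds are derived.
#' @return named list of `two_group_effect` objects (or `error` entries), in
#'   input order.
#' @export
multi_two_group <- function(pairs, n_resamples = 5000, ci_level = 0.95,
                            method = "BCa", seed = NULL) {
  if (length(pairs) < 1L) stop("multi_two_group: need at least one pair", call. = FALSE)
  if (is.null(names(pairs)) || any(names(pairs) == "")) {
    stop("multi_two_group: pairs must be named", call. = FALSE)
  }
  out <- vector("list", length(pairs))
  names(out) <- names(pairs)
  for (lab in names(pairs)) {
    pair_seed <- if (is.null(seed)) NULL else derive_seed(seed, lab)
    out[[lab]] <- tryCatch(
      bootstrap_effect(pairs[[lab]]$g1, pairs[[lab]]$g2,
                       n_resamples = n_resamples, ci_level = ci_level,
                       method = method, seed = pair_seed),
      error = function(e) list(error = conditionMessage(e))
    )
  }
  out
}
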