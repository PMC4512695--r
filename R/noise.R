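#' Colored-noise (Ornstein-Uhlenbeck) growth-rate parameters
#'
#' Parameters of the stationary Gaussian colored-noise process \eqn{g_c(t)}
#' used as a fluctuating growth rate: zero mean, stationary variance `D`
#' (units 1/time^2) and exponentially decaying autocovariance
#' \deqn{\langle g_c(t) g_c(t')\rangle = D e^{-|t-t'|/\tau_c}.}
#' The white-noise limit is obtained by letting `tau_c -> 0` while holding
#' the product `D * tau_c` fixed; no separate white-noise generator is
#' provided.
#'
#' @param D noise magnitude (stationary variance of the growth rate),
#'   must be `>= 0`.
#' @param tau_c autocorrelation time, must be `> 0`.
#' @return An object of class `noise_params`.
#' @examples
#' np <- noise_params(D = 1, tau_c = 1)
#' ens <- sample_ou(np, times = seq(0, 10, by = 0.1), n_reps = 50, seed = 1)
#' @export
noise_params <- function(D, tau_c) {
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D < 0)
    stop("`D` must be a single finite number >= 0", call. = FALSE)
  if (!is.numeric(tau_c) || length(tau_c) != 1L || !is.finite(tau_c) || tau_c <= 0)
    stop("`tau_c` must be a single finite number > 0", call. = FALSE)
  structure(list(D = as.numeric(D), tau_c = as.numeric(tau_c)),
            class = "noise_params")
}

#' @export
print.noise_params <- function(x, ...) {
  cat(sprintf("colored-noise parameters: D = %g (1/time^2), tau_c = %g (time)\n",
              x$D, x$tau_c))
  invisible(x)
}

.check_times <- function(times) {
  if (!is.numeric(times) || length(times) < 1L || anyNA(times))
    stop("`times` must be a non-empty numeric vector", call. = FALSE)
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  as.numeric(times)
}

## Prefix-stable per-replicate seeds: drawing n seeds from the root seed
## sequentially means the first k replicates are identical whatever n_reps is.
.replicate_seeds <- function(seed, n_reps) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n_reps)
}

## Exact-in-distribution OU paths on an arbitrary strictly increasing grid.
## Each row is one replicate generated from its own seed stream.
.ou_paths <- function(params, times, rep_seeds, stationary_start = TRUE) {
  n_t <- length(times)
  n_reps <- length(rep_seeds)
  eps <- matrix(0, n_reps, n_t)
  for (i in seq_len(n_reps)) {
    set.seed(rep_seeds[i])
    eps[i, ] <- stats::rnorm(n_t)
  }
  g <- matrix(0, n_reps, n_t)
  g[, 1] <- if (stationary_start) sqrt(params$D) * eps[, 1] else 0
  if (n_t > 1L) {
    dts <- diff(times)
    a <- exp(-dts / params$tau_c)
    b <- sqrt(params$D * (1 - a^2))
    for (j in seq_len(n_t - 1L))
      g[, j + 1L] <- a[j] * g[, j] + b[j] * eps[, j + 1L]
  }
  g
}

#' Sample an ensemble of colored-noise growth-rate paths
#'
#' Generates independent replicates of the stationary Gaussian process with
#' autocovariance \eqn{D e^{-\Delta t/\tau_c}} using the exact discrete
#' update \eqn{g(t+dt) = g(t) e^{-dt/\tau_c} +
#' \sqrt{D(1-e^{-2 dt/\tau_c})}\,\xi}, which is exact in distribution for
#' any step size.  By default the initial value is drawn from the
#' stationary law \eqn{N(0, D)}; `stationary_start = FALSE` gives a cold
#' start at 0.
#'
#' Replicate streams are derived deterministically from the root seed, so
#' increasing `n_reps` extends the ensemble without altering earlier
#' replicates.
#'
#' @param params a [noise_params()] object.
#' @param times strictly increasing sampling grid.
#' @param n_reps number of independent replicates (`>= 1`).
#' @param seed integer root seed.
#' @param stationary_start draw `g(0)` from `N(0, D)` (default) or start
#'   at 0.
#' @return An object of class `noise_ensemble`: list with `times`,
#'   `values` (`n_reps x n_times` matrix), `params`, `seed`.
#' @export
sample_ou <- function(params, times, n_reps, seed, stationary_start = TRUE) {
  stopifnot(inherits(params, "noise_params"))
  times <- .check_times(times)
  if (!is.numeric(n_reps) || n_reps < 1) stop("`n_reps` must be >= 1", call. = FALSE)
  n_reps <- as.integer(n_reps)
  g <- .ou_paths(params, times, .replicate_seeds(seed, n_reps), stationary_start)
  structure(list(times = times, values = g, params = params,
                 seed = as.integer(seed), stationary_start = stationary_start),
            class = "noise_ensemble")
}

#' @export
print.noise_ensemble <- function(x, ...) {
  cat(sprintf("colored-noise ensemble: %d replicates x %d time points on [%g, %g]\n",
              nrow(x$values), ncol(x$values), min(x$times), max(x$times)))
  print(x$params)
  invisible(x)
}

.grid_dt <- function(times) {
  dts <- diff(times)
  if (length(dts) == 0L) stop("grid has a single time point", call. = FALSE)
  dt <- dts[1]
  if (any(abs(dts - dt) > 1e-8 * max(dt, 1)))
    stop("operation requires a uniform time grid", call. = FALSE)
  dt
}

#' Ensemble estimate of the noise autocovariance
#'
#' Unbiased ensemble-average estimator of the lagged covariance
#' \eqn{\langle g(t) g(t+\Delta)\rangle} on a uniform grid: products are
#' averaged over time pairs within each replicate (the process has known
#' zero mean, so no mean is subtracted) and then across replicates; the
#' standard error is the between-replicate spread.
#'
#' @param ensemble a `noise_ensemble` (or any list with uniform `times`
#'   and a replicate-by-time `values` matrix).
#' @param max_lag largest lag to estimate; must be smaller than the time
#'   span of the grid.
#' @return A data.frame of class `autocorr_table` with columns `lag`,
#'   `acov`, `se`.
#' @export
estimate_autocorrelation <- function(ensemble, max_lag) {
  v <- ensemble$values
  if (is.null(v) || nrow(v) < 1L) stop("ensemble is empty", call. = FALSE)
  dt <- .grid_dt(ensemble$times)
  span <- max(ensemble$times) - min(ensemble$times)
  if (max_lag >= span) stop("`max_lag` must be smaller than the grid span", call. = FALSE)
  n_t <- ncol(v)
  L <- floor(max_lag / dt + 1e-9)
  out <- lapply(0:L, function(m) {
    prod <- v[, seq_len(n_t - m), drop = FALSE] * v[, seq_len(n_t - m) + m, drop = FALSE]
    per_rep <- rowMeans(prod)
    data.frame(lag = m * dt, acov = mean(per_rep),
               se = if (length(per_rep) > 1L) stats::sd(per_rep) / sqrt(length(per_rep)) else NA_real_)
  })
  structure(do.call(rbind, out), class = c("autocorr_table", "data.frame"))
}

#' Recover (D, tau_c) from an autocovariance table
#'
#' `D` is read off the lag-0 estimate; `tau_c` comes from a log-linear
#' least-squares fit of the positive-lag estimates (contiguous run of
#' positive values starting at the smallest positive lag).
#'
#' @param autocorr a table as returned by [estimate_autocorrelation()].
#' @return list with elements `D`, `tau_c` and the underlying `fit`.
#' @export
fit_noise_params <- function(autocorr) {
  stopifnot(is.data.frame(autocorr), all(c("lag", "acov") %in% names(autocorr)))
  a0 <- autocorr$acov[autocorr$lag == 0]
  if (length(a0) != 1L || !is.finite(a0) || a0 <= 0)
    stop("table must contain a positive lag-0 estimate", call. = FALSE)
  pos <- autocorr[autocorr$lag > 0, , drop = FALSE]
  pos <- pos[order(pos$lag), , drop = FALSE]
  keep <- cumprod(pos$acov > 0) > 0   # contiguous positive run from lag dt
  if (sum(keep) < 3L)
    stop(sprintf(paste("need >= 3 contiguous positive-lag points with positive",
                       "autocovariance for the log-linear fit (got %d);",
                       "smallest positive lags may be noise-dominated"), sum(keep)),
         call. = FALSE)
  pos <- pos[keep, , drop = FALSE]
  fit <- stats::lm(log(acov) ~ lag, data = pos)
  slope <- stats::coef(fit)[["lag"]]
  if (!is.finite(slope) || slope >= 0)
    stop("log-linear fit has non-negative slope; autocovariance does not decay",
         call. = FALSE)
  list(D = a0, tau_c = -1 / slope, fit = fit)
}

#' Two-state Markov decomposition of an intermittent noise process
#'
#' Assigns each sample to state 0 (value `<= 0`; exact zeros are a
#' probability-zero event and go to state 0 for determinism) or state 1
#' (value `> 0`), counts transitions between consecutive samples pooled
#' over replicates, and row-normalizes.  Longer correlation times raise
#' the 0->0 and 1->1 frequencies, i.e. increase intermittency.
#'
#' @param ensemble a `noise_ensemble` on a uniform grid with at least two
#'   time points.
#' @return An object of class `markov_decomposition`: transition
#'   frequencies `p00`, `p01`, `p10`, `p11`, occupancies `pi0`, `pi1`,
#'   sampling interval `dt`, and the raw transition counts.
#' @export
markov_decompose <- function(ensemble) {
  v <- ensemble$values
  if (is.null(v) || ncol(v) < 2L)
    stop("ensemble must have at least two time points", call. = FALSE)
  dt <- .grid_dt(ensemble$times)
  s <- v > 0
  from <- s[, -ncol(s), drop = FALSE]
  to <- s[, -1L, drop = FALSE]
  n00 <- sum(!from & !to); n01 <- sum(!from & to)
  n10 <- sum(from & !to);  n11 <- sum(from & to)
  r0 <- n00 + n01; r1 <- n10 + n11
  structure(list(p00 = n00 / r0, p01 = n01 / r0,
                 p10 = n10 / r1, p11 = n11 / r1,
                 pi0 = mean(!s), pi1 = mean(s), dt = dt,
                 counts = c(n00 = n00, n01 = n01, n10 = n10, n11 = n11)),
            class = "markov_decomposition")
}

#' @export
print.markov_decomposition <- function(x, ...) {
  cat(sprintf("two-state Markov decomposition (dt = %g):\n", x$dt))
  cat(sprintf("  p00 = %.4f  p01 = %.4f\n  p10 = %.4f  p11 = %.4f\n",
              x$p00, x$p01, x$p10, x$p11))
  cat(sprintf("  occupancy: pi0 = %.4f, pi1 = %.4f\n", x$pi0, x$pi1))
  invisible(x)
}
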