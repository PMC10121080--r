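# Independent oracles used across the suite.

with_seed_test <- function(seed, code) {
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Analytic biexponential kernel (unit peak), times in ms.
biexp_analytic <- function(t_ms, tau_rise_ms, tau_decay_ms) {
  f <- function(t) exp(-t / tau_decay_ms) - exp(-t / tau_rise_ms)
  pk <- stats::optimize(f, c(0, 20 * tau_rise_ms), maximum = TRUE)
  f(t_ms) / pk$objective
}

# Analytic 10-90% rise and 1/e decay times of the biexponential kernel (ms),
# by root finding on the continuous kernel.
biexp_kinetics_oracle <- function(tau_rise_ms, tau_decay_ms) {
  f <- function(t) exp(-t / tau_decay_ms) - exp(-t / tau_rise_ms)
  pk <- stats::optimize(f, c(0, 20 * tau_rise_ms), maximum = TRUE,
                        tol = 1e-12)
  lev_up <- function(p) stats::uniroot(function(t) f(t) / pk$objective - p,
                                       c(1e-9, pk$maximum), tol = 1e-12)$root
  lev_dn <- function(p) stats::uniroot(function(t) f(t) / pk$objective - p,
                                       c(pk$maximum, 50 * tau_decay_ms),
                                       tol = 1e-12)$root
  list(rise_ms = lev_up(0.9) - lev_up(0.1),
       decay_ms = lev_dn(exp(-1)) - pk$maximum,
       peak_ms = pk$maximum)
}

# Maximum average slope of the alpha function A*(t/tau)*exp(1 - t/tau) over
# a window of width w_ms (all times ms, A in mV): the best any w_ms-window
# regression can do on a noiseless waveform.
alpha_max_windowed_slope <- function(A_mV, tau_ms, w_ms) {
  Fa <- function(t) ifelse(t <= 0, 0, A_mV * (t / tau_ms) * exp(1 - t / tau_ms))
  obj <- function(t0) (Fa(t0 + w_ms) - Fa(t0)) / w_ms
  stats::optimize(obj, c(0, 3 * tau_ms), maximum = TRUE)$objective  # mV/ms = V/s
}

# Exact two-sided Mann-Whitney p value by full enumeration of all
# C(n1+n2, n1) group labelings (midrank scores, ties as they stand).
mw_enumeration_oracle <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(r), n1)
  sums <- apply(combs, 2, function(i) sum(r[i]))
  lo <- mean(sums <= w_obs + 1e-9)
  hi <- mean(sums >= w_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# Numeric t quantile by quadrature on the t density (oracle for qt).
t_quantile_quadrature <- function(p, df) {
  dens <- function(x) stats::dt(x, df)
  stats::uniroot(function(q)
    stats::integrate(dens, -Inf, q, rel.tol = 1e-9)$value - p,
    c(-10, 10), tol = 1e-9)$root
}
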