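# Synthetic voltage-clamp traces: Poisson event trains convolved with a
# biexponential kernel plus white Gaussian noise, with exact ground truth.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' Biexponential postsynaptic-current kernel
#'
#' `k(t) = (exp(-t/tau_decay) - exp(-t/tau_rise))`, normalized so that its
#' maximum over the supplied time grid equals 1.
#'
#' @param t_s Times (s), from 0.
#' @param tau_rise_ms,tau_decay_ms Kinetic time constants (ms);
#'   `tau_decay > tau_rise > 0`.
#' @return Numeric vector of kernel values with unit peak.
#' @export
psc_kernel <- function(t_s, tau_rise_ms, tau_decay_ms) {
  if (!(tau_decay_ms > tau_rise_ms && tau_rise_ms > 0))
    stop("validation error: need tau_decay > tau_rise > 0", call. = FALSE)
  tr <- tau_rise_ms / 1000
  td <- tau_decay_ms / 1000
  k <- exp(-t_s / td) - exp(-t_s / tr)
  k / max(k)
}

#' Simulate a postsynaptic-current sweep with known event ground truth
#'
#' Generates a voltage-clamp current trace as a homogeneous Poisson train of
#' synaptic events, each a biexponential kernel scaled to a lognormally drawn
#' peak amplitude, plus additive white Gaussian noise. Event times are
#' quantized to the sampling grid and the kernel is normalized to unit peak
#' on that grid, so ground-truth amplitudes are directly comparable to
#' measured baseline-to-peak amplitudes.
#'
#' @param rate_Hz Mean event rate (>= 0).
#' @param duration_s Trace duration (s).
#' @param tau_rise_ms,tau_decay_ms Kernel time constants (ms).
#' @param amp_mean_pA Mean of the lognormal peak-amplitude distribution (pA).
#' @param amp_sigma Log-scale standard deviation of the amplitude
#'   distribution; 0 gives fixed amplitudes.
#' @param noise_sd_pA Standard deviation of the additive Gaussian noise (pA).
#' @param polarity `"inward"` (negative deflections, EPSC-like at negative
#'   holding potentials) or `"outward"`.
#' @param sampling_rate Hz.
#' @param seed Optional RNG seed; the global RNG state is restored afterwards.
#' @param event_times_s Optional fixed event times overriding the Poisson
#'   draw (quantized to the sampling grid), for deterministic fixtures.
#' @return List with `sweep` (an `ephys_sweep`) and `truth`, a tibble of the
#'   exact event times and (positive-magnitude) peak amplitudes.
#' @export
simulate_psc_trace <- function(rate_Hz, duration_s,
                               tau_rise_ms = 1, tau_decay_ms = 10,
                               amp_mean_pA = 20, amp_sigma = 0.3,
                               noise_sd_pA = 2,
                               polarity = c("inward", "outward"),
                               sampling_rate = 10000, seed = NULL,
                               event_times_s = NULL) {
  polarity <- match.arg(polarity)
  if (rate_Hz < 0) stop("validation error: rate must be >= 0", call. = FALSE)
  with_seed(seed, {
    n_samp <- round(duration_s * sampling_rate)
    times <- if (is.null(event_times_s)) {
      n_ev <- stats::rpois(1, rate_Hz * duration_s)
      sort(round(stats::runif(n_ev, 0, duration_s - 1e-9) *
                   sampling_rate)) / sampling_rate
    } else sort(round(event_times_s * sampling_rate)) / sampling_rate
    n_ev <- length(times)
    if (amp_sigma > 0) {
      meanlog <- log(amp_mean_pA) - amp_sigma^2 / 2
      amps <- stats::rlnorm(n_ev, meanlog, amp_sigma)
    } else {
      amps <- rep(amp_mean_pA, n_ev)
    }
    kern_len <- min(n_samp, ceiling(8 * tau_decay_ms / 1000 * sampling_rate))
    kern <- psc_kernel((seq_len(kern_len) - 1) / sampling_rate,
                       tau_rise_ms, tau_decay_ms)
    sgn <- if (polarity == "inward") -1 else 1
    x <- numeric(n_samp)
    for (i in seq_len(n_ev)) {
      i0 <- round(times[i] * sampling_rate) + 1
      idx <- i0:min(n_samp, i0 + kern_len - 1)
      x[idx] <- x[idx] + sgn * amps[i] * kern[seq_along(idx)]
    }
    if (noise_sd_pA > 0) x <- x + stats::rnorm(n_samp, 0, noise_sd_pA)
    sweep <- new_sweep(x, sampling_rate, channel_kind = "voltage_clamp_current",
                       metadata = list(polarity = polarity,
                                       rate_Hz = rate_Hz,
                                       noise_sd_pA = noise_sd_pA),
                       quiet = TRUE)
    list(sweep = sweep,
         truth = tibble::tibble(time_s = times, amplitude_pA = amps))
  })
}

#' Simulate two independent group samples
#'
#' Calibration inputs for the statistics layer: two reproducible samples from
#' a normal or lognormal distribution with a configurable additive effect on
#' the second group's mean.
#'
#' @param n1,n2 Group sizes (>= 2).
#' @param dist `"normal"` or `"lognormal"`.
#' @param mean,sd Location and spread of group 1. For the lognormal these are
#'   the distribution's arithmetic mean and an approximate spread via a
#'   log-scale sd of `sd/mean`.
#' @param effect Additive shift of group 2's mean.
#' @param seed Optional RNG seed.
#' @return List with `sample1` and `sample2`.
#' @export
simulate_two_group_samples <- function(n1, n2, dist = c("normal", "lognormal"),
                                       mean = 0, sd = 1, effect = 0,
                                       seed = NULL) {
  dist <- match.arg(dist)
  if (n1 < 2 || n2 < 2) stop("need n1, n2 >= 2", call. = FALSE)
  with_seed(seed, {
    draw <- function(n, mu) {
      if (dist == "normal") return(stats::rnorm(n, mu, sd))
      sdlog <- sd / mu
      stats::rlnorm(n, log(mu) - sdlog^2 / 2, sdlog)
    }
    list(sample1 = draw(n1, mean), sample2 = draw(n2, mean + effect))
  })
}
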