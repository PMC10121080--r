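# Current-clamp measures: spike detection, F-I curve, rheobase, maximum
# firing rate, depolarization block, action-potential features, adaptation
# ratio, input resistance and resting potential.

#' Detect action potentials in a current-clamp sweep
#'
#' A spike is an upward crossing of `min_peak_mV` whose upstroke dV/dt
#' exceeds `min_dvdt_Vps`, with an absolute refractory separation; the spike
#' time is the voltage peak within 2 ms of the crossing.
#'
#' @param sweep A current-clamp `ephys_sweep`.
#' @param window_s Optional `c(from, to)` window (s); spikes outside are
#'   dropped.
#' @param min_peak_mV Peak criterion (default 0 mV).
#' @param min_dvdt_Vps Upstroke criterion (default 20 V/s).
#' @param refractory_ms Minimum peak separation (default 1 ms).
#' @return Tibble with `time_s` (peak times) and `peak_mV`.
#' @export
detect_spikes <- function(sweep, window_s = NULL, min_peak_mV = 0,
                          min_dvdt_Vps = 20, refractory_ms = 1) {
  stopifnot(inherits(sweep, "ephys_sweep"))
  v <- sweep$samples
  fs <- sweep$sampling_rate
  n <- length(v)
  up <- which(v[-1] >= min_peak_mV & v[-n] < min_peak_mV)
  out_t <- numeric(0); out_v <- numeric(0)
  last <- -Inf
  look <- max(1L, round(0.002 * fs))
  for (i in up) {
    dvdt <- (v[i + 1] - v[i]) * fs / 1000   # mV/sample -> V/s
    if (dvdt < min_dvdt_Vps) next
    j1 <- min(n, i + look)
    pk <- i + which.max(v[i:j1]) - 1L
    t_pk <- sweep$t0 + (pk - 1) / fs
    if ((t_pk - last) * 1000 < refractory_ms) next
    last <- t_pk
    out_t <- c(out_t, t_pk); out_v <- c(out_v, v[pk])
  }
  res <- tibble::tibble(time_s = out_t, peak_mV = out_v)
  if (!is.null(window_s))
    res <- res[res$time_s >= window_s[1] & res$time_s <= window_s[2], ]
  res
}

#' Frequency-current analysis of a current-step experiment
#'
#' Detects spikes in every step sweep and assembles the F-I table (rate =
#' spike count / step duration), the rheobase (smallest step current
#' eliciting at least one spike), the maximum firing rate and the current at
#' which it is attained (ties broken toward the lowest current), the ISI
#' adaptation ratio at the maximum-rate step, plus input resistance and
#' resting potential when the protocol includes hyperpolarizing steps.
#'
#' @param experiment An `ephys_experiment` whose sweeps carry
#'   `step_current_pA` metadata and a step protocol (as produced by
#'   [simulate_fi_sweeps()]).
#' @param ... Passed to [detect_spikes()].
#' @return An object of class `fi_result`: list with `steps` (per-step
#'   tibble), `rheobase_pA` (`NA` if no suprathreshold step, with a
#'   message), `max_rate_Hz`, `current_at_max_rate_pA`,
#'   `isi_ratio_at_max_rate`, `input_resistance_MOhm`,
#'   `resting_potential_mV`.
#' @export
fi_curve <- function(experiment, ...) {
  stopifnot(inherits(experiment, "ephys_experiment"))
  sweeps <- Filter(function(s) !is.null(s$metadata$step_current_pA),
                   experiment$sweeps)
  if (!length(sweeps)) stop("no step sweeps in experiment", call. = FALSE)
  proto <- sweeps[[1]]$protocol
  if (is.null(proto)) stop("step sweeps lack a protocol", call. = FALSE)
  win <- c(proto$step_onset_s, proto$step_onset_s + proto$duration_s)
  per <- lapply(sweeps, function(s) {
    sp <- detect_spikes(s, window_s = win, ...)
    tibble::tibble(step_current_pA = s$metadata$step_current_pA,
                   n_spikes = nrow(sp),
                   rate_Hz = nrow(sp) / proto$duration_s,
                   spike_times_s = list(sp$time_s),
                   last_spike_in_step_s = if (nrow(sp))
                     max(sp$time_s) - proto$step_onset_s else NA_real_)
  })
  steps <- dplyr::arrange(dplyr::bind_rows(per), .data$step_current_pA)
  supra <- steps$step_current_pA[steps$n_spikes > 0]
  rheo <- if (length(supra)) min(supra) else NA_real_
  if (is.na(rheo)) message("no suprathreshold step: rheobase missing")
  i_max <- which.max(steps$rate_Hz)   # first max = lowest current on ties
  max_rate <- steps$rate_Hz[i_max]
  isi_ratio <- if (max_rate > 0)
    isi_adaptation_ratio(steps$spike_times_s[[i_max]]) else NA_real_
  rin <- tryCatch(input_resistance(experiment), error = function(e) NA_real_)
  rmp <- tryCatch(resting_potential(sweeps[[1]]), error = function(e) NA_real_)
  structure(list(steps = steps,
                 step_duration_s = proto$duration_s,
                 rheobase_pA = rheo,
                 max_rate_Hz = max_rate,
                 current_at_max_rate_pA = steps$step_current_pA[i_max],
                 isi_ratio_at_max_rate = isi_ratio,
                 input_resistance_MOhm = rin,
                 resting_potential_mV = rmp),
            class = "fi_result")
}

#' @export
print.fi_result <- function(x, ...) {
  cat(sprintf(paste0("<fi_result> rheobase %g pA | max rate %g Hz @ %g pA | ",
                     "Rin %.1f MOhm | RMP %.1f mV\n"),
              x$rheobase_pA, x$max_rate_Hz, x$current_at_max_rate_pA,
              x$input_resistance_MOhm, x$resting_potential_mV))
  invisible(x)
}

#' Classify depolarization block from per-step last-spike times
#'
#' A step is blocked when it elicited at least one spike but the last spike
#' precedes `criterion_s` within the step; the cell is flagged as entering
#' depolarization block when any step at or above rheobase is blocked, and
#' the reported block current is the lowest blocked step current.
#'
#' @param fi An [fi_curve()] result.
#' @param criterion_s Last-spike criterion within the step (default 0.9 s
#'   for a 1 s step).
#' @return List with `entered` (flag), `block_current_pA` (`NA` when not
#'   blocked) and the per-step classification.
#' @export
depolarization_block <- function(fi, criterion_s = 0.9) {
  stopifnot(inherits(fi, "fi_result"))
  st <- fi$steps
  blocked <- st$n_spikes > 0 & !is.na(st$last_spike_in_step_s) &
    st$last_spike_in_step_s < criterion_s
  if (!is.na(fi$rheobase_pA))
    blocked <- blocked & st$step_current_pA >= fi$rheobase_pA
  entered <- any(blocked)
  list(entered = entered,
       block_current_pA = if (entered)
         min(st$step_current_pA[blocked]) else NA_real_,
       steps = tibble::tibble(step_current_pA = st$step_current_pA,
                              blocked = blocked))
}

#' Cohort contingency table for depolarization block
#'
#' @param group Group label per cell.
#' @param entered Logical block flag per cell.
#' @return A 2-column matrix of counts (columns `yes`, `no`), one row per
#'   group level in order of first appearance.
#' @export
block_contingency <- function(group, entered) {
  stopifnot(length(group) == length(entered))
  lev <- unique(as.character(group))
  m <- t(vapply(lev, function(g)
    c(yes = sum(entered[group == g]), no = sum(!entered[group == g])),
    c(yes = 0, no = 0)))
  rownames(m) <- lev
  m
}

#' Action-potential prominence and half-width
#'
#' Prominence is the topographic prominence of the voltage peak: peak value
#' minus the higher of the two flanking minima (bounded by the neighbouring
#' spikes or the analysis window). Half-width is the peak width at
#' half-maximal prominence, with linear interpolation between samples.
#' A flat-topped (clipped) peak is flagged unreliable.
#'
#' @param sweep Current-clamp sweep.
#' @param spike_time_s Peak time of the spike to measure (s).
#' @param window_s Analysis window `c(from, to)` (s); defaults to the whole
#'   sweep.
#' @param neighbor_times_s Peak times of neighbouring spikes used to bound
#'   the flanking minima search.
#' @return List with `prominence_mV`, `half_width_ms`, `unreliable`.
#' @export
ap_features <- function(sweep, spike_time_s, window_s = NULL,
                        neighbor_times_s = numeric(0)) {
  stopifnot(inherits(sweep, "ephys_sweep"))
  fs <- sweep$sampling_rate
  v <- sweep$samples
  n <- length(v)
  if (is.null(window_s)) window_s <- c(sweep$t0, sweep$t0 + (n - 1) / fs)
  idx <- function(t) min(n, max(1L, round((t - sweep$t0) * fs) + 1L))
  i0 <- idx(window_s[1]); i1 <- idx(window_s[2])
  pk0 <- idx(spike_time_s)
  rng <- max(i0, pk0 - round(0.002 * fs)):min(i1, pk0 + round(0.002 * fs))
  pk <- rng[which.max(v[rng])]
  nb <- sort(neighbor_times_s[abs(neighbor_times_s - spike_time_s) > 1e-9])
  lb <- nb[nb < spike_time_s]
  rb <- nb[nb > spike_time_s]
  lb <- if (length(lb)) idx(max(lb)) else i0
  rb <- if (length(rb)) idx(min(rb)) else i1
  left_min <- min(v[lb:pk]); right_min <- min(v[pk:rb])
  prom <- v[pk] - max(left_min, right_min)
  clipped <- {
    at_max <- abs(v[max(i0, pk - 50):min(i1, pk + 50)] - v[pk]) < 1e-9
    r <- rle(at_max)
    any(r$lengths[r$values] >= 6)
  }
  lev <- v[pk] - prom / 2
  kl <- pk
  while (kl > lb && v[kl - 1] > lev) kl <- kl - 1
  tl <- if (kl > lb) kl - 1 + (lev - v[kl - 1]) / (v[kl] - v[kl - 1])
  else as.numeric(kl)
  kr <- pk
  while (kr < rb && v[kr + 1] > lev) kr <- kr + 1
  tr <- if (kr < rb) kr + (v[kr] - lev) / (v[kr] - v[kr + 1])
  else as.numeric(kr)
  list(prominence_mV = prom,
       half_width_ms = (tr - tl) / fs * 1000,
       unreliable = clipped)
}

#' Spike-frequency adaptation ratio (first ISI / last ISI)
#'
#' @param spike_times_s Spike times of one train (s).
#' @return The ratio, or `NA` for trains with fewer than 3 spikes.
#' @export
isi_adaptation_ratio <- function(spike_times_s) {
  if (length(spike_times_s) < 3) return(NA_real_)
  isi <- diff(sort(spike_times_s))
  isi[1] / isi[length(isi)]
}

#' Input resistance from hyperpolarizing current steps
#'
#' Least-squares slope of the steady-state voltage deflection (mean over the
#' last `steady_ms` of the step minus the pre-step baseline mean) against
#' the injected current, over steps within `current_range_pA` (default the
#' -100 to -10 pA window).
#'
#' @param experiment Step experiment (see [fi_curve()]).
#' @param current_range_pA Steps used for the fit (inclusive range).
#' @param steady_ms Steady-state averaging window at the end of the step.
#' @return Input resistance in MOhm.
#' @export
input_resistance <- function(experiment, current_range_pA = c(-100, -10),
                             steady_ms = 200) {
  stopifnot(inherits(experiment, "ephys_experiment"))
  sweeps <- Filter(function(s) {
    I <- s$metadata$step_current_pA
    !is.null(I) && I >= current_range_pA[1] && I <= current_range_pA[2]
  }, experiment$sweeps)
  if (length(sweeps) < 3)
    stop("need at least 3 hyperpolarizing steps in ",
         current_range_pA[1], "..", current_range_pA[2], " pA", call. = FALSE)
  dv <- vapply(sweeps, function(s) {
    p <- s$protocol
    fs <- s$sampling_rate
    i_on <- round(p$step_onset_s * fs)
    i_off <- round((p$step_onset_s + p$duration_s) * fs)
    i_st <- i_off - round(steady_ms / 1000 * fs)
    mean(s$samples[i_st:i_off]) - mean(s$samples[1:i_on])
  }, 0)
  ii <- vapply(sweeps, function(s) s$metadata$step_current_pA, 0)
  unname(stats::coef(stats::lm(dv ~ ii))[2]) * 1000   # mV/pA = GOhm -> MOhm
}

#' Resting membrane potential from the pre-stimulus baseline
#'
#' @param sweep Current-clamp sweep.
#' @param window_s Baseline window `c(from, to)` (s); defaults to the
#'   pre-step segment of the sweep's protocol, which must be at least
#'   100 ms.
#' @return Mean baseline voltage (mV).
#' @export
resting_potential <- function(sweep, window_s = NULL) {
  stopifnot(inherits(sweep, "ephys_sweep"))
  if (is.null(window_s)) {
    onset <- if (!is.null(sweep$protocol)) sweep$protocol$step_onset_s
    else 0.1
    window_s <- c(sweep$t0, sweep$t0 + onset)
  }
  dur <- sweep_duration(sweep)
  if (window_s[2] > sweep$t0 + dur + 1e-9 || window_s[1] < sweep$t0 - 1e-9)
    stop("baseline window lies outside the sweep", call. = FALSE)
  if (diff(window_s) < 0.1 - 1e-9)
    stop("baseline window must be at least 100 ms", call. = FALSE)
  fs <- sweep$sampling_rate
  i0 <- round((window_s[1] - sweep$t0) * fs) + 1
  i1 <- round((window_s[2] - sweep$t0) * fs)
  mean(sweep$samples[i0:i1])
}
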