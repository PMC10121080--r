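# Evoked field-potential quantification: fEPSP slope, population-spike
# amplitude (tangent method), input-output curves, paired-pulse ratios and
# LTP time-course normalization.

field_response_region <- function(sweep, stim_time_s, blank_ms, search_ms) {
  fs <- sweep$sampling_rate
  i_stim <- round((stim_time_s - sweep$t0) * fs) + 1
  i0 <- i_stim + ceiling(blank_ms / 1000 * fs)
  i1 <- min(length(sweep$samples), i_stim + round(search_ms / 1000 * fs))
  if (i0 >= i1) stop("response window is empty", call. = FALSE)
  ib <- max(1L, i_stim - round(0.02 * fs)):max(1L, i_stim - 1L)
  list(i0 = i0, i1 = i1, baseline = mean(sweep$samples[ib]),
       noise_sd = stats::sd(sweep$samples[ib]), fs = fs)
}

#' Measure the fEPSP rising slope
#'
#' The maximum slope of the rising phase: the steepest regression slope over
#' a sliding window of `window_ms` between the response onset and the first
#' local peak of the deflection (which is the fEPSP peak when no population
#' spike is present, and the spike-onset flank when one is). The first
#' `blank_ms` after the stimulus are blanked as artifact.
#'
#' @param sweep A field-potential `ephys_sweep`.
#' @param stim_time_s Stimulus time (s); defaults to the sweep metadata.
#' @param blank_ms Artifact blanking window after the stimulus (ms).
#' @param window_ms Regression window (default 0.5 ms).
#' @param search_ms Response search window after the stimulus (ms).
#' @param noise_mult Response criterion: the peak deflection must exceed
#'   `noise_mult` times the pre-stimulus noise sd, else the slope is 0 and
#'   flagged.
#' @return List with `slope_Vps` (positive magnitude, V/s) and `flagged`.
#' @export
measure_fepsp_slope <- function(sweep, stim_time_s = NULL, blank_ms = 1,
                                window_ms = 0.5, search_ms = 15,
                                noise_mult = 5) {
  stopifnot(inherits(sweep, "ephys_sweep"))
  stim_time_s <- stim_time_s %||% sweep$metadata$stim_time_s
  if (is.null(stim_time_s)) stop("no stimulus time available", call. = FALSE)
  r <- field_response_region(sweep, stim_time_s, blank_ms, search_ms)
  d <- sweep$samples[r$i0:r$i1] - r$baseline
  crit <- max(noise_mult * r$noise_sd, 1e-12)
  if (max(abs(d)) < crit)
    return(list(slope_Vps = 0, flagged = TRUE))
  s <- sign(d[which.max(abs(d))])
  d <- s * d
  # first local maximum of the deflection above the criterion
  pk <- length(d)
  for (i in 2:(length(d) - 1)) {
    if (d[i] >= crit && d[i] >= d[i - 1] && d[i] > d[i + 1]) { pk <- i; break }
  }
  k <- max(2L, round(window_ms / 1000 * r$fs) + 1L)
  if (pk < k) pk <- min(length(d), k)
  tt <- (seq_len(k) - 1) / r$fs
  tc <- tt - mean(tt)
  den <- sum(tc^2)
  slopes <- vapply(seq_len(pk - k + 1), function(j)
    sum(tc * d[j:(j + k - 1)]) / den, 0)
  list(slope_Vps = max(slopes) / 1000, flagged = FALSE)   # mV/s -> V/s
}

#' Measure the population-spike amplitude (tangent method)
#'
#' The amplitude is the vertical distance from the negative spike trough to
#' the straight line joining the two flanking positive peaks. Returns 0 when
#' no trough exceeds `noise_mult` times the pre-stimulus noise sd below the
#' tangent line. With several qualifying troughs the largest is used and the
#' result is flagged.
#'
#' @inheritParams measure_fepsp_slope
#' @return List with `amplitude_mV` (>= 0) and `flagged`.
#' @export
measure_pop_spike <- function(sweep, stim_time_s = NULL, blank_ms = 1,
                              search_ms = 15, noise_mult = 5) {
  stopifnot(inherits(sweep, "ephys_sweep"))
  stim_time_s <- stim_time_s %||% sweep$metadata$stim_time_s
  if (is.null(stim_time_s)) stop("no stimulus time available", call. = FALSE)
  r <- field_response_region(sweep, stim_time_s, blank_ms, search_ms)
  d <- sweep$samples[r$i0:r$i1] - r$baseline
  n <- length(d)
  is_max <- c(FALSE, d[2:(n - 1)] >= d[1:(n - 2)] & d[2:(n - 1)] > d[3:n],
              FALSE)
  is_min <- c(FALSE, d[2:(n - 1)] <= d[1:(n - 2)] & d[2:(n - 1)] < d[3:n],
              FALSE)
  imax <- which(is_max); imin <- which(is_min)
  crit <- max(noise_mult * r$noise_sd, 1e-12)
  amps <- vapply(imin, function(i) {
    il <- imax[imax < i]; ir <- imax[imax > i]
    if (!length(il) || !length(ir)) return(NA_real_)
    il <- max(il); ir <- min(ir)
    # both flanking peaks must stand above the noise floor, so dips in the
    # pre-response baseline do not masquerade as spikes
    if (d[il] < crit || d[ir] < crit) return(NA_real_)
    line <- d[il] + (d[ir] - d[il]) * (i - il) / (ir - il)
    line - d[i]
  }, 0)
  ok <- !is.na(amps) & amps > crit
  if (!any(ok)) return(list(amplitude_mV = 0, flagged = FALSE))
  list(amplitude_mV = max(amps[ok]), flagged = sum(ok) > 1)
}

#' Input-output curve from per-sweep measurements
#'
#' @param responses Tibble with columns `intensity_uA`, `fepsp_slope_Vps`,
#'   `pop_spike_mV` (one or more rows per intensity).
#' @return List with `curve` (per-intensity mean slope and spike amplitude,
#'   increasing intensity) and `spike_onset_intensity_uA`, the lowest
#'   intensity with a non-zero mean spike (`NA` when never reached).
#' @export
io_analysis <- function(responses) {
  stopifnot(all(c("intensity_uA", "fepsp_slope_Vps", "pop_spike_mV") %in%
                  names(responses)))
  curve <- responses |>
    dplyr::group_by(.data$intensity_uA) |>
    dplyr::summarise(fepsp_slope_Vps = mean(.data$fepsp_slope_Vps),
                     pop_spike_mV = mean(.data$pop_spike_mV),
                     .groups = "drop") |>
    dplyr::arrange(.data$intensity_uA)
  onset <- curve$intensity_uA[curve$pop_spike_mV > 0]
  list(curve = curve,
       spike_onset_intensity_uA = if (length(onset)) min(onset) else NA_real_)
}

#' Paired-pulse ratio
#'
#' Second response as a percentage of the first: fEPSP slopes for
#' paired-pulse facilitation (`"ppf_slope"`), population-spike amplitudes
#' for paired-pulse inhibition (`"ppi_spike"`, 0 % when the second spike is
#' absent). Vectorized over response pairs.
#'
#' @param first,second Response measures of the two pulses.
#' @param mode `"ppf_slope"` or `"ppi_spike"`.
#' @return Percentages; `NA` (undefined) where the first response is 0.
#' @export
paired_pulse_ratio <- function(first, second,
                               mode = c("ppi_spike", "ppf_slope")) {
  mode <- match.arg(mode)
  out <- 100 * second / first
  undef <- first == 0
  if (any(undef)) {
    warning("first response is 0: ratio undefined", call. = FALSE)
    out[undef] <- NA_real_
  }
  out
}

#' Normalize an LTP time course to its pre-induction baseline
#'
#' Each response is expressed as a percentage of the mean over the
#' `baseline_min` minutes preceding induction (time 0); window means are
#' reported for the early (0-10 min) and late (50-60 min) phases.
#'
#' @param times_min Times relative to induction (min; negative = baseline).
#' @param values Response measure (e.g. fEPSP slope or spike amplitude).
#' @param baseline_min Required baseline length before induction (min).
#' @param early_win,late_win Reporting windows (min).
#' @return List with `timecourse` (tibble `time_min`, `percent`),
#'   `baseline_mean` (raw units), `early_percent`, `late_percent`.
#' @export
ltp_timecourse <- function(times_min, values, baseline_min = 10,
                           early_win = c(0, 10), late_win = c(50, 60)) {
  stopifnot(length(times_min) == length(values))
  base <- times_min < 0 & times_min >= -baseline_min
  if (!any(base) || -min(times_min) < 0.9 * baseline_min)
    stop("missing baseline: need ", baseline_min,
         " min of pre-induction data", call. = FALSE)
  bmean <- mean(values[base])
  pct <- 100 * values / bmean
  win_mean <- function(w) {
    sel <- times_min >= w[1] & times_min <= w[2]
    if (any(sel)) mean(pct[sel]) else NA_real_
  }
  list(timecourse = tibble::tibble(time_min = times_min, percent = pct),
       baseline_mean = bmean,
       early_percent = win_mean(early_win),
       late_percent = win_mean(late_win))
}
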