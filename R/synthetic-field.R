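# Synthetic evoked field-potential experiments with known ground truth.
#
# The generator emulates the in vivo study design: per animal, an
# input-output series (fEPSP slope saturating with stimulation intensity,
# population spike coupled to slope through a Boltzmann sigmoid) and a
# paired-pulse inhibition series (second/first population-spike amplitude as
# a ground-truth Boltzmann of the interpulse interval, with animal-level
# variation entering through the v50 parameter only).

#' Ground-truth parameters for a synthetic field-potential study
#'
#' The default paired-pulse inhibition truth uses group v50 values of 41.3 ms
#' (WT) and 45.8 ms (KO) with Top = 120 % and slope k = 5 ms, a 4 ms
#' between-animal v50 standard deviation, and 5 % multiplicative measurement
#' noise. See the methods vignette for the reasoning behind these defaults.
#'
#' @param io_max_slope_Vps,io_half_uA,io_hill Saturating (Hill) input-output
#'   curve of fEPSP slope vs intensity: `S(i) = max * i^h / (half^h + i^h)`.
#' @param es_top_mV,es_v50_Vps,es_k_Vps EPSP-spike coupling Boltzmann:
#'   population spike (mV) as a function of fEPSP slope (V/s).
#' @param ppi_top,ppi_v50_ms,ppi_k_ms Paired-pulse inhibition Boltzmann
#'   (percent of first spike vs interpulse interval, ms); `ppi_v50_ms` is a
#'   named vector with one entry per group.
#' @param between_sd_v50_ms Between-animal sd of the PPI v50 (ms).
#' @param noise_cv Multiplicative measurement noise (coefficient of
#'   variation) applied to slopes, spike amplitudes and PPI percentages.
#' @param spike_floor_mV Detection floor: population spikes below this value
#'   are recorded as 0 (absent).
#' @return A `field_truth` list.
#' @export
field_truth <- function(io_max_slope_Vps = 3.5, io_half_uA = 180,
                        io_hill = 2,
                        es_top_mV = 6, es_v50_Vps = 1.8, es_k_Vps = 0.35,
                        ppi_top = 120,
                        ppi_v50_ms = c(WT = 41.3, KO = 45.8),
                        ppi_k_ms = 5,
                        between_sd_v50_ms = 4, noise_cv = 0.05,
                        spike_floor_mV = 0.2) {
  structure(list(io_max_slope_Vps = io_max_slope_Vps, io_half_uA = io_half_uA,
                 io_hill = io_hill, es_top_mV = es_top_mV,
                 es_v50_Vps = es_v50_Vps, es_k_Vps = es_k_Vps,
                 ppi_top = ppi_top, ppi_v50_ms = ppi_v50_ms,
                 ppi_k_ms = ppi_k_ms, between_sd_v50_ms = between_sd_v50_ms,
                 noise_cv = noise_cv, spike_floor_mV = spike_floor_mV),
            class = "field_truth")
}

#' Standard input-output intensity grid (uA)
#'
#' The 20-level series from 30 to 800 uA used for input-output measurements.
#' @export
io_intensity_grid <- function() {
  c(30, 50, 100, 150, 175, 200, 225, 250, 275, 300,
    350, 400, 450, 500, 550, 600, 650, 700, 750, 800)
}

#' Standard paired-pulse interval grid (ms)
#'
#' The 11 interpulse intervals from 10 to 100 ms over which paired-pulse
#' inhibition is quantified.
#' @export
ipi_grid <- function() c(10, 15, 20, 30, 35, 40, 45, 50, 60, 80, 100)

#' Simulate a two-group evoked field-potential study
#'
#' Per animal: an input-output table (fEPSP slope and population-spike
#' amplitude vs stimulation intensity) and a paired-pulse inhibition table
#' (second spike as percent of first vs interpulse interval). Animal-level
#' variation enters through the PPI v50 only; all measures carry
#' multiplicative Gaussian noise of coefficient `truth$noise_cv`.
#'
#' @param n_per_group Named integer vector of animals per group, e.g.
#'   `c(WT = 17, KO = 16)`. Names must match `names(truth$ppi_v50_ms)`.
#' @param truth A [field_truth()] object.
#' @param intensities_uA Input-output intensity grid (non-empty).
#' @param ipis_ms Paired-pulse interval grid (non-empty).
#' @param seed Optional RNG seed.
#' @return List with tibbles `io` (subject, group, intensity_uA,
#'   fepsp_slope_Vps, pop_spike_mV), `ppi` (subject, group, ipi_ms,
#'   ppi_percent), and `truth` (the input truth plus the per-animal v50 draws
#'   and the noiseless spike-onset intensity).
#' @export
simulate_field_experiment <- function(n_per_group = c(WT = 17, KO = 16),
                                      truth = field_truth(),
                                      intensities_uA = io_intensity_grid(),
                                      ipis_ms = ipi_grid(),
                                      seed = NULL) {
  if (length(intensities_uA) == 0 || length(ipis_ms) == 0)
    stop("validation error: empty intensity or IPI grid", call. = FALSE)
  groups <- names(n_per_group)
  if (is.null(groups) || !all(groups %in% names(truth$ppi_v50_ms)))
    stop("validation error: every group label needs a ppi_v50_ms truth entry",
         call. = FALSE)
  with_seed(seed, {
    io <- list(); ppi <- list(); subjects <- list()
    for (g in groups) {
      for (i in seq_len(n_per_group[[g]])) {
        id <- sprintf("%s_%02d", g, i)
        v50_i <- truth$ppi_v50_ms[[g]] +
          stats::rnorm(1, 0, truth$between_sd_v50_ms)
        noise <- function(n) 1 + truth$noise_cv * stats::rnorm(n)

        slope0 <- truth$io_max_slope_Vps * intensities_uA^truth$io_hill /
          (truth$io_half_uA^truth$io_hill + intensities_uA^truth$io_hill)
        spike0 <- boltzmann(slope0, truth$es_top_mV, truth$es_v50_Vps,
                            truth$es_k_Vps)
        spike0[spike0 < truth$spike_floor_mV] <- 0
        slope <- slope0 * noise(length(slope0))
        spike <- spike0 * noise(length(spike0))
        io[[id]] <- tibble::tibble(subject = id, group = g,
                                   intensity_uA = intensities_uA,
                                   fepsp_slope_Vps = slope,
                                   pop_spike_mV = spike)

        ppi0 <- boltzmann(ipis_ms, truth$ppi_top, v50_i, truth$ppi_k_ms)
        ppi[[id]] <- tibble::tibble(subject = id, group = g,
                                    ipi_ms = ipis_ms,
                                    ppi_percent = ppi0 * noise(length(ppi0)))

        onset <- intensities_uA[spike0 > 0]
        subjects[[id]] <- tibble::tibble(
          subject = id, group = g, v50_ms = v50_i,
          spike_onset_uA = if (length(onset)) min(onset) else NA_real_)
      }
    }
    list(io = dplyr::bind_rows(io), ppi = dplyr::bind_rows(ppi),
         truth = c(unclass(truth),
                   list(subjects = dplyr::bind_rows(subjects))))
  })
}

#' Synthesize one evoked field-potential sweep
#'
#' Composite waveform for exercising the measurement operators end to end: a
#' brief biphasic stimulus artifact, a positive alpha-function fEPSP
#' `A (t/tau) exp(1 - t/tau)` whose analytic maximum rising slope is
#' `A e / tau`, and an optional negative Gaussian population-spike trough
#' superimposed on the rising phase, plus Gaussian noise.
#'
#' @param fepsp_amp_mV Alpha-function peak amplitude (mV).
#' @param fepsp_tau_ms Alpha-function time-to-peak (ms).
#' @param pop_spike_mV Depth of the population-spike trough (mV); 0 for none.
#' @param spike_latency_ms Trough latency after fEPSP onset (ms).
#' @param spike_sigma_ms Gaussian trough width parameter (ms).
#' @param stim_time_s Stimulus time within the sweep (s).
#' @param response_delay_ms Synaptic delay from stimulus to fEPSP onset (ms).
#' @param duration_s Sweep length (s).
#' @param artifact_mV Stimulus-artifact amplitude (mV).
#' @param noise_sd_mV Additive noise sd (mV).
#' @param sampling_rate Hz.
#' @param seed Optional RNG seed.
#' @return An `ephys_sweep` of kind `"field_potential"` with the stimulus
#'   time in its metadata.
#' @export
synth_evoked_sweep <- function(fepsp_amp_mV, fepsp_tau_ms = 2,
                               pop_spike_mV = 0, spike_latency_ms = 3.5,
                               spike_sigma_ms = 0.7,
                               stim_time_s = 0.01, response_delay_ms = 1.5,
                               duration_s = 0.08, artifact_mV = 8,
                               noise_sd_mV = 0, sampling_rate = 10000,
                               seed = NULL) {
  with_seed(seed, {
    n <- round(duration_s * sampling_rate)
    t <- (seq_len(n) - 1) / sampling_rate
    x <- numeric(n)
    # biphasic artifact, 0.6 ms
    x <- x + artifact_mV * (exp(-((t - stim_time_s) * 1000 / 0.1)^2) -
                              exp(-((t - stim_time_s - 3e-4) * 1000 / 0.1)^2)) *
      (t >= stim_time_s & t < stim_time_s + 6e-4)
    on <- stim_time_s + response_delay_ms / 1000
    tr <- (t - on) * 1000   # ms after onset
    alpha <- ifelse(tr > 0, fepsp_amp_mV * (tr / fepsp_tau_ms) *
                      exp(1 - tr / fepsp_tau_ms), 0)
    x <- x + alpha
    if (pop_spike_mV > 0)
      x <- x - pop_spike_mV *
        exp(-0.5 * ((tr - spike_latency_ms) / spike_sigma_ms)^2)
    if (noise_sd_mV > 0) x <- x + stats::rnorm(n, 0, noise_sd_mV)
    new_sweep(x, sampling_rate, channel_kind = "field_potential",
              metadata = list(stim_time_s = stim_time_s), quiet = TRUE)
  })
}

#' Simulate an LTP time course with decaying potentiation
#'
#' Baseline responses at 100 %, then potentiation decaying exponentially from
#' an early toward a late plateau level.
#'
#' @param baseline_min Minutes of pre-induction baseline.
#' @param post_min Minutes of post-induction follow-up.
#' @param early_pct,late_pct Potentiation level (percent of baseline) just
#'   after induction and at the late plateau.
#' @param tau_min Decay time constant of the potentiation (min).
#' @param interval_min Sampling interval of the time course (min).
#' @param noise_cv Multiplicative noise coefficient.
#' @param seed Optional RNG seed.
#' @return Tibble with `time_min` (induction at 0) and response measures
#'   `slope` and `spike` in raw (unnormalized) units.
#' @export
simulate_ltp_timecourse <- function(baseline_min = 10, post_min = 60,
                                    early_pct = 150, late_pct = 120,
                                    tau_min = 25, interval_min = 0.5,
                                    noise_cv = 0.03, seed = NULL) {
  with_seed(seed, {
    t <- seq(-baseline_min + interval_min, post_min, by = interval_min)
    pct <- ifelse(t <= 0, 100,
                  late_pct + (early_pct - late_pct) * exp(-t / tau_min))
    noise <- function(n) 1 + noise_cv * stats::rnorm(n)
    base_slope <- 2.5   # V/s
    base_spike <- 1.5   # mV
    tibble::tibble(time_min = t,
                   slope = base_slope * pct / 100 * noise(length(t)),
                   spike = base_spike * pct / 100 * noise(length(t)))
  })
}

#' Simulate paired evoked EPSC/IPSC repeats for one cell
#'
#' Emulates the evoked excitation/inhibition protocol: repeated EPSC peaks at
#' -60 mV holding (inward, negative) and IPSC peaks at +10 mV (outward,
#' positive) at the same stimulation intensity, with a known ground-truth
#' ratio.
#'
#' @param true_ratio Ground-truth |EPSC| / |IPSC| ratio.
#' @param ipsc_mean_pA Mean IPSC peak amplitude (pA, positive).
#' @param n_repeats Repeats per polarity (1-10).
#' @param noise_cv Multiplicative amplitude noise coefficient.
#' @param cell_id Identifier.
#' @param intensity_uA Stimulation intensity recorded in the set.
#' @param seed Optional RNG seed.
#' @return An `evoked_psc_set` list with `epsc_peaks_pA` (negative),
#'   `ipsc_peaks_pA` (positive), and the ground-truth ratio.
#' @export
simulate_evoked_psc_set <- function(true_ratio = 0.38, ipsc_mean_pA = 400,
                                    n_repeats = 5, noise_cv = 0.05,
                                    cell_id = "cell_1", intensity_uA = 40,
                                    seed = NULL) {
  stopifnot(n_repeats >= 1, n_repeats <= 10)
  with_seed(seed, {
    noise <- function(n) 1 + noise_cv * stats::rnorm(n)
    structure(list(cell = cell_id,
                   epsc_peaks_pA = -true_ratio * ipsc_mean_pA *
                     noise(n_repeats),
                   ipsc_peaks_pA = ipsc_mean_pA * noise(n_repeats),
                   intensity_uA = intensity_uA,
                   truth_ratio = true_ratio),
              class = "evoked_psc_set")
  })
}
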