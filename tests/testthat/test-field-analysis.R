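test_that("fEPSP slope matches the windowed analytic optimum of an alpha fEPSP", {
  sw <- synth_evoked_sweep(5, 2, pop_spike_mV = 0, noise_sd_mV = 0)
  res <- measure_fepsp_slope(sw)
  oracle <- alpha_max_windowed_slope(5, 2, 0.5)
  expect_false(res$flagged)
  expect_equal(res$slope_Vps, oracle, tolerance = 0.05)
})

test_that("slope estimates approach the instantaneous A*e/tau as the window shrinks", {
  sw <- synth_evoked_sweep(5, 2, pop_spike_mV = 0, noise_sd_mV = 0,
                           sampling_rate = 1e5)
  res <- measure_fepsp_slope(sw, window_ms = 0.1)
  expect_equal(res$slope_Vps, 5 * exp(1) / 2, tolerance = 0.05)
})

test_that("a flat sweep yields slope 0 with a flag", {
  sw <- new_sweep(rnorm(800, 0, 0.01), 10000,
                  channel_kind = "field_potential",
                  metadata = list(stim_time_s = 0.01), quiet = TRUE)
  res <- measure_fepsp_slope(sw)
  expect_equal(res$slope_Vps, 0)
  expect_true(res$flagged)
})

test_that("slope and spike operators are linear in scaling and DC-invariant", {
  sw <- synth_evoked_sweep(5, 2, pop_spike_mV = 3, noise_sd_mV = 0.02,
                           seed = 4)
  s1 <- measure_fepsp_slope(sw)$slope_Vps
  p1 <- measure_pop_spike(sw)$amplitude_mV
  dbl <- sw; dbl$samples <- 2 * sw$samples
  off <- sw; off$samples <- sw$samples + 4.2
  expect_equal(measure_fepsp_slope(dbl)$slope_Vps, 2 * s1, tolerance = 1e-6)
  expect_equal(measure_pop_spike(dbl)$amplitude_mV, 2 * p1, tolerance = 1e-6)
  expect_equal(measure_fepsp_slope(off)$slope_Vps, s1, tolerance = 1e-6)
  expect_equal(measure_pop_spike(off)$amplitude_mV, p1, tolerance = 1e-6)
})

test_that("the tangent method measures trough depth below the peak-to-peak line", {
  # flanking peaks of 2 and 4 mV equidistant from a -3 mV trough: the line
  # midpoint is 3 mV, so the tangent amplitude is 6 mV
  tt <- seq(0, 0.03, by = 1e-4)
  tri <- function(t, c, w, h) pmax(0, h * (1 - abs(t - c) / w))
  w <- tri(tt, 0.010, 0.002, 2) + tri(tt, 0.018, 0.002, 4) -
    tri(tt, 0.014, 0.002, 3)
  sw <- new_sweep(c(rep(0, 50), w), 1e4, channel_kind = "field_potential",
                  metadata = list(stim_time_s = 0.004), quiet = TRUE)
  res <- measure_pop_spike(sw, search_ms = 28)
  expect_equal(res$amplitude_mV, 6)
})

test_that("sweeps without a spike component measure 0 mV", {
  sw <- synth_evoked_sweep(5, 2, pop_spike_mV = 0, noise_sd_mV = 0.02,
                           seed = 9)
  expect_equal(measure_pop_spike(sw)$amplitude_mV, 0)
})

test_that("input-output analysis finds the spike onset intensity", {
  sim <- simulate_field_experiment(c(WT = 1, KO = 1),
                                   truth = field_truth(noise_cv = 0,
                                                       between_sd_v50_ms = 0),
                                   seed = 3)
  d <- sim$io[sim$io$subject == "WT_01", ]
  io <- io_analysis(d)
  expect_equal(nrow(io$curve), 20)
  expect_equal(io$spike_onset_intensity_uA,
               sim$truth$subjects$spike_onset_uA[1])
  # all-subthreshold: onset missing
  d0 <- d; d0$pop_spike_mV <- 0
  expect_true(is.na(io_analysis(d0)$spike_onset_intensity_uA))
})

test_that("paired-pulse ratios follow their definition and edge cases", {
  expect_equal(paired_pulse_ratio(6, 6), 100)
  expect_equal(paired_pulse_ratio(6, 3), 50)
  expect_equal(paired_pulse_ratio(6, 0), 0)    # full inhibition
  expect_warning(r <- paired_pulse_ratio(0, 3), "undefined")
  expect_true(is.na(r))
})

test_that("LTP normalization fixes the baseline at 100 percent", {
  t <- seq(-9.5, 60, by = 0.5)
  v <- rep(2.5, length(t))
  ltp <- ltp_timecourse(t, v)
  expect_equal(mean(ltp$timecourse$percent[t < 0]), 100)
  expect_equal(ltp$early_percent, 100)
  expect_equal(ltp$late_percent, 100)
  # scaling post-induction responses by 1.5 gives a 150 % early window
  v2 <- ifelse(t >= 0, 1.5 * 2.5, 2.5)
  expect_equal(ltp_timecourse(t, v2)$early_percent, 150)
  expect_error(ltp_timecourse(t[t > -5], v[t > -5]), "baseline")
})

test_that("simulated decaying potentiation is recovered within the noise CI", {
  tc <- simulate_ltp_timecourse(early_pct = 150, late_pct = 120,
                                tau_min = 25, noise_cv = 0.03, seed = 12)
  ltp <- ltp_timecourse(tc$time_min, tc$slope)
  # analytic window means of the generating curve
  pot <- function(t) 120 + 30 * exp(-t / 25)
  early_true <- integrate(pot, 0, 10)$value / 10
  late_true <- integrate(pot, 50, 60)$value / 10
  # noise cv 3% over ~20 points: se ~ 0.7% of level
  expect_equal(ltp$early_percent, early_true, tolerance = 0.03)
  expect_equal(ltp$late_percent, late_true, tolerance = 0.03)
})

test_that("PPI from noiseless waveform pairs is ordered with spike depth", {
  # the tangent measure is monotone in the underlying spike depth; identical
  # waveforms give exactly 100 % and a shallower second spike less
  s1 <- synth_evoked_sweep(5, 2, pop_spike_mV = 3, noise_sd_mV = 0)
  s2 <- synth_evoked_sweep(5, 2, pop_spike_mV = 1.5, noise_sd_mV = 0)
  a1 <- measure_pop_spike(s1)$amplitude_mV
  a2 <- measure_pop_spike(s2)$amplitude_mV
  expect_equal(paired_pulse_ratio(a1, a1, "ppi_spike"), 100)
  r <- paired_pulse_ratio(a1, a2, "ppi_spike")
  expect_gt(r, 0)
  expect_lt(r, 100)
})
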