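make_trace <- function(times, amps = 20, noise = 0, dur = NULL, seed = 1,
                       fs = 10000) {
  dur <- dur %||% (max(times) + 0.2)
  simulate_psc_trace(0, dur, amp_mean_pA = amps, amp_sigma = 0,
                     noise_sd_pA = noise, sampling_rate = fs, seed = seed,
                     event_times_s = times)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the zero-phase elliptic filter preserves DC and the passband", {
  sw <- new_sweep(rep(5, 5000), 10000, quiet = TRUE)
  out <- lowpass_filter(sw)
  expect_lt(max(abs(out$samples - 5)), 1e-9)

  t <- seq(0, 0.5, by = 1e-4)
  s100 <- new_sweep(sin(2 * pi * 100 * t), 10000, quiet = TRUE)
  g100 <- max(abs(lowpass_filter(s100)$samples[1000:4000]))
  expect_gte(g100, 0.98)

  s3k <- new_sweep(sin(2 * pi * 3000 * t), 10000, quiet = TRUE)
  g3k <- max(abs(lowpass_filter(s3k)$samples[1000:4000]))
  expect_lte(g3k, 10^(-40 / 20))   # at least the one-pass stopband spec

  expect_error(lowpass_filter(sw, cutoff_Hz = 6000), "Nyquist")
})

test_that("zero-phase filtering shifts event peaks by less than 0.2 ms", {
  sim <- make_trace(seq(0.5, 4.5, by = 1), noise = 0)
  raw <- detect_events(sim$sweep, 3, "inward")
  flt <- detect_events(lowpass_filter(sim$sweep), 3, "inward")
  expect_equal(nrow(raw), nrow(flt))
  expect_lt(max(abs(raw$peak_s - flt$peak_s)) * 1000, 0.2)
})

test_that("a flat noiseless trace yields no events", {
  sw <- new_sweep(rep(0, 10000), 10000, quiet = TRUE)
  expect_equal(nrow(detect_events(sw, 3, "inward")), 0)
})

test_that("known events in noise are all matched within tolerance", {
  sim <- make_trace(seq(0.5, 9.5, by = 1), amps = 20, noise = 2, seed = 6)
  sw <- lowpass_filter(sim$sweep)
  ev <- detect_events(sw, 3, "inward")
  m <- match_events(sim$truth$time_s, ev, tol_ms = 2)
  expect_equal(nrow(m$matched), 10)
  expect_equal(m$n_spurious, 0)
  expect_equal(m$recall, 1)
})

test_that("the IPSC threshold of 10 pA rejects a 6 pA event", {
  sim <- simulate_psc_trace(0, 1, amp_mean_pA = 6, amp_sigma = 0,
                            noise_sd_pA = 0, polarity = "outward",
                            event_times_s = 0.4)
  expect_equal(nrow(detect_events(sim$sweep, 10, "outward")), 0)
  expect_equal(nrow(detect_events(sim$sweep, 3, "outward")), 1)
})

test_that("a polarity inconsistent with the sweep metadata warns", {
  sim <- make_trace(0.5, noise = 0)
  expect_warning(detect_events(sim$sweep, 3, "outward"), "polarity")
})

test_that("rise and decay times match the analytic kernel values", {
  or <- biexp_kinetics_oracle(1, 10)
  fs <- 1e5
  sim <- make_trace(0.1, amps = 20, noise = 0, dur = 0.5, fs = fs)
  ev <- detect_events(sim$sweep, 3, "inward")
  ev <- measure_kinetics(sim$sweep, ev, "inward")
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$rise_time_ms - or$rise_ms), 0.05)
  expect_lt(abs(ev$decay_time_ms - or$decay_ms), 0.05)
})

test_that("kinetics are invariant to amplitude scaling", {
  fs <- 1e5
  base <- make_trace(0.1, amps = 20, noise = 0, dur = 0.5, fs = fs)
  doubled <- base
  doubled$sweep$samples <- 2 * base$sweep$samples
  k1 <- measure_kinetics(base$sweep,
                         detect_events(base$sweep, 3, "inward"), "inward")
  k2 <- measure_kinetics(doubled$sweep,
                         detect_events(doubled$sweep, 3, "inward"), "inward")
  expect_equal(k2$amplitude_pA, 2 * k1$amplitude_pA, tolerance = 1e-9)
  expect_equal(k2$rise_time_ms, k1$rise_time_ms, tolerance = 1e-9)
  expect_equal(k2$decay_time_ms, k1$decay_time_ms, tolerance = 1e-9)
})

test_that("an overlapping next event leaves the first decay unresolved", {
  # slow decay so the 1/e crossing lies beyond the second onset
  sim2 <- simulate_psc_trace(0, 1, tau_rise_ms = 1, tau_decay_ms = 40,
                             amp_mean_pA = 20, amp_sigma = 0,
                             noise_sd_pA = 0,
                             event_times_s = c(0.5, 0.505))
  ev <- detect_events(sim2$sweep, 3, "inward")
  ev <- measure_kinetics(sim2$sweep, ev, "inward")
  expect_equal(nrow(ev), 2)
  expect_true(ev$decay_unresolved[1])
  expect_true(is.na(ev$decay_time_ms[1]))
})

test_that("cell summaries apply the 100-event inclusion rule", {
  ev99 <- tibble::tibble(onset_s = seq_len(99) / 10,
                         peak_s = seq_len(99) / 10 + 0.002,
                         amplitude_pA = 20, baseline_pA = 0,
                         rise_time_ms = 1, decay_time_ms = 10,
                         decay_unresolved = FALSE,
                         interevent_interval_ms = NA)
  expect_false(summarize_cell(ev99, 60)$qualifies)
  ev120 <- ev99[rep(1, 120), ]
  s <- summarize_cell(ev120, 60)
  expect_true(s$qualifies)
  expect_equal(s$frequency_Hz, 2)
  s0 <- summarize_cell(ev99[0, ], 60)
  expect_equal(s0$n_events, 0)
  expect_true(is.na(s0$mean_amplitude_pA))
})

test_that("detected amplitudes are unbiased on noiseless isolated events", {
  sim <- simulate_psc_trace(0, 12, amp_mean_pA = 20, amp_sigma = 0.3,
                            noise_sd_pA = 0, seed = 4,
                            event_times_s = seq(0.5, 11.5, by = 1))
  ev <- detect_events(sim$sweep, 3, "inward")
  expect_equal(nrow(ev), 12)
  expect_lt(mean(abs(ev$amplitude_pA - sim$truth$amplitude_pA)), 0.1)
})
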