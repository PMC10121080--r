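lif_experiment <- function(pars = neuron_params(),
                           proto = build_step_protocol(-100, 490, 10), ...) {
  simulate_fi_sweeps(pars, proto, ...)
}

test_that("spike detection recovers simulator ground truth", {
  sim <- lif_experiment(proto = build_step_protocol(0, 300, 50))
  for (i in seq_along(sim$experiment$sweeps)) {
    sw <- sim$experiment$sweeps[[i]]
    sp <- detect_spikes(sw, window_s = c(0.1, 1.1))
    expect_equal(nrow(sp), sim$truth$n_spikes[i])
  }
})

test_that("a subthreshold sweep yields an empty spike train", {
  sw <- new_sweep(rep(-75, 10000) + rnorm(10000, 0, 0.3), 10000,
                  channel_kind = "current_clamp_voltage", quiet = TRUE)
  expect_equal(nrow(detect_spikes(sw)), 0)
})

test_that("the F-I table covers the full protocol and counts per second", {
  sim <- lif_experiment()
  fi <- fi_curve(sim$experiment)
  expect_equal(nrow(fi$steps), 60)
  expect_equal(fi$steps$rate_Hz, fi$steps$n_spikes / 1)
})

test_that("the F-I curve is non-decreasing when the block gate is off", {
  sim <- lif_experiment(neuron_params(block = FALSE))
  fi <- fi_curve(sim$experiment)
  expect_true(all(diff(fi$steps$rate_Hz) >= 0))
})

test_that("detected rheobase equals the closed form within one grid step", {
  pars <- neuron_params(g_L_nS = 10, E_L_mV = -80, V_th_mV = -65,
                        b_pA = 0, block = FALSE)
  sim <- lif_experiment(pars, build_step_protocol(-100, 300, 10))
  fi <- fi_curve(sim$experiment)
  expect_lte(abs(fi$rheobase_pA - lif_rheobase(pars)), 10)
})

test_that("an all-subthreshold cell reports a missing rheobase", {
  sim <- lif_experiment(proto = build_step_protocol(-100, 50, 10))
  expect_message(fi <- fi_curve(sim$experiment), "rheobase missing")
  expect_true(is.na(fi$rheobase_pA))
})

test_that("depolarization block is flagged from truncated steps only", {
  # gate disabled and no adaptation: fires to the end of every step
  sim <- lif_experiment(neuron_params(b_pA = 0, block = FALSE),
                        build_step_protocol(100, 400, 50))
  fi <- fi_curve(sim$experiment)
  db <- depolarization_block(fi)
  expect_false(db$entered)
  expect_true(is.na(db$block_current_pA))
  # gate enabled: the simulator truth identifies the first truncated step
  sim2 <- lif_experiment(neuron_params(), build_step_protocol(100, 490, 10))
  fi2 <- fi_curve(sim2$experiment)
  db2 <- depolarization_block(fi2)
  truth_block <- sim2$truth$step_current_pA[
    sim2$truth$n_spikes > 0 & sim2$truth$last_spike_in_step_s < 0.9]
  expect_true(db2$entered)
  expect_equal(db2$block_current_pA, min(truth_block))
})

test_that("cohort contingency tables conserve cell counts", {
  g <- rep(c("WT", "KO"), c(9, 10))
  flags <- c(rep(TRUE, 7), rep(FALSE, 2), rep(TRUE, 10))
  tab <- block_contingency(g, flags)
  expect_equal(unname(rowSums(tab)), c(9, 10))
  expect_equal(unname(tab), matrix(c(7, 10, 2, 0), 2))
})

test_that("AP features match the Gaussian closed form and its invariances", {
  fs <- 1e5
  t <- seq(0, 0.02, by = 1 / fs)
  spike <- 100 * exp(-0.5 * ((t - 0.01) / 5e-4)^2)
  sw <- new_sweep(spike, fs, channel_kind = "current_clamp_voltage",
                  quiet = TRUE)
  f <- ap_features(sw, 0.01)
  expect_equal(f$prominence_mV, 100, tolerance = 1e-6)
  expect_equal(f$half_width_ms, 2 * sqrt(2 * log(2)) * 0.5,
               tolerance = 1e-3)   # 1.177 ms
  expect_false(f$unreliable)
  # DC offset leaves both features unchanged
  sw2 <- sw; sw2$samples <- sw$samples - 70
  f2 <- ap_features(sw2, 0.01)
  expect_equal(f2$prominence_mV, f$prominence_mV, tolerance = 1e-9)
  expect_equal(f2$half_width_ms, f$half_width_ms, tolerance = 1e-9)
  # doubling height doubles prominence, half-width unchanged for a Gaussian
  sw3 <- sw; sw3$samples <- 2 * sw$samples
  f3 <- ap_features(sw3, 0.01)
  expect_equal(f3$prominence_mV, 200, tolerance = 1e-6)
  expect_equal(f3$half_width_ms, f$half_width_ms, tolerance = 1e-6)
})

test_that("clipped spike peaks are flagged unreliable", {
  fs <- 1e4
  t <- seq(0, 0.02, by = 1 / fs)
  spike <- pmin(100 * exp(-0.5 * ((t - 0.01) / 1e-3)^2), 60)
  sw <- new_sweep(spike, fs, channel_kind = "current_clamp_voltage",
                  quiet = TRUE)
  expect_true(ap_features(sw, 0.01)$unreliable)
})

test_that("the ISI adaptation ratio is first ISI over last ISI", {
  expect_equal(isi_adaptation_ratio(seq(0, 1, by = 0.1)), 1)
  isis <- c(30, 40, 55, 70, 85, 100) / 1000
  expect_equal(isi_adaptation_ratio(cumsum(c(0, isis))), 0.3)
  expect_true(is.na(isi_adaptation_ratio(c(0.1, 0.2))))
})

test_that("input resistance recovers the ohmic truth and its invariances", {
  pars <- neuron_params(g_L_nS = 5, b_pA = 0, block = FALSE)   # 200 MOhm
  sim <- lif_experiment(pars, build_step_protocol(-100, -10, 10))
  expect_equal(input_resistance(sim$experiment), 200, tolerance = 1e-6)
  # adding a DC offset to every sweep leaves the estimate unchanged
  shifted <- sim$experiment
  shifted$sweeps <- lapply(shifted$sweeps, function(s) {
    s$samples <- s$samples + 13.7; s
  })
  expect_equal(input_resistance(shifted), 200, tolerance = 1e-6)
  # steps outside the -100..-10 window are ignored by the fit
  full <- lif_experiment(pars, build_step_protocol(-100, 100, 10))
  expect_equal(input_resistance(full$experiment), 200, tolerance = 1e-6)
  few <- lif_experiment(pars, build_step_protocol(-20, -10, 10))
  expect_error(input_resistance(few$experiment), "at least 3")
})

test_that("resting potential is the baseline mean and validates its window", {
  sw <- new_sweep(rep(-80, 5000), 10000,
                  channel_kind = "current_clamp_voltage", quiet = TRUE)
  expect_equal(resting_potential(sw, c(0, 0.2)), -80)
  vals <- vapply(1:30, function(s) {
    sw2 <- new_sweep(-80 + with_seed_test(s, rnorm(10000)), 10000,
                     channel_kind = "current_clamp_voltage", quiet = TRUE)
    resting_potential(sw2, c(0, 1))
  }, 0)
  expect_lt(max(abs(vals + 80)), 0.1)   # se of the mean = 0.01 mV
  expect_error(resting_potential(sw, c(0, 2)), "outside")
  expect_error(resting_potential(sw, c(0, 0.05)), "100 ms")
})
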