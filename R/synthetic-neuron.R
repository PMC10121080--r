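# Adaptive leaky integrate-and-fire granule-cell simulator with a slow
# inactivation gate producing depolarization block. The reduced model is the
# simplest one exhibiting the phenotypes the intrinsic-excitability module
# measures: an exact closed-form rheobase gL*(Vth - EL) when adaptation and
# block are disabled, spike-frequency adaptation via an adaptation current,
# and a spikeless depolarized plateau once the gate falls below its
# threshold.

#' Parameters of the adaptive integrate-and-fire neuron
#'
#' Defaults describe a plausible mature dentate granule cell: input
#' resistance 250 MOhm (`g_L` = 4 nS), membrane time constant 20 ms
#' (`C` = 80 pF), resting potential -80 mV, rheobase
#' `g_L * (V_th - E_L)` = 100 pA, peak firing around 30 Hz with block at a
#' few hundred pA.
#'
#' @param C_pF Membrane capacitance (pF), > 0.
#' @param g_L_nS Leak conductance (nS), > 0.
#' @param E_L_mV Leak reversal / resting potential (mV).
#' @param V_th_mV Spike threshold (mV), > `E_L_mV`.
#' @param V_reset_mV Post-spike reset potential (mV).
#' @param V_spike_mV Peak of the stylized spike waveform (mV).
#' @param spike_ms Width of the stylized spike plateau (ms).
#' @param refractory_ms Absolute refractory period (ms).
#' @param b_pA Adaptation-current increment per spike (pA); 0 disables
#'   adaptation.
#' @param tau_w_ms Adaptation-current decay time constant (ms).
#' @param block Logical: enable the slow inactivation gate.
#' @param h_decrement Multiplicative per-spike gate decrement.
#' @param tau_h_ms Gate relaxation time constant (ms).
#' @param vh_mV,kh_mV Midpoint and slope of the gate's steady-state voltage
#'   dependence `hinf(V) = 1/(1 + exp((V - vh)/kh))`.
#' @param h_block Gate threshold: spiking is suppressed while `h < h_block`.
#' @param V_cap_mV Ceiling of the blocked depolarized plateau (mV).
#' @return A `neuron_params` list.
#' @export
neuron_params <- function(C_pF = 80, g_L_nS = 4, E_L_mV = -80, V_th_mV = -55,
                          V_reset_mV = -70, V_spike_mV = 35, spike_ms = 0.4,
                          refractory_ms = 2, b_pA = 60, tau_w_ms = 150,
                          block = TRUE, h_decrement = 0.09, tau_h_ms = 150,
                          vh_mV = -45, kh_mV = 4, h_block = 0.7,
                          V_cap_mV = -20) {
  if (g_L_nS <= 0 || C_pF <= 0)
    stop("validation error: g_L and C must be positive", call. = FALSE)
  if (V_th_mV <= E_L_mV)
    stop("validation error: V_th must exceed E_L", call. = FALSE)
  structure(list(C_pF = C_pF, g_L_nS = g_L_nS, E_L_mV = E_L_mV,
                 V_th_mV = V_th_mV, V_reset_mV = V_reset_mV,
                 V_spike_mV = V_spike_mV, spike_ms = spike_ms,
                 refractory_ms = refractory_ms, b_pA = b_pA,
                 tau_w_ms = tau_w_ms, block = block,
                 h_decrement = h_decrement, tau_h_ms = tau_h_ms,
                 vh_mV = vh_mV, kh_mV = kh_mV, h_block = h_block,
                 V_cap_mV = V_cap_mV),
            class = "neuron_params")
}

#' Closed-form rheobase of the reduced model
#'
#' With adaptation and block disabled the model spikes iff the injected
#' current exceeds `g_L * (V_th - E_L)`.
#'
#' @param params A [neuron_params()] object.
#' @return Rheobase current (pA).
#' @export
lif_rheobase <- function(params) {
  params$g_L_nS * (params$V_th_mV - params$E_L_mV)
}

#' Simulate a family of current-step sweeps from the integrate-and-fire model
#'
#' Integrates the model once per protocol step with a fixed-step explicit
#' scheme at `dt_ms` (default 0.01 ms, ten times finer than the 10 kHz
#' digitization) and returns current-clamp voltage sweeps plus per-step
#' ground truth (exact spike times from the integrator).
#'
#' @param params A [neuron_params()] object.
#' @param protocol A [build_step_protocol()] object.
#' @param noise_sd_mV Additive Gaussian noise on the recorded trace (mV).
#' @param tail_s Recording time after the step ends (s).
#' @param dt_ms Integration step (ms); must be <= 0.05 for stability.
#' @param sampling_rate Recording rate of the output sweeps (Hz).
#' @param cell_id Identifier stored in sweep metadata.
#' @param seed Optional RNG seed (affects the recording noise only).
#' @return List with `experiment` (one sweep per step) and `truth`, a tibble
#'   with per-step spike counts, spike times and last-spike times.
#' @export
simulate_fi_sweeps <- function(params = neuron_params(),
                               protocol = build_step_protocol(-100, 490, 10),
                               noise_sd_mV = 0, tail_s = 0.15, dt_ms = 0.01,
                               sampling_rate = 10000, cell_id = "cell_1",
                               seed = NULL) {
  stopifnot(inherits(params, "neuron_params"),
            inherits(protocol, "step_protocol"))
  record_every <- round(1000 / (sampling_rate * dt_ms))
  if (abs(record_every * dt_ms - 1000 / sampling_rate) > 1e-9)
    stop("validation error: dt_ms must divide the sampling interval",
         call. = FALSE)
  steps <- protocol_steps(protocol)
  onset_ms <- protocol$step_onset_s * 1000
  dur_ms <- protocol$duration_s * 1000
  total_ms <- onset_ms + dur_ms + tail_s * 1000
  with_seed(seed, {
    out <- lapply(steps, function(I) {
      sim <- .alif_integrate(I, onset_ms, dur_ms, total_ms, dt_ms,
                             record_every,
                             params$C_pF, params$g_L_nS, params$E_L_mV,
                             params$V_th_mV, params$V_reset_mV,
                             params$V_spike_mV, params$spike_ms,
                             params$refractory_ms, params$b_pA,
                             params$tau_w_ms, params$block,
                             params$h_decrement, params$tau_h_ms,
                             params$vh_mV, params$kh_mV, params$h_block,
                             params$V_cap_mV)
      v <- sim$V_mV
      if (noise_sd_mV > 0) v <- v + stats::rnorm(length(v), 0, noise_sd_mV)
      sw <- new_sweep(v, sampling_rate, channel_kind = "current_clamp_voltage",
                      protocol = protocol,
                      metadata = list(step_current_pA = I, subject = cell_id),
                      quiet = TRUE)
      list(sweep = sw, spikes = sim$spike_times_s)
    })
    truth <- tibble::tibble(
      step_current_pA = steps,
      n_spikes = vapply(out, function(o) length(o$spikes), 0L),
      spike_times_s = lapply(out, function(o) o$spikes),
      last_spike_s = vapply(out, function(o)
        if (length(o$spikes)) max(o$spikes) else NA_real_, 0)
    )
    truth$last_spike_in_step_s <- truth$last_spike_s - protocol$step_onset_s
    exp <- new_experiment(lapply(out, `[[`, "sweep"),
                          design = tibble::tibble(subject = cell_id),
                          ground_truth = list(params = params, steps = truth))
    list(experiment = exp, truth = truth)
  })
}
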