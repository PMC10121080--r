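# Detection and quantification of spontaneous/miniature postsynaptic
# currents in voltage-clamp sweeps.

# Steady-state initial conditions for an IIR filter (transposed direct form
# II), so that filtering a constant yields that constant from sample one.
lfilter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  bb <- c(b, rep(0, nf - length(b))) / a[1]
  aa <- c(a, rep(0, nf - length(a))) / a[1]
  if (nf == 1) return(numeric(0))
  comp <- matrix(0, nf - 1, nf - 1)
  comp[1, ] <- -aa[-1]
  if (nf > 2) comp[cbind(2:(nf - 1), 1:(nf - 2))] <- 1
  solve(diag(nf - 1) - t(comp), bb[-1] - aa[-1] * bb[1])
}

# Forward-backward ("zero-phase") IIR filtering with odd-reflection padding
# and steady-state initialization, so DC signals and edges are preserved.
zero_phase_filter <- function(b, a, x) {
  n <- length(x)
  nf <- max(length(a), length(b))
  npad <- min(n - 1, 3 * (nf - 1) * 10)
  zi <- lfilter_zi(b, a)
  ext <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  y <- .iir_filter(b, a, ext, zi * ext[1])
  y <- rev(.iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(npad + 1):(npad + n)]
}

#' Low-pass filter a sweep with a zero-phase elliptic filter
#'
#' Applies an elliptic (Cauer) low-pass filter forward and backward so the
#' result has zero phase shift, preserving event peak times. The filter is
#' scaled to exactly unit DC gain so baselines pass through unchanged.
#'
#' @param sweep An `ephys_sweep`.
#' @param cutoff_Hz Cutoff frequency (default 1000 Hz); must be below the
#'   Nyquist frequency.
#' @param order Filter order (default 4).
#' @param passband_ripple_dB,stopband_atten_dB Elliptic design parameters
#'   (defaults 0.1 dB ripple, 40 dB attenuation).
#' @return The sweep with filtered samples; the filter settings are recorded
#'   in its metadata.
#' @export
lowpass_filter <- function(sweep, cutoff_Hz = 1000, order = 4,
                           passband_ripple_dB = 0.1,
                           stopband_atten_dB = 40) {
  stopifnot(inherits(sweep, "ephys_sweep"))
  nyq <- sweep$sampling_rate / 2
  if (cutoff_Hz >= nyq)
    stop("validation error: cutoff must be below the Nyquist frequency (",
         nyq, " Hz)", call. = FALSE)
  flt <- signal::ellip(order, passband_ripple_dB, stopband_atten_dB,
                       cutoff_Hz / nyq)
  b <- flt$b / (sum(flt$b) / sum(flt$a))   # pin DC gain to 1
  out <- sweep
  out$samples <- zero_phase_filter(b, flt$a, sweep$samples)
  out$metadata$filter <- list(kind = "elliptic", cutoff_Hz = cutoff_Hz,
                              order = order,
                              passband_ripple_dB = passband_ripple_dB,
                              stopband_atten_dB = stopband_atten_dB,
                              zero_phase = TRUE)
  out
}

empty_events <- function() {
  tibble::tibble(onset_s = numeric(), peak_s = numeric(),
                 amplitude_pA = numeric(), baseline_pA = numeric(),
                 rise_time_ms = numeric(), decay_time_ms = numeric(),
                 decay_unresolved = logical(),
                 interevent_interval_ms = numeric())
}

#' Detect postsynaptic-current events by local-baseline threshold crossing
#'
#' Candidate peaks are local extrema of the (polarity-rectified) trace; each
#' is measured against a local baseline (median over the `baseline_ms`
#' window ending `baseline_gap_ms` before the peak) and kept when the
#' baseline-to-peak amplitude reaches `threshold_pA`. Accepted events are
#' separated by at least `refractory_ms`. Use a threshold of 3 pA for EPSCs
#' and 10 pA for IPSCs.
#'
#' @param sweep A (typically [lowpass_filter()]ed) voltage-clamp sweep.
#' @param threshold_pA Detection threshold (> 0), baseline-to-peak.
#' @param polarity `"inward"` (EPSC-like, negative) or `"outward"`
#'   (IPSC-like at depolarized holding, positive).
#' @param refractory_ms Minimum separation between detected events (ms).
#' @param baseline_ms Local-baseline window length (ms).
#' @param baseline_gap_ms Gap between the baseline window and the peak (ms).
#' @param onset_frac Fraction of the amplitude defining the event onset.
#' @param persist_ms,persist_frac Persistence criterion replacing manual
#'   curation: the mean deflection over the `persist_ms` after the peak
#'   must stay above `persist_frac` of the amplitude. Synaptic events decay
#'   over milliseconds and pass; band-limited noise blips do not.
#' @param rise_ms Cap on the onset search: the event onset is looked for at
#'   most `rise_ms` before the trough preceding the peak.
#' @return Tibble of events ordered by onset: `onset_s`, `peak_s`,
#'   `amplitude_pA` (positive magnitude), `baseline_pA`, kinetic columns
#'   (`NA` until [measure_kinetics()]), `interevent_interval_ms`.
#' @export
detect_events <- function(sweep, threshold_pA = 3,
                          polarity = c("inward", "outward"),
                          refractory_ms = 2, baseline_ms = 10,
                          baseline_gap_ms = 3, onset_frac = 0.1,
                          persist_ms = 2.5, persist_frac = 0.6,
                          rise_ms = 2) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(sweep, "ephys_sweep"))
  if (threshold_pA <= 0) stop("`threshold_pA` must be > 0", call. = FALSE)
  meta_pol <- sweep$metadata$polarity
  if (!is.null(meta_pol) && !identical(meta_pol, polarity))
    warning("requested polarity '", polarity,
            "' differs from sweep metadata polarity '", meta_pol, "'",
            call. = FALSE)
  fs <- sweep$sampling_rate
  sgn <- if (polarity == "inward") -1 else 1
  y <- sgn * sweep$samples
  refr_n <- max(1L, round(refractory_ms / 1000 * fs))
  base_n <- max(1L, round(baseline_ms / 1000 * fs))
  gap_n <- max(1L, round(baseline_gap_ms / 1000 * fs))

  cand <- pracma::findpeaks(y, minpeakheight = stats::median(y) +
                              0.5 * threshold_pA,
                            minpeakdistance = refr_n)
  if (is.null(cand)) return(empty_events())
  idx <- sort(cand[, 2])

  keep <- logical(length(idx))
  onset_t <- amp <- base <- numeric(length(idx))
  last_peak <- -Inf
  for (j in seq_along(idx)) {
    i <- idx[j]
    w0 <- max(1L, i - gap_n - base_n)
    w1 <- max(1L, i - gap_n)
    if ((i - last_peak) < refr_n) next
    # baseline: the higher of the local median and the trough separating
    # the candidate from the previous accepted event, so the amplitude is
    # the genuine increment; this rejects ripples riding on a decay while
    # keeping stacked events, whose own rise is a fresh deflection
    lb <- if (is.finite(last_peak))
      last_peak + which.min(y[last_peak:i]) - 1L else 1L
    b_med <- stats::median(y[w0:w1])
    b_j <- if (is.finite(last_peak)) max(b_med, y[lb]) else b_med
    a_j <- y[i] - b_j
    if (a_j < threshold_pA) next
    p1 <- min(length(y), i + max(1L, round(persist_ms / 1000 * fs)))
    if (p1 > i && mean(y[(i + 1):p1] - b_j) < persist_frac * a_j) next
    keep[j] <- TRUE
    amp[j] <- a_j
    base[j] <- b_j
    # onset: last crossing of baseline + onset_frac * amplitude before the
    # peak, not reaching back past the trough (lb) separating it from the
    # previous accepted event
    last_peak <- i
    lev <- b_j + onset_frac * a_j
    k <- i
    while (k > lb && y[k - 1] > lev && (i - k) < 5 * base_n) k <- k - 1
    if (k > 1 && y[k - 1] <= lev) {
      frac <- (lev - y[k - 1]) / (y[k] - y[k - 1])
      onset_t[j] <- (k - 2 + frac) / fs
    } else onset_t[j] <- (k - 1) / fs
  }
  if (!any(keep)) return(empty_events())
  ev <- tibble::tibble(onset_s = sweep$t0 + onset_t[keep],
                       peak_s = sweep$t0 + (idx[keep] - 1) / fs,
                       amplitude_pA = amp[keep],
                       baseline_pA = base[keep],
                       rise_time_ms = NA_real_, decay_time_ms = NA_real_,
                       decay_unresolved = NA,
                       interevent_interval_ms = NA_real_)
  ev <- ev[order(ev$onset_s), ]
  ev$interevent_interval_ms <- c(NA_real_, diff(ev$onset_s) * 1000)
  ev
}

#' Measure rise and decay kinetics of detected events
#'
#' Completes an event table with the 10-90 % rise time (time between the
#' crossings of 10 % and 90 % of the baseline-to-peak amplitude on the
#' rising limb) and the decay time (peak to 1/e of the amplitude on the
#' falling limb), both by linear interpolation between samples. A decay that
#' is interrupted by the next event's onset before reaching 1/e is flagged
#' unresolved and excluded from summary means.
#'
#' @param sweep The sweep the events were detected on.
#' @param events Event tibble from [detect_events()].
#' @param polarity As in [detect_events()].
#' @return The event tibble with `rise_time_ms`, `decay_time_ms` and
#'   `decay_unresolved` filled in.
#' @export
measure_kinetics <- function(sweep, events,
                             polarity = c("inward", "outward")) {
  polarity <- match.arg(polarity)
  if (nrow(events) == 0) return(events)
  fs <- sweep$sampling_rate
  sgn <- if (polarity == "inward") -1 else 1
  y <- sgn * sweep$samples
  n <- length(y)
  cross_up <- function(i0, i1, lev) {
    # first upward crossing of lev in y[i0..i1]; interpolated index
    seg <- y[i0:i1]
    k <- which(seg[-1] >= lev & seg[-length(seg)] < lev)
    if (!length(k)) return(NA_real_)
    k <- k[1]
    i0 + k - 1 + (lev - seg[k]) / (seg[k + 1] - seg[k])
  }
  cross_down <- function(i0, i1, lev) {
    seg <- y[i0:i1]
    k <- which(seg[-1] <= lev & seg[-length(seg)] > lev)
    if (!length(k)) return(NA_real_)
    k <- k[1]
    i0 + k - 1 + (seg[k] - lev) / (seg[k] - seg[k + 1])
  }
  for (j in seq_len(nrow(events))) {
    pk <- round((events$peak_s[j] - sweep$t0) * fs) + 1
    on <- max(1L, floor((events$onset_s[j] - sweep$t0) * fs) - 2L)
    b <- events$baseline_pA[j]
    a <- events$amplitude_pA[j]
    if (pk > on) {
      t10 <- cross_up(on, pk, b + 0.1 * a)
      t90 <- cross_up(on, pk, b + 0.9 * a)
      if (!is.na(t10) && !is.na(t90))
        events$rise_time_ms[j] <- (t90 - t10) / fs * 1000
    }
    lim <- if (j < nrow(events))
      round((events$onset_s[j + 1] - sweep$t0) * fs) else n
    lim <- min(n, max(pk + 1, lim))
    td <- cross_down(pk, lim, b + a / exp(1))
    if (is.na(td)) {
      events$decay_unresolved[j] <- TRUE
    } else {
      events$decay_unresolved[j] <- FALSE
      events$decay_time_ms[j] <- (td - pk) / fs * 1000
    }
  }
  events
}

#' Summarize detected events for one cell
#'
#' A cell qualifies for group analysis when at least `min_events` events
#' were detected. Unresolved decays are excluded from the kinetic means.
#'
#' @param events Event tibble (after [measure_kinetics()]).
#' @param duration_s Analyzed trace duration (> 0).
#' @param min_events Minimum event count for inclusion (default 100).
#' @param cell_id Identifier carried into the summary.
#' @return One-row tibble: cell, n_events, mean_amplitude_pA, frequency_Hz,
#'   mean_rise_ms, mean_decay_ms, qualifies.
#' @export
summarize_cell <- function(events, duration_s, min_events = 100,
                           cell_id = NA_character_) {
  if (duration_s <= 0) stop("`duration_s` must be > 0", call. = FALSE)
  n <- nrow(events)
  dec <- events$decay_time_ms[!is.na(events$decay_unresolved) &
                                !events$decay_unresolved]
  tibble::tibble(
    cell = cell_id,
    n_events = n,
    mean_amplitude_pA = if (n) mean(events$amplitude_pA) else NA_real_,
    frequency_Hz = n / duration_s,
    mean_rise_ms = if (n && any(!is.na(events$rise_time_ms)))
      mean(events$rise_time_ms, na.rm = TRUE) else NA_real_,
    mean_decay_ms = if (length(dec)) mean(dec) else NA_real_,
    qualifies = n >= min_events
  )
}

#' Match detected events against ground truth
#'
#' Greedy one-to-one matching of detected event onsets to ground-truth
#' event (onset) times within a tolerance; reports recall and precision of
#' the detector.
#'
#' @param truth_times_s Ground-truth event onset times (s).
#' @param events Detected event tibble.
#' @param tol_ms Matching tolerance (ms).
#' @return List with `matched` (tibble of truth/detected time pairs),
#'   `n_missed`, `n_spurious`, `recall`, `precision`.
#' @export
match_events <- function(truth_times_s, events, tol_ms = 2) {
  det <- events$onset_s
  tol <- tol_ms / 1000
  used <- logical(length(det))
  pairs <- vector("list", length(truth_times_s))
  for (i in seq_along(truth_times_s)) {
    d <- abs(det - truth_times_s[i])
    d[used] <- Inf
    j <- if (length(d)) which.min(d) else integer(0)
    if (length(j) && is.finite(d[j]) && d[j] <= tol) {
      used[j] <- TRUE
      pairs[[i]] <- c(truth_times_s[i], det[j])
    }
  }
  m <- do.call(rbind, pairs)
  n_match <- if (is.null(m)) 0L else nrow(m)
  list(matched = if (is.null(m)) tibble::tibble(truth_s = numeric(),
                                                detected_s = numeric())
       else tibble::tibble(truth_s = m[, 1], detected_s = m[, 2]),
       n_missed = length(truth_times_s) - n_match,
       n_spurious = sum(!used),
       recall = if (length(truth_times_s)) n_match / length(truth_times_s)
       else NA_real_,
       precision = if (length(det)) n_match / length(det) else NA_real_)
}
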