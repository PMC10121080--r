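#' Construct a recording sweep
#'
#' A sweep is one episode of a recorded or simulated signal together with its
#' sampling rate and protocol metadata. It is the universal input unit of the
#' package: voltage-clamp current traces (pA), current-clamp voltage traces
#' (mV) and evoked field potentials (mV) are all carried as sweeps.
#'
#' @param samples Numeric vector of signal values. Units depend on
#'   `channel_kind`: pA for `"voltage_clamp_current"`, mV otherwise.
#' @param sampling_rate Sampling rate in Hz. The package default throughout is
#'   10 kHz, the usual digitization rate for these recordings; other rates are
#'   accepted but noted with a message.
#' @param t0 Time of the first sample in seconds.
#' @param channel_kind One of `"voltage_clamp_current"`,
#'   `"current_clamp_voltage"`, `"field_potential"`.
#' @param protocol Optional protocol object: a [build_step_protocol()] result
#'   or a tibble of stimulation events such as [build_tbs_protocol()] returns.
#' @param metadata Named list of free-form metadata (cell id, animal id,
#'   genotype, treatment, holding potential, step current, ...).
#' @param quiet Suppress the non-default sampling rate message.
#' @return An object of class `"ephys_sweep"`.
#' @export
new_sweep <- function(samples, sampling_rate,
                      t0 = 0,
                      channel_kind = c("voltage_clamp_current",
                                       "current_clamp_voltage",
                                       "field_potential"),
                      protocol = NULL, metadata = list(), quiet = FALSE) {
  channel_kind <- match.arg(channel_kind)
  if (!is.numeric(samples) || length(samples) == 0L)
    stop("`samples` must be a non-empty numeric vector", call. = FALSE)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("`sampling_rate` must be a single positive number (Hz)", call. = FALSE)
  if (!quiet && sampling_rate != 10000)
    message("sweep uses a non-default sampling rate: ", sampling_rate, " Hz")
  structure(
    list(samples = as.numeric(samples),
         sampling_rate = as.numeric(sampling_rate),
         t0 = as.numeric(t0),
         channel_kind = channel_kind,
         protocol = protocol,
         metadata = metadata),
    class = "ephys_sweep"
  )
}

#' @export
print.ephys_sweep <- function(x, ...) {
  cat(sprintf("<ephys_sweep> %s | %d samples @ %g Hz | %.4g s\n",
              x$channel_kind, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' Sample times of a sweep
#'
#' @param sweep An [new_sweep()] object.
#' @return Numeric vector of times in seconds, starting at `t0`.
#' @export
sweep_times <- function(sweep) {
  sweep$t0 + (seq_along(sweep$samples) - 1) / sweep$sampling_rate
}

sweep_duration <- function(sweep) length(sweep$samples) / sweep$sampling_rate

#' Construct an experiment: an ordered collection of sweeps plus a design
#'
#' @param sweeps List of [new_sweep()] objects.
#' @param design A data frame of grouping factors with one row per subject
#'   (columns such as `subject`, `genotype`, `treatment`).
#' @param ground_truth Optional ground-truth record attached by the synthetic
#'   module.
#' @return An object of class `"ephys_experiment"`.
#' @export
new_experiment <- function(sweeps, design = NULL, ground_truth = NULL) {
  if (!is.list(sweeps) || !all(vapply(sweeps, inherits, TRUE, "ephys_sweep")))
    stop("`sweeps` must be a list of ephys_sweep objects", call. = FALSE)
  rates <- unique(vapply(sweeps, function(s) s$sampling_rate, 0))
  if (length(rates) > 1L)
    message("experiment mixes sampling rates: ",
            paste(rates, collapse = ", "), " Hz")
  if (!is.null(design)) {
    design <- tibble::as_tibble(design)
    subj <- vapply(sweeps, function(s)
      as.character(s$metadata$subject %||% NA_character_), "")
    known <- unique(as.character(design$subject))
    bad <- stats::na.omit(setdiff(subj, c(known, NA_character_)))
    if (length(bad))
      stop("sweep subject id(s) not present in design: ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  structure(list(sweeps = sweeps, design = design, ground_truth = ground_truth),
            class = "ephys_experiment")
}

#' @export
print.ephys_experiment <- function(x, ...) {
  cat(sprintf("<ephys_experiment> %d sweeps\n", length(x$sweeps)))
  if (!is.null(x$design)) {
    cat("  design:\n")
    print(x$design, n = 4)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- current-step protocol ------------------------------------------------

#' Define a square current-step protocol
#'
#' Enumerates a family of square current injections covering
#' `start_pA..stop_pA` inclusive in `increment_pA` steps, e.g. the standard
#' granule-cell F-I protocol of 1 s pulses in 10 pA increments from -100 to
#' 490 pA.
#'
#' @param start_pA,stop_pA First and last step current (pA).
#' @param increment_pA Step increment (pA); must divide the range.
#' @param duration_s Duration of each step (s).
#' @param inter_step_s Interval between steps (s).
#' @param step_onset_s Time of step onset within each sweep (s); the
#'   pre-onset segment is the baseline.
#' @return An object of class `"step_protocol"`.
#' @export
build_step_protocol <- function(start_pA, stop_pA, increment_pA,
                                duration_s = 1, inter_step_s = 1,
                                step_onset_s = 0.1) {
  if (increment_pA == 0) stop("`increment_pA` must be non-zero", call. = FALSE)
  if (duration_s <= 0) stop("`duration_s` must be positive", call. = FALSE)
  n <- (stop_pA - start_pA) / increment_pA
  if (n < 0) stop("increment sign inconsistent with start/stop", call. = FALSE)
  if (abs(n - round(n)) > 1e-8)
    stop("`increment_pA` does not divide the range start..stop", call. = FALSE)
  structure(
    list(start_pA = start_pA, stop_pA = stop_pA, increment_pA = increment_pA,
         duration_s = duration_s, inter_step_s = inter_step_s,
         step_onset_s = step_onset_s),
    class = "step_protocol"
  )
}

#' Enumerate the step currents of a protocol
#' @param protocol A [build_step_protocol()] object.
#' @return Numeric vector of step currents (pA), start..stop inclusive.
#' @export
protocol_steps <- function(protocol) {
  seq(protocol$start_pA, protocol$stop_pA, by = protocol$increment_pA)
}

#' Reconstruct a step protocol from its enumerated steps
#'
#' Inverse of [protocol_steps()]: given the step currents and the timing
#' parameters, returns the original protocol.
#' @param steps_pA Numeric vector of equally spaced step currents.
#' @inheritParams build_step_protocol
#' @export
protocol_from_steps <- function(steps_pA, duration_s = 1, inter_step_s = 1,
                                step_onset_s = 0.1) {
  if (length(steps_pA) < 1L) stop("no steps supplied", call. = FALSE)
  inc <- if (length(steps_pA) == 1L) 10 else unique(round(diff(steps_pA), 9))
  if (length(inc) != 1L) stop("steps are not equally spaced", call. = FALSE)
  build_step_protocol(steps_pA[1], steps_pA[length(steps_pA)], inc,
                      duration_s, inter_step_s, step_onset_s)
}

#' @export
print.step_protocol <- function(x, ...) {
  cat(sprintf("<step_protocol> %g..%g pA by %g pA (%d steps, %g s each)\n",
              x$start_pA, x$stop_pA, x$increment_pA,
              length(protocol_steps(x)), x$duration_s))
  invisible(x)
}

# ---- stimulation-event protocols ------------------------------------------

#' Build a theta-burst stimulation (TBS) protocol
#'
#' The LTP-induction pattern: six series (separated by 20 s) of six trains
#' (separated by 0.2 s) of six pulses at 400 Hz, i.e. 216 stimulus times with
#' 2.5 ms within-train spacing.
#'
#' @param t0_s Time of the first pulse (s).
#' @param intensity_uA Stimulation intensity attached to every event (uA).
#' @param n_series,n_trains,n_pulses Pattern counts (defaults 6, 6, 6).
#' @param series_interval_s,train_interval_s Spacing between series and
#'   between trains (s).
#' @param pulse_rate_Hz Within-train pulse rate (Hz).
#' @return Tibble of stimulation events with columns `time_s`,
#'   `intensity_uA`, `pulse_index_in_pair` (`NA`: not a paired-pulse
#'   protocol) and `interpulse_interval_ms` (`NA`).
#' @export
build_tbs_protocol <- function(t0_s = 0, intensity_uA = NA_real_,
                               n_series = 6, n_trains = 6, n_pulses = 6,
                               series_interval_s = 20, train_interval_s = 0.2,
                               pulse_rate_Hz = 400) {
  grid <- expand.grid(pulse = seq_len(n_pulses) - 1,
                      train = seq_len(n_trains) - 1,
                      series = seq_len(n_series) - 1)
  times <- t0_s + grid$series * series_interval_s +
    grid$train * train_interval_s + grid$pulse / pulse_rate_Hz
  tibble::tibble(time_s = sort(times),
                 intensity_uA = intensity_uA,
                 pulse_index_in_pair = NA_integer_,
                 interpulse_interval_ms = NA_real_)
}

#' Build a paired-pulse stimulation event pair
#'
#' @param t0_s Time of the first pulse (s).
#' @param ipi_ms Interpulse interval (ms).
#' @param intensity_uA Stimulation intensity (uA).
#' @return Tibble of two stimulation events.
#' @export
build_paired_pulse <- function(t0_s, ipi_ms, intensity_uA = NA_real_) {
  tibble::tibble(time_s = c(t0_s, t0_s + ipi_ms / 1000),
                 intensity_uA = intensity_uA,
                 pulse_index_in_pair = c(1L, 2L),
                 interpulse_interval_ms = ipi_ms)
}

# ---- container i/o --------------------------------------------------------

#' Write an experiment to disk
#'
#' Two formats are supported. The native container (`format = "container"`)
#' is a single serialized file that round-trips bit-exactly: samples,
#' metadata, protocols and ground truth are restored unchanged by
#' [read_experiment()]. The delimited fallback (`format = "delimited"`)
#' writes a directory of plain-text sweeps (`sweep_NNN.csv`, columns
#' `time_s,value`) plus a structured-text sidecar `metadata.yaml`, for
#' inspection with ordinary text tools.
#'
#' @param experiment An [new_experiment()] object.
#' @param path Output file (container) or directory (delimited).
#' @param format `"container"` or `"delimited"`.
#' @return `path`, invisibly.
#' @export
write_experiment <- function(experiment, path,
                             format = c("container", "delimited")) {
  format <- match.arg(format)
  stopifnot(inherits(experiment, "ephys_experiment"))
  if (format == "container") {
    saveRDS(experiment, path)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(n_sweeps = length(experiment$sweeps),
               design = if (is.null(experiment$design)) NULL else
                 lapply(as.list(experiment$design), as.vector),
               sweeps = list())
  for (i in seq_along(experiment$sweeps)) {
    sw <- experiment$sweeps[[i]]
    fn <- sprintf("sweep_%03d.csv", i)
    utils::write.csv(
      data.frame(time_s = sweep_times(sw), value = sw$samples),
      file.path(path, fn), row.names = FALSE)
    meta$sweeps[[fn]] <- list(sampling_rate = sw$sampling_rate, t0 = sw$t0,
                              channel_kind = sw$channel_kind,
                              metadata = sw$metadata)
  }
  yaml::write_yaml(meta, file.path(path, "metadata.yaml"))
  invisible(path)
}

#' Read an experiment from disk
#'
#' Counterpart of [write_experiment()]. The format is inferred from `path`
#' (directory: delimited, file: container) unless given explicitly.
#'
#' @param path Container file or delimited directory.
#' @param format `"container"`, `"delimited"`, or `NULL` to infer.
#' @return An `ephys_experiment`.
#' @export
read_experiment <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file or directory: ", path, call. = FALSE)
  if (is.null(format)) format <- if (dir.exists(path)) "delimited" else "container"
  if (format == "container") {
    x <- readRDS(path)
    if (!inherits(x, "ephys_experiment"))
      stop("parse error: ", path, " does not contain an experiment record",
           call. = FALSE)
    return(x)
  }
  meta_file <- file.path(path, "metadata.yaml")
  if (!file.exists(meta_file))
    stop("parse error: missing sidecar metadata.yaml in ", path, call. = FALSE)
  meta <- yaml::read_yaml(meta_file)
  sweeps <- lapply(names(meta$sweeps), function(fn) {
    m <- meta$sweeps[[fn]]
    if (is.null(m$sampling_rate))
      stop("validation error: sweep record ", fn, " lacks a sampling rate",
           call. = FALSE)
    d <- utils::read.csv(file.path(path, fn))
    check_time_column(d, fn)
    new_sweep(d$value, m$sampling_rate, t0 = m$t0 %||% d$time_s[1],
              channel_kind = m$channel_kind, metadata = m$metadata %||% list(),
              quiet = TRUE)
  })
  design <- if (!is.null(meta$design)) tibble::as_tibble(meta$design) else NULL
  new_experiment(sweeps, design = design)
}

check_time_column <- function(d, what) {
  if (!all(c("time_s", "value") %in% names(d)))
    stop("parse error: ", what, " must have columns time_s,value", call. = FALSE)
  if (nrow(d) >= 2 && any(diff(d$time_s) <= 0))
    stop("parse error: non-monotone time column in ", what, call. = FALSE)
  invisible(d)
}

#' Read a single delimited sweep
#'
#' Reads a two-column `time_s,value` text file and infers the sampling rate
#' from the median sample spacing.
#'
#' @param path CSV file with header `time_s,value`.
#' @param channel_kind Channel kind to assign (see [new_sweep()]).
#' @return An `ephys_sweep` with the inferred sampling rate.
#' @export
read_sweep_delimited <- function(path,
                                 channel_kind = "voltage_clamp_current") {
  d <- utils::read.csv(path)
  check_time_column(d, path)
  if (nrow(d) < 2)
    stop("validation error: cannot infer sampling rate from fewer than 2 samples",
         call. = FALSE)
  dt <- stats::median(diff(d$time_s))
  new_sweep(d$value, sampling_rate = 1 / dt, t0 = d$time_s[1],
            channel_kind = channel_kind, quiet = TRUE)
}
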