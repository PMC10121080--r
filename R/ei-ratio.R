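# Evoked excitation/inhibition ratio of individual cells from paired
# EPSC/IPSC measurements at two holding potentials.

#' Construct a paired evoked EPSC/IPSC measurement set
#'
#' EPSC peaks are recorded at a hyperpolarized holding potential (inward,
#' negative by convention) and IPSC peaks at a depolarized one (outward,
#' positive), at the same stimulation intensity, typically 5-6 repeats per
#' polarity.
#'
#' @param epsc_peaks_pA,ipsc_peaks_pA Peak amplitudes per repeat (1-10
#'   each).
#' @param cell Cell identifier.
#' @param intensity_uA Stimulation intensity shared by both polarities.
#' @return An `evoked_psc_set`.
#' @export
evoked_psc_set <- function(epsc_peaks_pA, ipsc_peaks_pA,
                           cell = NA_character_, intensity_uA = NA_real_) {
  for (v in list(epsc_peaks_pA, ipsc_peaks_pA))
    if (length(v) < 1 || length(v) > 10)
      stop("need 1-10 repeats per polarity", call. = FALSE)
  structure(list(cell = cell, epsc_peaks_pA = epsc_peaks_pA,
                 ipsc_peaks_pA = ipsc_peaks_pA,
                 intensity_uA = intensity_uA),
            class = "evoked_psc_set")
}

#' Excitation/inhibition ratio of one cell
#'
#' `|mean EPSC peak| / |mean IPSC peak|`, with peaks measured per repeat and
#' then averaged (robust to latency jitter across repeats). Undefined (NA,
#' with a warning) when the mean IPSC is zero.
#'
#' @param set An [evoked_psc_set()].
#' @return The E/I ratio (positive scalar) or `NA`.
#' @export
ei_ratio <- function(set) {
  stopifnot(inherits(set, "evoked_psc_set"))
  e <- abs(mean(set$epsc_peaks_pA))
  i <- abs(mean(set$ipsc_peaks_pA))
  if (i == 0) {
    warning("mean IPSC is 0: E/I ratio undefined", call. = FALSE)
    return(NA_real_)
  }
  e / i
}
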