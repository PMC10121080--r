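# Boltzmann-sigmoid fitting with the bottom pinned to zero, R-squared
# gating, level interpolation and shared-vs-separate curve comparison by
# the extra sum-of-squares F test.

#' Boltzmann sigmoid with zero bottom
#'
#' `y = Top / (1 + exp((v50 - x) / k))`.
#'
#' @param x Abscissa (interpulse interval in ms, or fEPSP slope in V/s).
#' @param Top Upper asymptote.
#' @param v50 Half-maximum point (units of `x`).
#' @param k Slope factor (units of `x`), > 0.
#' @export
boltzmann <- function(x, Top, v50, k) Top / (1 + exp((v50 - x) / k))

#' Fit a Boltzmann sigmoid with the bottom fixed at zero
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) of
#' `y = Top / (1 + exp((v50 - x)/k))` with deterministic initialization
#' (Top at the data maximum, v50 at the interpolated half-maximum crossing,
#' k at a tenth of the x-range) and up to three perturbed restarts on
#' non-convergence. Bounds: `Top` in (0, 2 max y], `k` in (0, x-range].
#' The goodness of fit is `R^2 = 1 - SSres/SStot` over the fitted range
#' only, and the fit is flagged `included` when `R^2 > 0.8` — the gate
#' applied before group-level analysis.
#'
#' @param x,y Data; at least 4 points within the fitted range.
#' @param fit_range_max_x Optional upper x limit (inclusive); for
#'   paired-pulse inhibition curves the early portion up to the 100 ms
#'   interval is fitted.
#' @param r2_gate Inclusion threshold on R^2 (default 0.8).
#' @return An object of class `boltzmann_fit`: `Top`, `v50`, `k`,
#'   `bottom` (always 0), `r_squared`, `ss_res`, `n`, `converged`,
#'   `included`, plus the fitted data range.
#' @export
fit_boltzmann <- function(x, y, fit_range_max_x = NULL, r2_gate = 0.8) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  if (!is.null(fit_range_max_x)) keep <- keep & x <= fit_range_max_x
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4)
    stop("need at least 4 points within the fitted range", call. = FALSE)
  if (stats::sd(y) == 0)
    stop("degenerate data: y is constant (SStot = 0)", call. = FALSE)
  xr <- diff(range(x))
  ymax <- max(y)
  half <- ymax / 2
  above <- which(y >= half)
  v50_0 <- if (length(above) && min(above) > 1) {
    i <- min(above)
    x[i - 1] + (half - y[i - 1]) * (x[i] - x[i - 1]) / (y[i] - y[i - 1])
  } else stats::median(x)
  start0 <- list(Top = ymax, v50 = v50_0, k = xr / 10)
  lower <- c(Top = 1e-9, v50 = -Inf, k = 1e-9)
  upper <- c(Top = 2 * ymax, v50 = Inf, k = xr)
  dat <- data.frame(x = x, y = y)
  try_fit <- function(st) {
    tryCatch(suppressWarnings(
      minpack.lm::nlsLM(y ~ Top / (1 + exp((v50 - x) / k)), data = dat,
                        start = st, lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
  }
  fit <- try_fit(start0)
  pert <- c(0.5, 1.5, 2)
  i <- 1
  while (is.null(fit) && i <= 3) {
    st <- list(Top = min(2 * ymax, start0$Top * pert[i]),
               v50 = start0$v50 + (pert[i] - 1) * xr / 4,
               k = min(xr, start0$k * pert[i]))
    fit <- try_fit(st)
    i <- i + 1
  }
  if (is.null(fit)) {
    res <- list(Top = NA_real_, v50 = NA_real_, k = NA_real_, bottom = 0,
                r_squared = NA_real_, ss_res = NA_real_, n = length(x),
                converged = FALSE, included = FALSE, x = x, y = y)
    class(res) <- "boltzmann_fit"
    return(res)
  }
  cf <- stats::coef(fit)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  res <- list(Top = unname(cf["Top"]), v50 = unname(cf["v50"]),
              k = unname(cf["k"]), bottom = 0,
              r_squared = r2, ss_res = ss_res, n = length(x),
              converged = TRUE, included = r2 > r2_gate, x = x, y = y)
  class(res) <- "boltzmann_fit"
  res
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<boltzmann_fit> did not converge (n =", x$n, ")\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<boltzmann_fit> Top %.4g | v50 %.4g | k %.4g | R2 %.4f | %s (n = %d)\n",
    x$Top, x$v50, x$k, x$r_squared,
    if (x$included) "included" else "excluded", x$n))
  invisible(x)
}

#' Interpolate the x positions at which fixed response levels are reached
#'
#' Closed-form inversion of the fitted sigmoid,
#' `x = v50 - k * log(Top/y - 1)`, at the requested absolute levels
#' (by default 50, 75 and 100 % of the first response for paired-pulse
#' inhibition curves). Levels at or above the fitted `Top` are unattainable
#' and reported as `NA`.
#'
#' @param fit A converged [fit_boltzmann()] result.
#' @param levels Response levels in the units of `y`.
#' @return Named numeric vector of crossings (units of `x`).
#' @export
interpolate_levels <- function(fit, levels = c(50, 75, 100)) {
  stopifnot(inherits(fit, "boltzmann_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  out <- vapply(levels, function(lev) {
    if (lev >= fit$Top) return(NA_real_)
    fit$v50 - fit$k * log(fit$Top / lev - 1)
  }, 0)
  names(out) <- paste0("x_at_", levels)
  out
}

#' Fit the EPSP-spike coupling curve
#'
#' Boltzmann fit of the population-spike amplitude against the fEPSP slope;
#' the v50 parameter (the slope at which half of the maximal spike is
#' attained) is the per-animal measure carried into group comparisons.
#'
#' @param slopes_Vps fEPSP slopes (x).
#' @param spikes_mV Population-spike amplitudes (y).
#' @inheritParams fit_boltzmann
#' @return A `boltzmann_fit`.
#' @export
fit_epsp_spike <- function(slopes_Vps, spikes_mV, r2_gate = 0.8) {
  fit_boltzmann(slopes_Vps, spikes_mV, r2_gate = r2_gate)
}

#' Compare two datasets by shared vs separate Boltzmann fits
#'
#' Extra sum-of-squares F test of the nested pair: one sigmoid fitted to the
#' pooled data (3 parameters) against separate sigmoids per dataset (6
#' parameters):
#' `F = ((SS_shared - SS_sep)/(df_shared - df_sep)) / (SS_sep/df_sep)`.
#'
#' @param x1,y1,x2,y2 The two datasets.
#' @param fit_range_max_x Optional shared fit range limit.
#' @return List with `F`, `df` (numerator, denominator), `p`, and the
#'   shared and separate fits.
#' @export
compare_curves_extra_ss <- function(x1, y1, x2, y2, fit_range_max_x = NULL) {
  f1 <- fit_boltzmann(x1, y1, fit_range_max_x)
  f2 <- fit_boltzmann(x2, y2, fit_range_max_x)
  fs <- fit_boltzmann(c(x1, x2), c(y1, y2), fit_range_max_x)
  if (!f1$converged || !f2$converged || !fs$converged)
    stop("one of the component fits failed to converge", call. = FALSE)
  n <- fs$n
  ss_sep <- f1$ss_res + f2$ss_res
  df_sep <- n - 6
  df_sh <- n - 3
  if (df_sep <= 0) stop("too few points for the comparison", call. = FALSE)
  Fstat <- max(0, ((fs$ss_res - ss_sep) / (df_sh - df_sep)) /
                 (ss_sep / df_sep))
  list(F = Fstat, df = c(df_sh - df_sep, df_sep),
       p = stats::pf(Fstat, df_sh - df_sep, df_sep, lower.tail = FALSE),
       shared = fs, separate = list(f1, f2))
}
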