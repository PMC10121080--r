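---
title: "Quantifying dentate granule cell electrophysiology with dgephys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dentate granule cell electrophysiology with dgephys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgephys)
```

dgephys implements a complete quantification chain for cellular and network
electrophysiology of the hippocampal dentate gyrus: postsynaptic-current
event detection in voltage-clamp sweeps, intrinsic-excitability and
action-potential feature extraction from current steps, evoked
field-potential analysis (input-output curves, paired-pulse
facilitation/inhibition, LTP normalization), Boltzmann-sigmoid
quantification of EPSP-spike coupling and paired-pulse inhibition, and the
statistics layer such studies report. Because raw recordings of this kind
are rarely deposited, the package ships a synthetic-data module that
generates sweeps and whole two-group studies with known ground truth, so
every analysis stage is benchmarked against a generative model rather than
against another analysis tool. This vignette explains the models,
conventions, defaults and their limitations.

## Data model

The universal input is the *sweep* (`new_sweep()`): one episode of signal
with a sampling rate (default 10 kHz, the usual digitization rate), a
channel kind (voltage-clamp current in pA, current-clamp voltage in mV, or
field potential in mV), a protocol, and free-form metadata. Sweeps are
grouped into *experiments* with a subject-level design table. Experiments
round-trip bit-exactly through a native serialized container
(`write_experiment()` / `read_experiment()`), and a delimited-text fallback
(one `time_s,value` CSV per sweep plus a YAML sidecar) keeps everything
inspectable with ordinary tools. All times are seconds internally;
interpulse intervals are expressed in milliseconds at API boundaries, the
unit in which they are reported in the field. No reader for proprietary
acquisition formats is included; records must be exported to one of the two
supported containers first.

Protocols are first-class: `build_step_protocol(-100, 490, 10)` enumerates
the standard granule-cell F-I family (sixty 1-s square pulses in 10-pA
increments), and `build_tbs_protocol()` produces the theta-burst LTP
induction pattern (six series, separated by 20 s, of six trains, separated
by 0.2 s, of six pulses at 400 Hz; 216 stimulus times with 2.5 ms
within-train spacing).

## Synthetic data as ground truth

### Postsynaptic-current traces

`simulate_psc_trace()` builds a voltage-clamp trace as a homogeneous
Poisson train of synaptic events convolved with a biexponential kernel
$k(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r}$ plus white Gaussian noise.
Event times are quantized to the sampling grid and the kernel is normalized
to unit peak *on that grid*, so the drawn lognormal amplitudes are exactly
the baseline-to-peak amplitudes an ideal detector should report. Defaults
($\tau_r$ = 1 ms, $\tau_d$ = 10 ms, mean amplitude 20 pA, noise 2 pA)
mimic AMPA-receptor sEPSCs in granule cells. The noise is white by design;
real recordings add line hum, seal drift and biological burstiness that the
generator does not emulate, so detector benchmarks on this synthetic ground
truth bound what the algorithm itself can do, not what any recording rig
will deliver.

### The granule-cell neuron model

`simulate_fi_sweeps()` integrates an adaptive leaky integrate-and-fire
neuron with a slow inactivation gate:

$$C\,\dot V = -g_L (V - E_L) + I(t) - w, \qquad
  \dot w = -w/\tau_w, \qquad
  \dot h = (h_\infty(V) - h)/\tau_h,$$

with $w \mathrel{+}= b$ and $h \mathrel{*}= (1 - d)$ at each spike, and
$h_\infty(V) = 1/(1+e^{(V - v_h)/k_h})$. A spike is emitted when
$V \ge V_{th}$ while $h \ge h_{block}$; when $h$ falls below $h_{block}$
spiking stops and the voltage settles into a capped depolarized plateau —
depolarization block. This is the simplest model exhibiting all the
phenotypes the intrinsic module measures, with closed-form checks in the
reduced limits: with adaptation and block disabled, the rheobase is exactly
$g_L (V_{th} - E_L)$ and sub-rheobase steps settle at the ohmic deflection
$I/g_L$.

Defaults describe a plausible mature granule cell: $g_L$ = 4 nS and $C$ =
80 pF (input resistance 250 M$\Omega$, membrane time constant 20 ms),
$E_L$ = $-80$ mV, $V_{th}$ = $-55$ mV, rheobase 100 pA. The adaptation
increment $b$ = 60 pA with $\tau_w$ = 150 ms gives an F-I slope of roughly
0.11 Hz/pA, and the gate constants ($d$ = 0.09, $\tau_h$ = 150 ms,
$h_{block}$ = 0.7) were set from the steady-state relation
$d \cdot r \cdot h_{block} = (h_\infty - h_{block})/\tau_h$ so that block
sets in near 30 Hz — i.e. around 370-400 pA — reproducing peak firing
around 30 Hz followed by an abrupt, spikeless plateau at stronger
injections. Integration uses a fixed-step explicit scheme at dt = 0.01 ms
(ten times finer than the digitization); larger steps are rejected. A
1-nV threshold tolerance absorbs the floating-point stall of the
asymptotic approach to threshold at exactly-rheobase currents.

### Field-potential studies

`simulate_field_experiment()` emulates the in vivo two-group design at the
table level: per animal, an input-output series (fEPSP slope saturating
with intensity via a Hill curve; population spike coupled to slope through
a Boltzmann sigmoid, floored at a detection threshold) and a paired-pulse
inhibition series (second population spike as percent of the first,
following a ground-truth Boltzmann of the interpulse interval). The default
intensity grid is the 20-level 30-800 µA series and the default IPI grid
the 11-level 10-100 ms series. Animal-level variation enters through the
PPI v50 only; Top and slope are shared. This matches the structure in which
the group contrast of interest is a pure v50 shift, and keeps the
between-animal model identifiable from the small per-animal curves.

Defaults: Top = 120 %, $k$ = 5 ms, v50 = 41.3 ms (WT) and 45.8 ms (KO) —
the group means such studies report — with 5 % multiplicative measurement
noise. The between-animal v50 standard deviation defaults to 4 ms. The
observed per-animal spread in real cohorts (SEM near 1.5 ms at n = 17,
i.e. a total SD near 6 ms) mixes true between-animal variance with
fit/measurement error; assigning 4 ms to the former and letting the
5 % curve noise contribute the rest gives a positive-control study with
roughly 85 % power to detect a 4.5 ms shift at n = 17/16, whereas putting
the full 6 ms into between-animal variance would leave the design at
roughly 55 % power (the borderline regime in which a single real cohort
lands). A synthetic validation study should detect the effect it was built
around reliably, so the 4 ms decomposition is the default; both knobs are
exposed in `field_truth()`.

`synth_evoked_sweep()` additionally synthesizes waveform-level evoked
responses (stimulus artifact, alpha-function fEPSP, Gaussian
population-spike trough) so the slope and amplitude operators can be
exercised end to end.

## Event analysis

Traces are low-pass filtered with a fourth-order elliptic filter (cutoff
1 kHz, 0.1 dB passband ripple, 40 dB stopband) applied forward-backward
for zero phase. The implementation pads by odd reflection and initializes
the filter at steady state, so constants pass through unchanged and event
peak times shift by well under 0.2 ms. The filter is rescaled to exactly
unit DC gain; without that, an even-order elliptic design attenuates DC by
the passband ripple.

Detection replaces an interactive commercial detector with deterministic
rules, so results are reproducible and benchmarkable:

* candidate peaks are local extrema of the polarity-rectified trace;
* the local baseline is the higher of (a) the median over the 10 ms window
  ending 3 ms before the peak and (b) the trough separating the candidate
  from the previous accepted event; the amplitude is the baseline-to-peak
  increment and must reach the threshold (3 pA for EPSCs, 10 pA for
  IPSCs);
* a persistence criterion — the mean deflection over the 2.5 ms after the
  peak must stay above 60 % of the amplitude — separates synaptic events,
  which decay over milliseconds, from band-limited noise blips;
* accepted events are separated by at least a 2 ms refractory interval.

The trough-referenced baseline is what rejects secondary ripples riding on
an event's decay while keeping genuinely stacked events, whose own rise is
a fresh deflection. On synthetic traces at 10 Hz with amplitudes at ten
times the noise SD, the detector reaches recall and precision above 0.95;
at 20 Hz recall drops toward 0.93 because a growing fraction of event
pairs coincide within the refractory window and are physically merged in
the trace — no threshold detector can split them, and the benchmark counts
them as misses.

Kinetics follow explicit conventions, configurable because interactive
tools rarely document theirs: rise time is 10-90 % of the baseline-to-peak
amplitude on the rising limb, decay time is peak to $1/e$ of the amplitude
on the falling limb, both with linear interpolation between samples. A
decay interrupted by the next event's onset is flagged unresolved and
excluded from per-cell means. Cells qualify for group analysis at a
minimum of 100 events (`summarize_cell()`).

## Intrinsic excitability

Spikes in current-clamp sweeps are voltage peaks above 0 mV whose upstroke
exceeds 20 V/s, with a 1 ms refractory period — thresholds chosen to match
common practice for granule-cell waveforms, and configurable. From the
per-step spike trains, `fi_curve()` assembles the F-I table (rate =
count/duration), the rheobase (smallest step current with at least one
spike), the maximum rate and its current (ties broken toward the lowest
current), and the ISI adaptation ratio (first/last interspike interval,
evaluated at the maximum-rate step; undefined below three spikes).

Depolarization block is classified per step: at least one spike whose last
occurrence precedes 0.9 s within the 1 s step. A cell is flagged as
entering block when any step at or above rheobase is blocked, and the
block current is the lowest blocked step. Note that this rule also marks
near-rheobase steps of strongly adapting cells, where interspike intervals
stretch beyond the criterion; the per-cell aggregation behind published
contingency tables is not standardized, so the criterion and the
aggregation are both parameters rather than constants.

Action-potential prominence is interpreted as topographic peak prominence
(peak minus the higher flanking minimum, bounded by neighbouring spikes),
and half-width as the width at half-prominence with linear interpolation —
the standard signal-processing readings of those terms; absolute values
under other conventions (e.g. threshold-referenced amplitude) will differ.
Flat-topped peaks are flagged as clipped. Input resistance is the
least-squares slope of the steady-state voltage deflection (mean over the
last 200 ms of the step, avoiding sag transients, minus the pre-step
baseline) against current over the $-100$ to $-10$ pA steps; resting
potential is the mean of a pre-stimulus baseline of at least 100 ms.

## Field-potential analysis

The fEPSP slope is the steepest 0.5 ms sliding-window regression slope
between response onset and the first local peak of the deflection (the
fEPSP peak when no population spike is present, the spike-onset flank when
one is), after blanking 1 ms of stimulus artifact. A windowed estimator is
necessarily a lower bound on the instantaneous maximum slope: for an
alpha-function fEPSP with $\tau$ = 2 ms the analytic maximum $A e/\tau$ is
approached only as the window shrinks toward the sampling interval, and
the tests assert both the windowed-oracle identity at 0.5 ms and the
convergence to $A e/\tau$ at 0.1 ms. Absolute slopes are therefore
convention-dependent; relative measures (percent of baseline, group
ratios) are not.

The population-spike amplitude uses the tangent method: the vertical
distance from the spike trough to the line joining the two flanking
positive peaks, which is robust to slow-wave tilt. Both flanking peaks
and the tangent offset must exceed five times the pre-stimulus noise SD,
giving a defined "first population spike appeared" operator for
input-output curves; otherwise the amplitude is 0. Both operators are
DC-invariant and scale linearly with the signal.

Paired-pulse ratios are `100 * second/first`, on slopes for facilitation
and spike amplitudes for inhibition (0 % when the second spike is absent;
undefined and flagged when the first response is 0). LTP time courses are
normalized to the mean of the 10 min pre-induction baseline and summarized
over the 0-10 and 50-60 min windows.

## Boltzmann fits and curve comparison

EPSP-spike coupling and paired-pulse inhibition are quantified with the
Boltzmann sigmoid $y = \mathrm{Top}/(1 + e^{(v_{50} - x)/k})$, bottom
pinned to zero. Fitting is bounded Levenberg-Marquardt least squares with
deterministic initialization (Top at the data maximum, v50 at the
interpolated half-maximum crossing, k at a tenth of the x-range), bounds
Top $\in (0, 2\max y]$ and $k \in (0, \text{range}]$, and up to three
perturbed restarts on non-convergence. $R^2$ is computed on the fitted
range only, and fits with $R^2 \le 0.8$ are excluded from group analysis.
For PPI curves the fitted range runs up to and including the 100 ms
interval. Level crossings use the closed-form inversion
$x = v_{50} - k \ln(\mathrm{Top}/y - 1)$; a level at or above the fitted
Top is unattainable and reported missing (and excluded from group means)
rather than extrapolated.

Two datasets are compared by the extra sum-of-squares F test between one
shared fit (3 parameters) and separate fits (6 parameters):
$F = \frac{(SS_{sh} - SS_{sep})/3}{SS_{sep}/(n-6)}$. Nesting guarantees
$F \ge 0$. The test assumes homoscedastic errors; under multiplicative
noise its null p values are anticonservative, which the calibration tests
make explicit by simulating the additive-noise null.

## Statistics layer

`compare_groups()` mirrors the decision tree used in such studies:
normality screening, then Welch's t test for normal data and the
Mann-Whitney test otherwise, reporting the estimated difference (oriented
group1 $-$ group2, i.e. WT $-$ KO in the standard design) with the 95 %
CI of the difference. Specifics:

* **D'Agostino-Pearson omnibus test** (`dagostino_pearson()`):
  $K^2 = Z^2_{skew} + Z^2_{kurt}$ against $\chi^2_2$, implemented from the
  original transformations and verified to 8 digits against an independent
  implementation. It requires $n \ge 20$, the smallest size at which the
  kurtosis transformation is trustworthy; smaller samples are routed to
  the nonparametric branch with a note.
* **Welch's t** accepts raw samples or `(mean, SEM, n)` summaries, so
  printed cohort tables can be re-analyzed; the Welch-Satterthwaite df and
  the CI of the difference are computed identically either way.
* **Mann-Whitney** (`mann_whitney()`): for $n_1+n_2 \le 25$ the two-sided
  p value is exact, from the full permutation distribution of the midrank
  sum enumerated by a shift algorithm with ties as they stand (bit-identical
  to the reference implementation in the tie-free case, and still exact
  with ties, where the reference falls back to an approximation). The
  estimate is the Hodges-Lehmann median of pairwise differences with the
  exact-quantile CI; above 25, a mid-rank normal approximation with tie
  correction is used. Exact tests are discrete: at $n = 8/8$ the
  attainable size below 0.05 is 0.0499, but at other sizes it can be as
  low as 0.04.
* **Chi-squared independence** is Pearson's statistic without continuity
  correction — the convention that reproduces textbook 2x2 values from
  small cohorts; corrected values would differ.
* **Two-way (RM) ANOVA** (`two_way_anova()`): classical repeated-measures
  decomposition on complete data; with missing cells, a compound-symmetry
  mixed model (random subject intercept) fitted by REML with Satterthwaite
  degrees of freedom, which coincides with the RM-ANOVA F statistics on
  complete balanced data (asserted to 1e-6 in the tests). Bonferroni
  post-tests compare groups at each level of the within factor with the
  multiplier equal to the number of comparisons; `bonferroni()` is
  $\min(1, m\,p)$ with an explicit family size.

## Pipeline and reproducibility

`run_study()` chains simulation, per-animal PPI fitting, the $R^2$ gate
and the group comparisons into one call, writing per-stage CSVs, a config
snapshot and a manifest with MD5 checksums. All randomness flows from one
seed; reruns are bit-identical. Configuration keys are validated by name
against `default_study_config()`. `scripts/acceptance.R` recomputes the
package's headline quantities from scratch and writes them as JSON;
`scripts/run_study.R` is a thin command-line wrapper over `run_study()`.

## Problem sizes and what the tests show

The test-suite defaults were chosen to characterize each stage tightly at
desk scale: 60 s detection benchmarks over 20 seeds, 200-replicate fit
recovery, 2000-replicate type-I calibrations, and 100-replicate
end-to-end study recovery at the full n = 17/16 design. Passing them
demonstrates that the chain is internally correct against its generative
models — it does not certify performance on real recordings, whose noise
is not white, whose events are not a homogeneous Poisson process, and
whose cells are not integrate-and-fire units. The synthetic module is a
test harness and a power-analysis tool, not a claim about biology.

Known limitations, beyond those noted above: no template-matching or
deconvolution detector (merged near-coincident PSCs are not split); no
sag, rebound or phase-plane threshold measures; no conductance-based
neuron model or network simulation; no current-source-density analysis;
Bonferroni is the only multiplicity procedure; and no reader for
proprietary acquisition file formats.
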