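---
title: "Methods: auditory tuning, spike-train discriminability and population decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: auditory tuning, spike-train discriminability and population decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freqdisc)
```

`freqdisc` implements the analysis chain of a Go/No-Go auditory
frequency-discrimination study: behavioral psychophysics, tone-evoked
multi-unit tuning analysis, spike-train discriminability, and a Bayesian
population decoder that links the measured tuning parameters to predicted
discrimination performance. This vignette is the package's own account of
the methods: the models, their assumptions, the tunable parameters, the
numerical choices, and what the synthetic-data module does and does not
capture.

## Recordings model and the evoked-response criterion

Spiking data are organised as a *tuning matrix*: for one multi-unit
cluster, a grid of 20 log-spaced tone frequencies (1–64 kHz) crossed with
ten intensities (0–90 dB SPL in 10-dB steps), each cell holding 30 repeated
spike trains from 40 ms before to 100 ms after tone onset. Peristimulus
time histograms use half-open 5-ms bins; counts are averaged across trials.

A cell counts as *sound-evoked* when some bin in the 0–40 ms window exceeds
the mean pre-stimulus (−40–0 ms) bin count by four pre-stimulus standard
deviations. Two numerical choices matter here:

* **SD floor.** The empirical SD of eight sparse Poisson bins is a noisy
  underestimate and is exactly zero for a silent baseline, where a 4-SD
  rule is undefined. `detect_evoked()` therefore floors the empirical SD
  by the Poisson SD of a trial-averaged bin at the pre-stimulus mean rate,
  with an absolute floor of `1/n_trials` counts. Without the floor, a
  baseline that happens to look quiet in the pre-window turns a handful of
  ordinary baseline spikes into a "response"; with it, the per-cell
  false-positive rate at realistic multi-unit rates is well below 1% while
  recall for true responses stays near 1 (this is asserted in the test
  suite).

* **Vertical support.** Frequency-response areas are contiguous in level:
  if a tone drives a unit at some intensity it also does so a step louder.
  Thresholds and bandwidth rows therefore require the cell one level step
  above to pass the criterion as well (the top row is exempt). This is the
  package's automatic stand-in for the manual curation of "discernible
  tuning curves" that recording studies apply by eye: it rejects isolated
  supra-criterion cells, which are statistical flukes of the 4-SD rule,
  at the cost of being one step conservative for units whose response
  truly exists at exactly one intensity (which a V-shaped FRA does not
  produce).

## Rate-level functions

The CF-column rate-level function (driven rate versus intensity at the
unit's characteristic frequency) is fit with a six-parameter
logistic-plus-Gaussian curve,

$$y(x) = a + \frac{d - a}{1 + e^{(b - x)/c}} + e\,
  e^{-\,(x - f)^2 / (2c^2)},$$

with lower asymptote $a$, upper asymptote $d$, inflection $b$, shared
slope/width parameter $c$, and Gaussian amplitude $e$ and centre $f$. One
symbol $c$ serves both the logistic slope and the Gaussian width, which is
what keeps the model at six parameters while covering monotone, saturating
and non-monotone shapes. Derived quantities: response minimum $a$ and
maximum $d$; the threshold is the lowest level (1-dB evaluation grid) where
the fitted curve reaches $a + 0.2\,(d-a)$, i.e., 20% of the range; the gain
is the maximum slope of the fitted curve over its ascending portion,
evaluated numerically because the composite curve has no closed-form
maximum slope. Fits with RMSE at or above 100 spikes/s are excluded from
downstream analysis.

Least squares is run with bounded Levenberg–Marquardt
(`minpack.lm::nlsLM`) from a ladder of starts: a logistic-only stage first,
then composite starts including one seeded from the logistic residuals
(Gaussian centre at the residual peak). The best RMSE wins; exact ties go
to the smallest $c$. Three guards keep the flexible composite from chasing
noise, all derived from what the parameters *mean* rather than from the
data at hand: $a$ and $d$ are boxed near the observed floor and peak
(they are reported as response minimum/maximum, so a fitted "maximum" of
three times the observed peak is meaningless); candidates with $d < a$
(inverted asymptote roles) are discarded; $e$ may not exceed the observed
dynamic range and $c$ may not be finer than a third of the level-grid
step, since sub-grid needles cannot be evidenced by 10-dB-spaced data.
On noiseless curves the fitter recovers all six parameters to better than
1%; with Poisson noise at 30 trials the derived threshold is recovered
within 5 dB for roughly nine units in ten — that residual scatter is the
intrinsic statistics of an unweighted least-squares fit at these counts,
not an optimiser artefact.

## Frequency-response-area metrics

Per frequency, the threshold is the lowest (supported) evoked intensity;
the characteristic frequency (CF) is the frequency with the minimum
threshold. Ties at the minimum threshold are broken by the larger
evoked-window rate at threshold, then by the lower frequency, with a tie
flag. Bandwidth at +10/+20/+30/+40 dB above the minimum threshold spans the
first to the last evoked cell of that intensity row — gaps inside the row
are allowed — and $Q = \mathrm{CF}/(f_{hi} - f_{lo})$ with linear-kHz
bandwidth, since only the linear difference makes $Q$ a dimensionless
sharpness index. Rows that leave the tested grid are unresolved; rows
landing between tested intensities fall back to the nearest tested row
below, flagged. When the evoked span excludes the CF (non-V shapes) the
package warns and continues.

## Rate-independent SPIKE-distance

Discriminability between spike-train blocks uses the rate-independent
SPIKE-distance. For each train in a pair, the instantaneous spike-timing
difference at time $t$ is
$S_n(t) = (\Delta t_P\, x_F + \Delta t_F\, x_P)/x_{ISI}$, built from the
distances of the preceding/following spikes to the nearest spikes of the
other train, interpolated by the position of $t$ inside the current
interspike interval. The profile is
$S'(t) = (S_1(t) + S_2(t)) / (2\,\langle x_{ISI}(t)\rangle_n)$, the
unweighted average of the two train contributions normalised by the mean of
the two instantaneous ISIs. The first-power normalisation is what makes
the measure dimensionless and invariant under a common rescaling of all
spike times and the window — the defining property of the rate-independent
variant, and an invariant the test suite asserts to $10^{-6}$. Auxiliary
spikes at the window edges define every term near the boundaries. $S'$ is
piecewise linear between spikes of either train, so the time integral
$D = \frac{1}{T}\int S'\,dt$ is computed exactly (trapezoid per segment) in
compiled code; a dense-grid brute-force evaluator kept in the test suite
agrees to $10^{-3}$. The multi-train distance averages all pairwise
profiles, and since averaging commutes with integration it equals the mean
of the pairwise distances.

For the tuning-vs-discriminability analysis, the 30 trains at the unit's
CF (at 40 dB above its minimum threshold) are compared with the 30 trains
at each other frequency of that row: the 30×30 cross-block distance matrix
is averaged and reported as $\Delta$ relative to the mean within-CF pair
distance, so $\Delta = 0$ at zero separation by construction. Pooling the
60 trains into one multi-train distance is available as a switch, but the
pooled value mixes in the neighbour block's *internal* similarity — sparse
blocks are internally similar, which masks exactly the distance dependence
the comparison is after — so the cross-block average is the default.

## The population decoder

The decoder models a tonotopic sheet of 640 neurons with preferred
frequencies equally log-spaced over 1–64 kHz. All neurons share the mean
tuning curve $f(x) = A\,e^{-(x-B)^2/\sigma^2} + N$ on the octave axis
($x = \log_2$ frequency), exactly as printed with $\sigma^2$ (no factor 2)
in the exponent; a conventional $2\sigma^2$ form is available as a switch.
The width $\sigma$ comes from the measured bandwidth: the tuning edge —
the first divergence of the response from baseline — is identified with
the 99% point of the Gaussian CDF written via the error function, and
$\sigma$ is obtained by root-finding that relation (the quantile is
solved, not hard-coded). A heterogeneous per-neuron parameter option
exists, but the homogeneous mean-curve population is the default because
the summaries feeding it are population means.

Each trial draws one Poisson spike count per neuron with mean equal to the
tuning-curve value integrated over the readout count window; draws below
90% of the neuron's baseline count are not propagated and arrive at the
readout as zero. Classification is Bayesian with the *matching* censored
likelihood — all sub-threshold probability mass on zero, the Poisson pmf
above — so the decoder assumes exactly the generative model and nothing
else; exact posterior ties are broken by a fair coin. On populations of
two or three neurons the decisions are checked against exhaustive
enumeration of all outcome vectors.

The readout count window (default 2 ms) is the one deliberately
interpretive constant in the decoder. Per-trial activity must be a count
for a Poisson draw to make sense, and the window sets how much information
each trial carries. With tens-of-milliseconds windows a 640-neuron
population discriminates even 1/12-octave steps essentially perfectly —
error curves are flat at zero and carry no information about tuning
differences. A 2-ms window reads out the temporally precise onset
transient of the evoked response; per-trial counts are then well below one
spike per neuron and the error rate spans the behaviorally meaningful
range, falling from chance at zero separation towards zero across one
octave, which is the regime in which tuning-parameter differences are
visible at all.

Discrimination experiments present each Go tone (4, 8, 16, 32 kHz) against
No-Go tones ±1 to ±12 twelfth-octaves away, classify balanced Go and No-Go
trial blocks, and report the balanced error (mean of miss and false-alarm
rates; a No-Go-only error mode is a switch). The full protocol is 10,000
trials per condition repeated 15 times; tests and the acceptance script run
1,000 trials and 5 runs, which leaves the binomial noise on a band-mean
error near $10^{-3}$ — far below the effects examined. The
parameter-permutation experiment crosses spontaneous rate, evoked
amplitude and tuning width between a WT-like and a KO-like summary (eight
combinations) over the 1/3–2/3-octave band (offsets of 4–8 twelfths, where
behavioral genotype differences concentrate); one-axis sweeps scale a
single parameter over a multiplier grid.

## Synthetic data: what it emulates, and what it does not

The generator exists so that every stage has ground truth. A unit is a
V-shaped FRA: no response below a minimum threshold; above it, a
responsive band centred on the CF whose half-width grows linearly with
level from a quarter-octave tip, reaching a configured full bandwidth 40 dB
above threshold. Inside the band the evoked rate tapers linearly from the
peak at CF to half the peak at the band edge, so edge cells remain
detectable and measured bandwidths track generative ones. Trials are
inhomogeneous Poisson: baseline rate throughout the window, plus an evoked
rate during a 25-ms interval at 15-ms latency of which half is concentrated
in a 2-ms onset transient. The onset term models the temporal precision of
real tone-evoked cortical onsets; without any cross-trial timing
reliability a rate-independent timing metric has nothing to anchor the
within-CF baseline to, and the Δ-distance analysis degenerates.

Defaults describe multi-unit clusters, which pool several single units:
baseline 12 spikes/s, peak evoked rate 100 spikes/s, tuning-tip half-width
0.25 octaves, bandwidth at +40 dB near 2.4 octaves. Regimes scale these:
the KO-cortex-like regime multiplies spontaneous rate by 1.5, evoked rate
by 1.3 and bandwidth by 1.4 (directions from the physiology; magnitudes
are fixture choices), and midbrain-like regimes leave all three at 1.

Behavioral sessions come from an equal-variance Gaussian observer with a
fixed response criterion: on a Go trial at level $L$ the response
probability is $\Phi(d'(L) - \lambda)$ and on a catch trial
$\Phi(-\lambda)$, with $d'(L)$ a logistic function of level and $\lambda$
set from the false-alarm floor. A symmetric ±d'/2 placement around a
roving criterion was considered and rejected: it makes the catch-trial
false-alarm probability depend on a tone level that a catch trial does not
have, and breaks the property that the analysis stage recovers the
generative $d'$ exactly in expectation — which is the point of a
generator. Discrimination sessions are 50:50 Go/No-Go with a sigmoidal
false-alarm curve in octave distance.

Deliberately absent: spike-train autocorrelation and refractoriness,
adaptation across trials, correlated noise across units, anesthesia state
drift, reaction-time structure, and any learning dynamics in behavior.
Passing tests therefore demonstrate that the analysis chain is correct and
directionally faithful under Poisson statistics with reliable onsets; they
do not certify performance on data whose failure modes live in those
omitted features.

## Problem sizes and reproducibility

All stochastic stages derive per-stage seeds from one master seed
(`derive_seed()`), so cohorts, sessions and decoder runs are
bit-reproducible. The test suite and the acceptance script use reduced but
statistically adequate sizes chosen once: 50 parameter draws for fit
recovery, 100 randomized train pairs against the brute-force oracle,
12-unit cohorts per regime for the tuning and discriminability directions,
20 behavioral sessions, and 1,000-trial × 5-run decoder experiments. The
spike-train analyses use the 0–100 ms post-onset span; psychophysics
defaults (300 trials, 30% catch rate, levels 10–60 dB in 5-dB steps)
mirror a one-hour operant session.

## Known limitations

* The 4-SD evoked criterion is a per-cell test with no multiplicity
  control; the vertical-support rule absorbs most but not all false
  positives, and bandwidths at the lowest suprathreshold row remain
  quantisation-limited on a 20-step frequency grid.
* The RLF threshold at 30 trials carries an intrinsic ±2–3 dB statistical
  scatter; about one unit in ten lands outside ±5 dB. Comparisons between
  groups should use the fitted curves, not single-unit thresholds.
* The decoder's absolute error rates depend on the readout count window,
  which is not experimentally constrained; only directions and relative
  comparisons between parameter sets are interpretable.
* `fa_by_octave_band()` pools No-Go tones above and below the Go frequency
  by absolute octave distance (side is kept as metadata), which assumes
  symmetric discrimination.
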