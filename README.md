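# freqdisc

Analysis toolkit for auditory Go/No-Go frequency-discrimination studies
that pair operant psychophysics with tone-evoked extracellular recordings.
It is aimed at auditory neuroscientists who need a tested, reproducible
version of the full chain from spike tables and trial logs to the summary
quantities those studies report:

* **Psychophysics** — hit/false-alarm/correct-rejection rates, d′
  psychometric curves with a d′ = 1.5 detection threshold, and false-alarm
  rates binned by tonal distance from the Go tone (per-1/12-octave curve
  and near/middle/far 1/3-octave bands).
* **Evoked responses** — peristimulus time histograms (5-ms bins) and a
  4-SD evoked-response criterion against pre-stimulus activity.
* **Rate-level functions** — the six-parameter logistic-plus-Gaussian
  model
  `y(x) = a + (d − a)/(1 + exp((b − x)/c)) + e·exp(−(x − f)²/(2c²))`,
  with derived response minimum/maximum, 20%-of-range threshold, gain
  (maximum ascending slope) and an RMSE < 100 admission filter.
* **Frequency response areas** — characteristic frequency (CF), minimum
  threshold, bandwidths 10–40 dB above threshold and Q-values
  (CF / bandwidth).
* **Spike-train discriminability** — the rate-independent SPIKE-distance,
  `S′(t) = (S₁(t) + S₂(t)) / (2⟨x_ISI(t)⟩)`, integrated piecewise-exactly
  in compiled code, with the Δ-distance-versus-octave-from-CF analysis over
  30-train blocks.
* **Population decoding** — 640 Gaussian-tuned neurons
  (`f(x) = A·exp(−(x−B)²/σ²) + N` on the octave axis, σ solved from the
  measured bandwidth via the 99% point of the Erf form of the Gaussian
  CDF), a censored-Poisson readout (draws below 90% of baseline are not
  propagated), Bayesian Go/No-Go classification, error-rate curves over
  ±1 octave in 1/12-octave steps, parameter-permutation experiments and
  one-axis parameter sweeps.
* **Synthetic data** — seeded generators for V-shaped tuning matrices
  (inhomogeneous Poisson with a precise onset transient) under WT-like and
  KO-like regimes, and for behavioral sessions from an equal-variance
  Gaussian observer, so every stage is testable without animal data.

## Worked example

```r
library(freqdisc)

# simulate one wild-type-like multi-unit and analyze it
params  <- unit_gen_params(cf = 8, min_threshold = 20)
mat     <- gen_tuning_matrix(params, seed = 42)
metrics <- extract_fra_metrics(mat)
metrics
#> <fra_metrics> unit u1: CF 8.93 kHz, threshold 20 dB, Q40 0.66

fit <- fit_rlf(build_cf_rlf(mat, metrics$cf))
fit
#> <rlf_fit> a=9.97 b=15.6 c=3.3 d=66.59 e=40.67 f=84.6 rmse=4.81 thr=11 dB gain=7.315

dd <- delta_distance_vs_cf(mat, metrics)
subset(dd, octave_distance >= 0 & octave_distance < 1.1,
       c(freq_khz, octave_distance, delta_distance))
#>    freq_khz octave_distance delta_distance
#> 11   8.9253          0.0000         0.0000
#> 12  11.1092          0.3158         0.0018
#> 13  13.8276          0.6316         0.0067
#> 14  17.2110          0.9474         0.0048
```

The unit's CF is recovered within one grid step of the generative 8 kHz
and the threshold exactly; the rate-level fit (RMSE 4.8 spikes/s, well
under the admission cutoff) gives a response range of about 10–67 spikes/s
with its threshold interpolated below the first responsive tested level;
and the spike-train dissimilarity of neighbouring frequency blocks grows
with octave distance from the CF.

```r
# decoder: wild-type-like vs broadened/noisier population, 1/3-2/3-octave band
wt <- tuning_summary(A = 100, sigma = sigma_from_bandwidth(2.4),
                     N_base = 12, label = "WT")
ko <- tuning_summary(A = 130, sigma = sigma_from_bandwidth(3.36),
                     N_base = 18, label = "KO")
res_wt <- run_discrimination_experiment(build_population(wt),
                                        offsets = c(-8:-4, 4:8),
                                        n_trials = 1000, n_runs = 3, seed = 1)
res_ko <- run_discrimination_experiment(build_population(ko),
                                        offsets = c(-8:-4, 4:8),
                                        n_trials = 1000, n_runs = 3, seed = 1)
c(WT = mean(band_error(res_wt, c(0, Inf))$error_rate),
  KO = mean(band_error(res_ko, c(0, Inf))$error_rate))
#>     WT     KO
#> 0.0226 0.0263
```

The population with broadened tuning and elevated spontaneous rate makes
about 16% more errors in the intermediate band where behavioral
discrimination deficits concentrate.

End-to-end runs (simulate → analyze → decode → report) are orchestrated by
`run_pipeline()` with a YAML-configurable `default_config()`; see the
methods vignette (`vignettes/frequency-discrimination-pipeline.Rmd`) for
the models, parameter meanings and numerical choices.

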