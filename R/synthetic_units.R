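#' Generative parameters for one synthetic unit
#'
#' Encodes a V-shaped frequency-response area: no evoked response below
#' `min_threshold`; above it the responsive frequency band is centred on `cf`
#' with half-width (in octaves) growing linearly with level at `1/v_slope`
#' octaves per dB. Within the band the evoked rate tapers linearly from
#' `peak_evoked_rate` at CF to half the peak at the band edge, so edge cells
#' remain detectable and the measured bandwidth tracks the generative one.
#'
#' @param cf characteristic frequency (kHz).
#' @param baseline_rate spontaneous rate (spikes/s) throughout the window.
#' @param peak_evoked_rate added evoked rate at CF (spikes/s) during the
#'   evoked interval.
#' @param min_threshold lowest responsive level (dB SPL).
#' @param bw_octaves_at_40db full bandwidth (octaves) 40 dB above threshold.
#' @param tip_halfwidth half-width of the tuning-curve tip at threshold
#'   (octaves); multi-unit clusters pool several single units, so the tip has
#'   a realistic finite width (default a quarter octave).
#' @param v_slope dB of level per octave of half-width growth above the tip;
#'   defaults so that the full width 40 dB above threshold equals
#'   `bw_octaves_at_40db`.
#' @param latency evoked-response onset (ms after stimulus onset).
#' @param evoked_duration evoked-response duration (ms).
#' @return an object of class `unit_gen_params`.
#' @export
unit_gen_params <- function(cf, baseline_rate = 12, peak_evoked_rate = 100,
                            min_threshold = 20, bw_octaves_at_40db = 2.4,
                            tip_halfwidth = 0.25,
                            v_slope = 80 / (bw_octaves_at_40db -
                                              2 * tip_halfwidth),
                            latency = 15, evoked_duration = 25) {
  stopifnot(baseline_rate >= 0, peak_evoked_rate >= 0,
            bw_octaves_at_40db > 0, tip_halfwidth >= 0, v_slope > 0)
  if (bw_octaves_at_40db <= 2 * tip_halfwidth)
    stopf("bw_octaves_at_40db must exceed twice tip_halfwidth")
  structure(list(cf = cf, baseline_rate = baseline_rate,
                 peak_evoked_rate = peak_evoked_rate,
                 min_threshold = min_threshold,
                 bw_octaves_at_40db = bw_octaves_at_40db,
                 tip_halfwidth = tip_halfwidth, v_slope = v_slope,
                 latency = latency, evoked_duration = evoked_duration),
            class = "unit_gen_params")
}

#' Generative tuning half-width at a stimulus level
#'
#' @param params a [unit_gen_params].
#' @param level stimulus level (dB SPL).
#' @return half-width in octaves (0 below threshold).
#' @export
halfwidth_at <- function(params, level) {
  if (level < params$min_threshold) return(0)
  params$tip_halfwidth + (level - params$min_threshold) / params$v_slope
}

#' Genotype-like generative regime
#'
#' Dimensionless multipliers applied to a base unit population. The stock
#' regimes mirror the directions reported for cortical recordings in the
#' Fmr1-knockout model: elevated spontaneous rate, elevated evoked gain and
#' broadened tuning in KO-like cortex; midbrain-like regimes are unchanged.
#' The magnitudes are fixture choices.
#'
#' @param label regime name.
#' @param spont_scale,evoked_scale,width_scale positive multipliers on
#'   baseline rate, evoked rate and tuning bandwidth.
#' @param n_units population size.
#' @param cf_range CF range (kHz); CFs are drawn log-uniformly inside it.
#' @return an object of class `genotype_regime`.
#' @export
genotype_regime <- function(label = "WT", spont_scale = 1, evoked_scale = 1,
                            width_scale = 1, n_units = 20,
                            cf_range = c(2, 32)) {
  stopifnot(spont_scale > 0, evoked_scale > 0, width_scale > 0, n_units > 0)
  if (cf_range[2] <= cf_range[1]) stopf("empty cf_range")
  structure(list(label = label, spont_scale = spont_scale,
                 evoked_scale = evoked_scale, width_scale = width_scale,
                 n_units = n_units, cf_range = as.numeric(cf_range)),
            class = "genotype_regime")
}

#' Stock generative regimes
#'
#' @param label one of `"WT"`, `"KO-ACx"`, `"KO-IC"`.
#' @param ... overrides passed to [genotype_regime()].
#' @return a [genotype_regime].
#' @export
stock_regime <- function(label = c("WT", "KO-ACx", "KO-IC"), ...) {
  label <- match.arg(label)
  base <- switch(label,
    "WT" = list(spont_scale = 1, evoked_scale = 1, width_scale = 1),
    "KO-ACx" = list(spont_scale = 1.5, evoked_scale = 1.3, width_scale = 1.4),
    "KO-IC" = list(spont_scale = 1, evoked_scale = 1, width_scale = 1))
  do.call(genotype_regime, utils::modifyList(c(list(label = label), base),
                                             list(...)))
}

#' Draw a population of synthetic unit parameters
#'
#' CFs are log-uniform over the regime's CF range; baseline rate, evoked rate,
#' threshold and bandwidth are drawn from fixed base distributions and then
#' multiplied by the regime scales. Bit-reproducible for a fixed seed.
#'
#' @param regime a [genotype_regime].
#' @param seed integer seed.
#' @return list of [unit_gen_params], one per unit.
#' @export
gen_unit_population <- function(regime, seed = 1) {
  set.seed(derive_seed(seed, "units", regime$label))
  n <- regime$n_units
  cf <- 2^stats::runif(n, log2(regime$cf_range[1]), log2(regime$cf_range[2]))
  baseline <- stats::rgamma(n, shape = 8, rate = 8 / 12) * regime$spont_scale
  peak <- stats::rgamma(n, shape = 12, rate = 12 / 100) * regime$evoked_scale
  thr <- sample(c(10, 20, 30), n, replace = TRUE, prob = c(0.3, 0.5, 0.2))
  bw <- pmax(stats::rnorm(n, 2.4, 0.3), 1.2) * regime$width_scale
  lapply(seq_len(n), function(i)
    unit_gen_params(cf = cf[i], baseline_rate = baseline[i],
                    peak_evoked_rate = peak[i], min_threshold = thr[i],
                    bw_octaves_at_40db = bw[i]))
}

#' Generative evoked rate for one grid cell
#'
#' @param params a [unit_gen_params].
#' @param freq,level stimulus (kHz, dB SPL).
#' @return added evoked rate in spikes/s (0 outside the V).
#' @export
evoked_rate_at <- function(params, freq, level) {
  if (level < params$min_threshold) return(0)
  oct <- abs(log2(freq / params$cf))
  hw <- halfwidth_at(params, level)
  if (oct > hw) return(0)
  rel <- if (hw > 0) oct / hw else 0
  params$peak_evoked_rate * (1 - 0.5 * rel)
}

#' Generate a synthetic tuning matrix
#'
#' Each cell's trials are inhomogeneous Poisson: the baseline rate throughout
#' the analysis window plus, inside the V-shaped responsive region, an evoked
#' rate during `[latency, latency + evoked_duration]`. A fraction of the
#' evoked intensity (`onset_fraction`, default half) is concentrated in a brief onset
#' transient of width `onset_width` ms at the response latency — the
#' temporally precise first-spike component of tone-evoked cortical
#' responses — and the remainder is sustained over the evoked interval. The
#' total evoked rate is unchanged by this split.
#'
#' @param params a [unit_gen_params].
#' @param grid stimulus grid from [default_grid()].
#' @param n_trials repeats per cell.
#' @param seed integer seed.
#' @param window analysis window (ms).
#' @param unit_id,animal_id,penetration_id,genotype identifiers stored on the
#'   matrix.
#' @return a [tuning_matrix].
#' @export
gen_tuning_matrix <- function(params, grid = default_grid(), n_trials = 30,
                              seed = 1, window = c(-40, 100), unit_id = "u1",
                              animal_id = "a1", penetration_id = "p1",
                              genotype = "WT", onset_fraction = 0.5,
                              onset_width = 2) {
  set.seed(derive_seed(seed, "matrix", unit_id))
  span_s <- (window[2] - window[1]) / 1000
  ev_win <- c(params$latency, params$latency + params$evoked_duration)
  ev_s <- (ev_win[2] - ev_win[1]) / 1000
  cells <- list()
  for (f in grid$freqs) for (l in grid$levels) {
    ev_rate <- evoked_rate_at(params, f, l)
    trains <- lapply(seq_len(n_trials), function(i) {
      n_base <- stats::rpois(1, params$baseline_rate * span_s)
      t <- stats::runif(n_base, window[1], window[2])
      if (ev_rate > 0) {
        n_on <- stats::rpois(1, onset_fraction * ev_rate * ev_s)
        n_sus <- stats::rpois(1, (1 - onset_fraction) * ev_rate * ev_s)
        t <- c(t,
               stats::runif(n_on, ev_win[1], ev_win[1] + onset_width),
               stats::runif(n_sus, ev_win[1], ev_win[2]))
      }
      spike_train(t, window = window)
    })
    cells[[cell_key(f, l)]] <- spike_train_set(trains, unit_id = unit_id,
                                               freq = f, level = l)
  }
  tuning_matrix(cells, grid$freqs, grid$levels, unit_id = unit_id,
                animal_id = animal_id, penetration_id = penetration_id,
                genotype = genotype)
}

#' Generate a cohort of tuning matrices for a regime
#'
#' @param regime a [genotype_regime].
#' @param grid stimulus grid.
#' @param n_trials repeats per cell.
#' @param seed integer seed.
#' @return list with `params` (per-unit generative truth) and `matrices`.
#' @export
gen_cohort <- function(regime, grid = default_grid(), n_trials = 30,
                       seed = 1) {
  params <- gen_unit_population(regime, seed = seed)
  matrices <- lapply(seq_along(params), function(i)
    gen_tuning_matrix(params[[i]], grid = grid, n_trials = n_trials,
                      seed = derive_seed(seed, regime$label, i),
                      unit_id = sprintf("%s_u%02d", regime$label, i),
                      genotype = regime$label))
  list(params = params, matrices = matrices)
}
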