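#' Solve the Gaussian tuning width from a measured bandwidth
#'
#' Tuning edges in the recordings are the first and last frequencies with any
#' evoked response, i.e. the point where the tuning curve first diverges from
#' its baseline asymptote. That edge is identified with the 99% point of the
#' Gaussian's cumulative distribution, written in terms of the error
#' function, `P(X <= x) = (1 + erf((x - mu)/(sigma*sqrt(2)))) / 2`, and sigma
#' is obtained by root-finding that relation at `P = p` for the half-width
#' `full_bandwidth / 2` (the quantile is solved, not hard-coded).
#'
#' @param full_bandwidth full tuning bandwidth in octaves.
#' @param p CDF value defining the tuning edge (default 0.99).
#' @return sigma in octaves.
#' @export
sigma_from_bandwidth <- function(full_bandwidth, p = 0.99) {
  if (full_bandwidth <= 0) stopf("bandwidth must be positive")
  erf <- function(z) 2 * stats::pnorm(z * sqrt(2)) - 1
  half <- full_bandwidth / 2
  # find sigma with (1 + erf(half / (sigma sqrt 2))) / 2 = p
  g <- function(sigma) (1 + erf(half / (sigma * sqrt(2)))) / 2 - p
  stats::uniroot(g, lower = half * 1e-6, upper = half * 1e6,
                 tol = 1e-12)$root
}

#' Bandwidth implied by a Gaussian tuning width (inverse of
#' [sigma_from_bandwidth()])
#'
#' @param sigma tuning width in octaves.
#' @param p CDF value defining the tuning edge.
#' @return full bandwidth in octaves.
#' @export
bandwidth_from_sigma <- function(sigma, p = 0.99) {
  2 * sigma * stats::qnorm(p)
}

#' Mean tuning summary feeding the decoder
#'
#' @param A peak evoked amplitude above baseline (spikes/s).
#' @param sigma Gaussian tuning width (octaves).
#' @param N_base baseline/asymptote rate (spikes/s).
#' @param label provenance label.
#' @return an object of class `tuning_summary`.
#' @export
tuning_summary <- function(A, sigma, N_base, label = "synthetic") {
  stopifnot(A >= 0, sigma > 0, N_base >= 0)
  structure(list(A = A, sigma = sigma, N_base = N_base, label = label),
            class = "tuning_summary")
}

#' @export
print.tuning_summary <- function(x, ...) {
  cat(sprintf("<tuning_summary> %s: A=%.2f sp/s, sigma=%.3f oct, N=%.2f sp/s\n",
              x$label, x$A, x$sigma, x$N_base))
  invisible(x)
}

#' Mean tuning summary from pipeline FRA + RLF outputs
#'
#' Mirrors how the decoder is informed by the recordings: the response
#' maximum/minimum come from the admitted rate-level fits (amplitude
#' `A = mean(resp_max - resp_min)`, baseline `N = mean(resp_min)`) and the
#' tuning width from the mean octave bandwidth 40 dB above threshold,
#' converted through [sigma_from_bandwidth()].
#'
#' @param fra_table data.frame from [fra_metrics_table()].
#' @param rlf_table data.frame from [rlf_fits_table()] (admitted fits).
#' @param label provenance label.
#' @return a [tuning_summary].
#' @export
tuning_summary_from_analysis <- function(fra_table, rlf_table,
                                         label = "measured") {
  ok <- !is.na(fra_table$bw40_lo) & !is.na(fra_table$bw40_hi) &
    fra_table$bw40_hi > fra_table$bw40_lo
  if (!any(ok)) stopf("no resolved +40 dB bandwidths")
  bw_oct <- mean(log2(fra_table$bw40_hi[ok] / fra_table$bw40_lo[ok]))
  A <- mean(rlf_table$resp_max - rlf_table$resp_min, na.rm = TRUE)
  N <- mean(rlf_table$resp_min, na.rm = TRUE)
  tuning_summary(A = A, sigma = sigma_from_bandwidth(bw_oct),
                 N_base = N, label = label)
}

#' Build a decoder population of Gaussian-tuned neurons
#'
#' Every neuron shares the mean tuning parameters (`A`, `sigma`, `N_base`)
#' of the summary; preferred frequencies `B` are equally log-spaced over the
#' frequency range (in octaves re 1 kHz). A heterogeneous population can be
#' built by passing per-neuron vectors via `A`, `sigma`, `N_base` overrides.
#'
#' @param summary a [tuning_summary].
#' @param n number of neurons (default 640).
#' @param f_range frequency range in kHz (default 1-64, eight octaves).
#' @param A,sigma,N_base optional per-neuron overrides (recycled to `n`).
#' @param sq_form `"paper"` uses `exp(-(x-B)^2 / sigma^2)` (tuning curves as
#'   printed, no factor 2); `"conventional"` uses `exp(-(x-B)^2/(2 sigma^2))`
#'   for sensitivity analysis.
#' @param count_window_s readout integration window in seconds: each trial's
#'   Poisson activity is a spike count, so the tuning-curve rate (spikes/s)
#'   is scaled by this window to give the per-trial Poisson mean. Defaults
#'   to 0.002 s: the readout integrates the temporally precise onset
#'   transient of the evoked response, so per-trial counts are well below
#'   one spike and the population operates in the low-information regime
#'   where error rates span the behavioral range.
#' @return an object of class `decoder_population` with vectors `A`, `B`
#'   (octaves re 1 kHz), `sigma`, `N_base`.
#' @export
build_population <- function(summary, n = 640, f_range = c(1, 64),
                             A = NULL, sigma = NULL, N_base = NULL,
                             sq_form = c("paper", "conventional"),
                             count_window_s = 0.002) {
  sq_form <- match.arg(sq_form)
  stopifnot(inherits(summary, "tuning_summary"), n >= 1, count_window_s > 0)
  B <- seq(log2(f_range[1]), log2(f_range[2]), length.out = n)
  structure(list(
    A = rep(A %||% summary$A, length.out = n),
    B = B,
    sigma = rep(sigma %||% summary$sigma, length.out = n),
    N_base = rep(N_base %||% summary$N_base, length.out = n),
    label = summary$label, sq_form = sq_form, f_range = f_range,
    count_window_s = count_window_s),
    class = "decoder_population")
}

#' @export
print.decoder_population <- function(x, ...) {
  cat(sprintf(
    "<decoder_population> %s: %d neurons, B in [%.1f, %.1f] oct re 1 kHz\n",
    x$label, length(x$B), min(x$B), max(x$B)))
  invisible(x)
}

#' Mean population response to a tone
#'
#' Tuning-curve value `f(x) = A * exp(-(x - B)^2 / sigma^2) + N` per neuron,
#' with `x` the stimulus position in octaves re 1 kHz.
#'
#' @param pop a [decoder_population].
#' @param stim_freq stimulus frequency (kHz).
#' @return numeric vector of per-neuron mean rates (spikes/s).
#' @export
population_rates <- function(pop, stim_freq) {
  x <- log2(stim_freq)
  denom <- if (pop$sq_form == "paper") pop$sigma^2 else 2 * pop$sigma^2
  pop$A * exp(-(x - pop$B)^2 / denom) + pop$N_base
}

#' Per-trial Poisson count means for a stimulus
#'
#' Tuning-curve rate scaled by the population's readout count window.
#'
#' @param pop a [decoder_population].
#' @param stim_freq stimulus frequency (kHz).
#' @return numeric vector of per-neuron expected counts per trial.
#' @export
population_counts <- function(pop, stim_freq) {
  population_rates(pop, stim_freq) * pop$count_window_s
}

#' Simulate censored-Poisson readout trials
#'
#' Per neuron and trial a Poisson spike count with the tuning-curve mean
#' (rate times the readout count window) is drawn; draws below 90% of the
#' neuron's baseline count are not propagated to the readout layer and
#' arrive as 0.
#'
#' @param pop a [decoder_population].
#' @param stim_freq stimulus frequency (kHz).
#' @param n_trials number of trials.
#' @param seed integer seed.
#' @param threshold_frac censoring threshold as a fraction of baseline.
#' @return integer matrix `n_trials x n_neurons` of propagated activity.
#' @export
simulate_readout <- function(pop, stim_freq, n_trials, seed = 1,
                             threshold_frac = 0.9) {
  if (n_trials <= 0) stopf("n_trials must be positive")
  set.seed(derive_seed(seed, "readout"))
  lambda <- population_counts(pop, stim_freq)
  n <- length(lambda)
  draws <- matrix(stats::rpois(n_trials * n, rep(lambda, each = n_trials)),
                  nrow = n_trials)
  theta <- threshold_frac * pop$N_base * pop$count_window_s
  censored <- sweep(draws, 2, theta, `<`)
  draws[censored] <- 0L
  draws
}

# per-neuron log-pmf lookup under the censored-Poisson observation model
# (all sub-threshold mass lands on 0): tab[v + 1, j] = log P(obs = v | j),
# computed once per hypothesis and indexed for whole trial blocks.
censored_loglik_parts <- function(lambda, theta, vmax = 0) {
  ll0 <- ifelse(theta > 0,
                stats::ppois(ceiling(theta) - 1, lambda, log.p = TRUE),
                stats::dpois(0, lambda, log = TRUE))
  tab <- t(vapply(seq_along(lambda), function(j)
    stats::dpois(0:vmax, lambda[j], log = TRUE), numeric(vmax + 1)))
  tab[, 1] <- ll0
  list(ll0 = ll0, lambda = lambda, tab = tab, vmax = vmax)
}

censored_loglik_matrix <- function(activity, parts) {
  n_tr <- nrow(activity); n <- ncol(activity)
  # linear index into the (neuron x value) lookup table
  idx <- rep(seq_len(n), each = n_tr) + n * as.vector(activity)
  rowSums(matrix(parts$tab[idx], n_tr, n))
}

#' Bayesian Go/No-Go classification of readout activity
#'
#' Computes, per trial, the posterior probability that the stimulus was the
#' Go tone given the population activity, under the censored-Poisson
#' observation model (the same model that generates the activity: Poisson
#' pmf above the propagation threshold, all sub-threshold mass on zero).
#' The label is the maximum-posterior hypothesis; exact ties are broken by a
#' fair coin.
#'
#' @param activity numeric vector (one trial) or matrix (trials x neurons)
#'   of propagated activity.
#' @param pop a [decoder_population].
#' @param go_freq,nogo_freq hypothesis frequencies (kHz).
#' @param prior prior probability of the Go hypothesis.
#' @param threshold_frac censoring threshold as a fraction of baseline.
#' @return data.frame with `posterior_go` and `label` (`"go"`/`"nogo"`) per
#'   trial.
#' @export
bayes_classify <- function(activity, pop, go_freq, nogo_freq, prior = 0.5,
                           threshold_frac = 0.9) {
  if (is.null(dim(activity))) activity <- matrix(activity, nrow = 1)
  storage.mode(activity) <- "integer"
  theta <- threshold_frac * pop$N_base * pop$count_window_s
  vmax <- max(activity, 0L)
  pg <- censored_loglik_parts(population_counts(pop, go_freq), theta, vmax)
  pn <- censored_loglik_parts(population_counts(pop, nogo_freq), theta, vmax)
  ll_go <- censored_loglik_matrix(activity, pg) + log(prior)
  ll_no <- censored_loglik_matrix(activity, pn) + log(1 - prior)
  post <- 1 / (1 + exp(ll_no - ll_go))
  label <- ifelse(ll_go > ll_no, "go", "nogo")
  ties <- ll_go == ll_no
  if (any(ties))
    label[ties] <- ifelse(stats::runif(sum(ties)) < 0.5, "go", "nogo")
  data.frame(posterior_go = post, label = label, stringsAsFactors = FALSE)
}

#' Run a Go/No-Go decoder discrimination experiment
#'
#' For each Go frequency and signed 1/12-octave offset, balanced Go and
#' No-Go trial blocks are simulated through the censored-Poisson readout and
#' classified with [bayes_classify()]; the error rate is the balanced mean
#' of the miss rate and the false-alarm rate (switchable to No-Go errors
#' only). The protocol defaults follow the decoding experiments: Go tones at
#' 4, 8, 16 and 32 kHz, No-Go tones up to one octave above and below in
#' 1/12-octave steps, 10,000 trials per condition, 15 repeated runs.
#'
#' @param pop a [decoder_population].
#' @param go_freqs Go tone frequencies (kHz).
#' @param offsets signed No-Go offsets in twelfth octaves.
#' @param n_trials trials per condition (per stimulus).
#' @param n_runs repeated runs.
#' @param seed master seed; per-(run, condition) seeds are derived.
#' @param error_mode `"balanced"` (mean of miss and FA rates) or `"nogo"`
#'   (No-Go misclassification only).
#' @param threshold_frac censoring threshold as a fraction of baseline.
#' @return data.frame (class `decoder_experiment`) with one row per
#'   (run, go_freq, offset): `miss_rate`, `fa_rate`, `error_rate`,
#'   `octave_distance`.
#' @export
run_discrimination_experiment <- function(pop, go_freqs = c(4, 8, 16, 32),
                                          offsets = c(-12:-1, 1:12),
                                          n_trials = 10000, n_runs = 15,
                                          seed = 1,
                                          error_mode = c("balanced", "nogo"),
                                          threshold_frac = 0.9) {
  error_mode <- match.arg(error_mode)
  rows <- list()
  for (run in seq_len(n_runs)) {
    for (gi in seq_along(go_freqs)) {
      g <- go_freqs[gi]
      for (off in offsets) {
        nogo <- g * 2^(off / 12)
        s <- derive_seed(seed, "exp", run, gi, off)
        act_go <- simulate_readout(pop, g, n_trials, seed = derive_seed(s, "go"),
                                   threshold_frac = threshold_frac)
        act_no <- simulate_readout(pop, nogo, n_trials,
                                   seed = derive_seed(s, "nogo"),
                                   threshold_frac = threshold_frac)
        set.seed(derive_seed(s, "ties"))
        cls_go <- bayes_classify(act_go, pop, g, nogo,
                                 threshold_frac = threshold_frac)
        cls_no <- bayes_classify(act_no, pop, g, nogo,
                                 threshold_frac = threshold_frac)
        miss <- mean(cls_go$label == "nogo")
        fa <- mean(cls_no$label == "go")
        err <- if (error_mode == "balanced") (miss + fa) / 2 else fa
        rows[[length(rows) + 1]] <- data.frame(
          run = run, go_freq = g, offset_steps = off,
          octave_distance = abs(off) / 12, miss_rate = miss, fa_rate = fa,
          error_rate = err, n_trials = n_trials)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("decoder_experiment", class(out))
  out
}

#' Mean error rate within an octave-distance band
#'
#' @param result a [run_discrimination_experiment()] result.
#' @param band inclusive octave-distance band (default 1/3 to 2/3 octave,
#'   offsets 4-8 twelfths).
#' @return data.frame of per-run band-mean error rates.
#' @export
band_error <- function(result, band = c(1 / 3, 2 / 3)) {
  sel <- result$octave_distance >= band[1] - 1e-9 &
    result$octave_distance <= band[2] + 1e-9
  r <- result[sel, , drop = FALSE]
  out <- do.call(rbind, lapply(split(r, r$run), function(g)
    data.frame(run = g$run[1], error_rate = mean(g$error_rate))))
  rownames(out) <- NULL
  out
}

perm_labels <- c("WT_full", "KO_spont", "KO_evoked", "KO_width",
                 "KO_spont+evoked", "KO_spont+width", "KO_evoked+width",
                 "KO_full")

#' Parameter-permutation decoder experiment
#'
#' Crosses the three tuning parameters (spontaneous rate `N`, evoked
#' amplitude `A`, tuning width `sigma`) between a WT-like and a KO-like mean
#' summary: all eight combinations from `WT_full` to `KO_full`, each run
#' through [run_discrimination_experiment()] restricted to the 1/3-2/3
#' octave band (offsets of 4-8 twelfth octaves on both sides), where
#' behavioral discrimination differs most.
#'
#' @param wt_summary,ko_summary [tuning_summary] objects.
#' @param go_freqs,n_trials,n_runs,seed experiment settings.
#' @param count_window_s readout count window, see [build_population()].
#' @param offsets signed twelfth-octave offsets (default the 1/3-2/3 band).
#' @param n,f_range population settings.
#' @return data.frame with `permutation`, `run`, `error_rate` (per-run band
#'   means).
#' @export
parameter_permutation_experiment <- function(wt_summary, ko_summary,
                                             go_freqs = c(4, 8, 16, 32),
                                             offsets = c(-8:-4, 4:8),
                                             n_trials = 10000, n_runs = 15,
                                             seed = 1, n = 640,
                                             f_range = c(1, 64),
                                             count_window_s = 0.002) {
  combos <- expand.grid(spont = c(FALSE, TRUE), evoked = c(FALSE, TRUE),
                        width = c(FALSE, TRUE))
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    co <- combos[i, ]
    lab <- if (!any(unlist(co))) "WT_full"
      else if (all(unlist(co))) "KO_full"
      else paste0("KO_", paste(c("spont", "evoked",
                                 "width")[unlist(co)], collapse = "+"))
    s <- tuning_summary(
      A = if (co$evoked) ko_summary$A else wt_summary$A,
      sigma = if (co$width) ko_summary$sigma else wt_summary$sigma,
      N_base = if (co$spont) ko_summary$N_base else wt_summary$N_base,
      label = lab)
    pop <- build_population(s, n = n, f_range = f_range,
                            count_window_s = count_window_s)
    res <- run_discrimination_experiment(
      pop, go_freqs = go_freqs, offsets = offsets, n_trials = n_trials,
      n_runs = n_runs, seed = derive_seed(seed, "perm", lab))
    be <- band_error(res, band = c(0, Inf))  # offsets already band-limited
    data.frame(permutation = lab, run = be$run, error_rate = be$error_rate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$permutation <- factor(out$permutation, levels = perm_labels)
  out
}

#' One-axis parameter sweep of decoder band error
#'
#' Scales one tuning parameter (width `sigma`, noise `N`, or amplitude `A`)
#' of a base summary over a multiplier grid and reports the per-run band
#' error at each grid point.
#'
#' @param base_summary a [tuning_summary].
#' @param axis `"width"`, `"noise"` or `"amplitude"`.
#' @param grid multiplier grid (e.g. `seq(0.5, 2, by = 0.25)`).
#' @param go_freqs,offsets,n_trials,n_runs,seed,n,f_range experiment
#'   settings as in [parameter_permutation_experiment()].
#' @param count_window_s readout count window, see [build_population()].
#' @return long data.frame with `axis`, `multiplier`, `run`, `error_rate`.
#' @export
parameter_sweep <- function(base_summary,
                            axis = c("width", "noise", "amplitude"),
                            grid = c(0.75, 1, 1.5), go_freqs = c(4, 8, 16, 32),
                            offsets = c(-8:-4, 4:8), n_trials = 10000,
                            n_runs = 15, seed = 1, n = 640,
                            f_range = c(1, 64), count_window_s = 0.002) {
  axis <- match.arg(axis)
  if (!length(grid)) stopf("empty sweep grid")
  rows <- lapply(grid, function(m) {
    s <- tuning_summary(
      A = base_summary$A * if (axis == "amplitude") m else 1,
      sigma = base_summary$sigma * if (axis == "width") m else 1,
      N_base = base_summary$N_base * if (axis == "noise") m else 1,
      label = sprintf("%s x%.3g", axis, m))
    pop <- build_population(s, n = n, f_range = f_range,
                            count_window_s = count_window_s)
    res <- run_discrimination_experiment(
      pop, go_freqs = go_freqs, offsets = offsets, n_trials = n_trials,
      n_runs = n_runs, seed = derive_seed(seed, "sweep", axis,
                                          round(m * 1000)))
    be <- band_error(res, band = c(0, Inf))
    data.frame(axis = axis, multiplier = m, run = be$run,
               error_rate = be$error_rate, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
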