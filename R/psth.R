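#' Peristimulus time histogram for a spike-train set
#'
#' Bins are half-open `[lo, hi)` and 5 ms wide by default; counts are total
#' spikes per bin across trials divided by the number of trials, so units are
#' spikes per trial per bin.
#'
#' @param train_set a [spike_train_set].
#' @param bin_width bin width in ms; must divide the window length.
#' @return an object of class `psth` with `bin_edges`, `counts_per_bin`,
#'   `bin_width`, `n_trials` and `window`.
#' @export
build_psth <- function(train_set, bin_width = 5) {
  n_trials <- length(train_set$trains)
  if (n_trials == 0L) stopf("build_psth: spike_train_set has no trials")
  window <- train_set$trains[[1]]$window
  span <- window[2] - window[1]
  n_bins <- span / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-9)
    stopf("bin_width %g does not divide window length %g", bin_width, span)
  n_bins <- as.integer(round(n_bins))
  edges <- window[1] + bin_width * (0:n_bins)
  all_times <- unlist(lapply(train_set$trains, `[[`, "times"), use.names = FALSE)
  # half-open bins; a spike exactly at the window end lands in the last bin
  idx <- pmin(floor((all_times - window[1]) / bin_width) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins) / n_trials
  structure(list(bin_edges = edges, counts_per_bin = counts,
                 bin_width = bin_width, n_trials = n_trials, window = window),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("<psth> %d bins of %g ms over [%g, %g] ms, %d trials\n",
              length(x$counts_per_bin), x$bin_width, x$window[1], x$window[2],
              x$n_trials))
  invisible(x)
}

#' Evoked-response criterion on a PSTH
#'
#' A cell is flagged as sound-evoked when any bin fully inside the evoked
#' window exceeds the mean pre-stimulus bin count by `k` standard deviations
#' of the pre-stimulus bins. The empirical SD over a handful of sparse
#' Poisson bins is a noisy underestimate (and undefined at zero), so it is
#' floored by the Poisson SD of a trial-averaged bin at the pre-stimulus
#' mean rate, with an absolute floor of `1/n_trials` counts; silent-baseline
#' cells therefore remain classifiable and near-empty baselines do not
#' trigger spurious detections.
#'
#' @param psth a [build_psth] result.
#' @param evoked_window,pre_window length-2 windows in ms; both must lie
#'   inside the PSTH span.
#' @param k exceedance criterion in pre-stimulus SDs.
#' @return list with `evoked` (logical), `peak_bin` (index of the maximal
#'   evoked-window bin), `peak_count`, `criterion` (the threshold count), and
#'   the pre-stimulus `pre_mean` / `pre_sd` actually used.
#' @export
detect_evoked <- function(psth, evoked_window = c(0, 40),
                          pre_window = c(-40, 0), k = 4) {
  edges <- psth$bin_edges
  if (evoked_window[1] < psth$window[1] - 1e-9 ||
      evoked_window[2] > psth$window[2] + 1e-9)
    stopf("evoked window [%g, %g] outside PSTH span",
          evoked_window[1], evoked_window[2])
  in_win <- function(w) which(edges[-length(edges)] >= w[1] - 1e-9 &
                                edges[-1] <= w[2] + 1e-9)
  pre_idx <- in_win(pre_window)
  ev_idx <- in_win(evoked_window)
  if (!length(pre_idx) || !length(ev_idx))
    stopf("detect_evoked: windows contain no complete bins")
  pre <- psth$counts_per_bin[pre_idx]
  pre_mean <- mean(pre)
  pre_sd <- stats::sd(pre)
  if (is.na(pre_sd)) pre_sd <- 0
  pre_sd <- max(pre_sd, sqrt(pre_mean / psth$n_trials), 1 / psth$n_trials)
  criterion <- pre_mean + k * pre_sd
  ev <- psth$counts_per_bin[ev_idx]
  peak <- which.max(ev)
  list(evoked = ev[peak] > criterion, peak_bin = ev_idx[peak],
       peak_count = ev[peak], criterion = criterion,
       pre_mean = pre_mean, pre_sd = pre_sd)
}

#' Mean firing rate in a window of a spike-train set
#'
#' @param train_set a [spike_train_set].
#' @param window length-2 window in ms.
#' @return mean rate across trials in spikes/s.
#' @export
window_rate <- function(train_set, window = c(0, 40)) {
  n <- length(train_set$trains)
  if (!n) stopf("window_rate: no trials")
  counts <- vapply(train_set$trains, function(tr)
    sum(tr$times >= window[1] & tr$times < window[2]), numeric(1))
  mean(counts) / ((window[2] - window[1]) / 1000)
}
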