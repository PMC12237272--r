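# Shared fixtures, built lazily once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture_cohort <- function(label = "WT", n_units = 12, seed = 3) {
  key <- sprintf("%s_%d_%d", label, n_units, seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- gen_cohort(stock_regime(label, n_units = n_units),
                                        seed = seed)
  }
  .fixture_cache[[key]]
}

fixture_metrics <- function(label = "WT", n_units = 12, seed = 3) {
  key <- sprintf("met_%s_%d_%d", label, n_units, seed)
  if (is.null(.fixture_cache[[key]])) {
    co <- fixture_cohort(label, n_units, seed)
    .fixture_cache[[key]] <- lapply(co$matrices, function(m)
      suppressWarnings(extract_fra_metrics(m)))
  }
  .fixture_cache[[key]]
}

# deterministic spike-train set: each trial has the given spike times
det_train_set <- function(times, n_trials = 30, freq = 8, level = 50,
                          window = c(-40, 100)) {
  spike_train_set(replicate(n_trials, spike_train(times, window),
                            simplify = FALSE),
                  unit_id = "det", freq = freq, level = level)
}

# small hand-built tuning matrix: evoked cells get a deterministic burst,
# silent cells only empty trains
toy_matrix <- function(freqs, levels, evoked_cells, n_spikes = 3,
                       n_trials = 30) {
  cells <- list()
  for (f in freqs) for (l in levels) {
    k <- cell_key(f, l)
    times <- if (!is.null(evoked_cells[[k]])) {
      n <- evoked_cells[[k]]
      seq(16, 34, length.out = n)
    } else numeric()
    cells[[k]] <- det_train_set(times, n_trials, freq = f, level = l)
  }
  tuning_matrix(cells, freqs, levels, unit_id = "toy")
}

wt_summary <- function() tuning_summary(A = 100,
                                        sigma = sigma_from_bandwidth(2.4),
                                        N_base = 12, label = "WT")
ko_summary <- function() tuning_summary(A = 130,
                                        sigma = sigma_from_bandwidth(1.4 * 2.4),
                                        N_base = 18, label = "KO")
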