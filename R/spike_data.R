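#' Spike train container
#'
#' A spike train holds spike times in milliseconds relative to stimulus onset
#' (0 = onset), restricted to the analysis window. The default window runs
#' from 40 ms before onset to 100 ms after.
#'
#' @param times numeric vector of spike times (ms). Sorted on construction.
#' @param window length-2 numeric, analysis window in ms.
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(times = numeric(), window = c(-40, 100)) {
  times <- sort(as.numeric(times))
  if (length(times) && (times[1] < window[1] || times[length(times)] > window[2]))
    stopf("spike times outside analysis window [%g, %g] ms", window[1], window[2])
  structure(list(times = times, window = as.numeric(window)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes in [%g, %g] ms\n",
              length(x$times), x$window[1], x$window[2]))
  invisible(x)
}

#' Repeated-trial spike trains for one stimulus cell
#'
#' One unit x one (frequency, level) combination, with one spike train per
#' stimulus repeat (30 repeats by default in the recording protocol).
#'
#' @param trains list of [spike_train] objects.
#' @param unit_id unit identifier.
#' @param freq stimulus frequency (kHz).
#' @param level stimulus intensity (dB SPL).
#' @return an object of class `spike_train_set`.
#' @export
spike_train_set <- function(trains, unit_id = "u1", freq = NA_real_,
                            level = NA_real_) {
  stopifnot(is.list(trains), all(vapply(trains, inherits, TRUE, "spike_train")))
  structure(list(unit_id = unit_id, freq = as.numeric(freq),
                 level = as.numeric(level), trains = trains),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("<spike_train_set> unit %s @ %g kHz / %g dB, %d trials\n",
              x$unit_id, x$freq, x$level, length(x$trains)))
  invisible(x)
}

#' Full frequency x intensity tuning matrix for one unit
#'
#' Holds a [spike_train_set] for every cell of the stimulus grid. The default
#' recording grid is 20 log-spaced frequencies from 1 to 64 kHz crossed with
#' intensities 0 to 90 dB SPL in 10-dB steps.
#'
#' @param cells named list of [spike_train_set]s; names are `"<freq>|<level>"`
#'   as produced by [cell_key()].
#' @param freqs ascending stimulus frequencies (kHz).
#' @param levels ascending intensities (dB SPL).
#' @param unit_id,animal_id,penetration_id identifiers.
#' @param genotype free-text group label (e.g. `"WT"`, `"KO"`).
#' @return an object of class `tuning_matrix`.
#' @export
tuning_matrix <- function(cells, freqs, levels, unit_id = "u1",
                          animal_id = "a1", penetration_id = "p1",
                          genotype = "WT") {
  freqs <- sort(as.numeric(freqs)); levels <- sort(as.numeric(levels))
  want <- as.vector(outer(freqs, levels, cell_key))
  missing <- setdiff(want, names(cells))
  if (length(missing))
    stopf("tuning matrix is missing %d grid cells (first: %s)",
          length(missing), missing[1])
  structure(list(unit_id = unit_id, animal_id = animal_id,
                 penetration_id = penetration_id, genotype = genotype,
                 freqs = freqs, levels = levels, cells = cells[want]),
            class = "tuning_matrix")
}

#' Key used to index tuning-matrix cells
#' @param freq frequency in kHz.
#' @param level intensity in dB SPL.
#' @return character key `"<freq>|<level>"` (frequency printed to 6 signif.).
#' @export
cell_key <- function(freq, level) sprintf("%.6g|%.6g", freq, level)

#' Extract one cell of a tuning matrix
#' @param matrix a [tuning_matrix].
#' @inheritParams cell_key
#' @return the [spike_train_set] at that grid cell.
#' @export
get_cell <- function(matrix, freq, level) {
  key <- cell_key(freq, level)
  cell <- matrix$cells[[key]]
  if (is.null(cell)) stopf("no cell at %g kHz / %g dB", freq, level)
  cell
}

#' @export
print.tuning_matrix <- function(x, ...) {
  cat(sprintf(
    "<tuning_matrix> unit %s (%s), %d freqs x %d levels, %d trials/cell\n",
    x$unit_id, x$genotype, length(x$freqs), length(x$levels),
    length(x$cells[[1]]$trains)))
  invisible(x)
}

#' Default stimulus grid
#'
#' @param n_freqs number of log-spaced frequency steps.
#' @param f_range frequency range (kHz).
#' @param levels intensity grid (dB SPL).
#' @return list with `freqs` and `levels`.
#' @export
default_grid <- function(n_freqs = 20, f_range = c(1, 64),
                         levels = seq(0, 90, by = 10)) {
  list(freqs = 2^seq(log2(f_range[1]), log2(f_range[2]), length.out = n_freqs),
       levels = levels)
}

spike_table_columns <- c("unit_id", "animal_id", "penetration_id", "genotype",
                         "trial_index", "freq_khz", "level_db", "spike_time_ms")

#' Read a spike table CSV into tuning matrices
#'
#' The on-disk format is a UTF-8 comma-separated table with one row per spike
#' (columns `unit_id, animal_id, penetration_id, genotype, trial_index,
#' freq_khz, level_db, spike_time_ms`) plus one sentinel row with
#' `spike_time_ms = NA` per trial so that silent trials survive a round trip.
#' Rows with spike times outside the analysis window are dropped with a
#' message reporting the count.
#'
#' @param path CSV file path.
#' @param window analysis window in ms.
#' @param n_trials expected repeats per cell; trials absent from the file are
#'   filled in as silent up to this count when sentinel rows are missing.
#' @return list of [tuning_matrix] objects, one per unit.
#' @export
read_spike_table <- function(path, window = c(-40, 100), n_trials = 30) {
  if (!file.exists(path)) stopf("spike table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(spike_table_columns, names(df))
  if (length(missing))
    stopf("spike table schema error: missing column(s) %s",
          paste(missing, collapse = ", "))
  if (!nrow(df)) return(list())
  if (!is.numeric(df$spike_time_ms)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$spike_time_ms))) &
                   !is.na(df$spike_time_ms) & df$spike_time_ms != "")
    stopf("spike table parse error: non-numeric spike_time_ms at data row %d",
          if (length(bad)) bad[1] else NA_integer_)
  }
  spikes <- df[!is.na(df$spike_time_ms), , drop = FALSE]
  out_of_window <- spikes$spike_time_ms < window[1] |
    spikes$spike_time_ms > window[2]
  if (any(out_of_window)) {
    message(sprintf("read_spike_table: dropped %d spike(s) outside [%g, %g] ms",
                    sum(out_of_window), window[1], window[2]))
    spikes <- spikes[!out_of_window, , drop = FALSE]
    df <- rbind(spikes, df[is.na(df$spike_time_ms), , drop = FALSE])
  }
  lapply(split(df, df$unit_id), function(u) {
    freqs <- sort(unique(u$freq_khz)); levels <- sort(unique(u$level_db))
    cells <- list()
    for (f in freqs) for (l in levels) {
      rows <- u[u$freq_khz == f & u$level_db == l, , drop = FALSE]
      trains <- lapply(seq_len(n_trials), function(i) {
        t <- rows$spike_time_ms[rows$trial_index == i]
        spike_train(t[!is.na(t)], window = window)
      })
      cells[[cell_key(f, l)]] <- spike_train_set(
        trains, unit_id = u$unit_id[1], freq = f, level = l)
    }
    tuning_matrix(cells, freqs, levels, unit_id = u$unit_id[1],
                  animal_id = u$animal_id[1],
                  penetration_id = u$penetration_id[1],
                  genotype = u$genotype[1])
  })
}

#' Write tuning matrices to the spike table CSV format
#'
#' Spike times are printed to 3 decimals; every trial contributes a sentinel
#' row with empty `spike_time_ms` so trial counts round-trip exactly.
#'
#' @param matrices list of [tuning_matrix] (or a single one).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(matrices, path) {
  if (inherits(matrices, "tuning_matrix")) matrices <- list(matrices)
  rows <- lapply(matrices, function(m) {
    do.call(rbind, lapply(m$cells, function(cell) {
      do.call(rbind, lapply(seq_along(cell$trains), function(i) {
        t <- cell$trains[[i]]$times
        data.frame(unit_id = m$unit_id, animal_id = m$animal_id,
                   penetration_id = m$penetration_id, genotype = m$genotype,
                   trial_index = i, freq_khz = cell$freq, level_db = cell$level,
                   spike_time_ms = if (length(t)) sprintf("%.3f", t) else NA,
                   stringsAsFactors = FALSE)
      }))
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}
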