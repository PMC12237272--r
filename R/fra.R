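#' Frequency-response-area metrics for a tuning matrix
#'
#' Per-frequency threshold is the lowest intensity whose cell passes the
#' evoked-response criterion ([detect_evoked()]) with support from above:
#' the cell one level step up must also be evoked (real frequency-response
#' areas are contiguous in level, so an isolated supra-criterion cell with a
#' silent cell above it is a statistical fluke; this continuity requirement
#' is the automatic stand-in for the manual curation of discernible tuning
#' curves, and is dropped for the top intensity row). The characteristic
#' frequency (CF) is the frequency with the minimal threshold and
#' `min_threshold` is that minimum. Ties at the minimum threshold are broken
#' by the larger evoked-window rate at threshold, then by the lower
#' frequency (with a tie flag). A unit with no evoked cell is unresolved.
#'
#' @param matrix a [tuning_matrix].
#' @param evoked_window,pre_window,k evoked-criterion settings, see
#'   [detect_evoked()].
#' @param bw_offsets suprathreshold offsets (dB) at which bandwidths and
#'   Q-values are computed.
#' @return an object of class `fra_metrics`: `cf`, `min_threshold`,
#'   per-frequency `thresholds`, `bw` (list keyed `"+10"`... with `f_lo`,
#'   `f_hi`, `level`, `flag`), `q` (named numeric), `resolved`, `tie`.
#' @export
extract_fra_metrics <- function(matrix, evoked_window = c(0, 40),
                                pre_window = c(-40, 0), k = 4,
                                bw_offsets = c(10, 20, 30, 40)) {
  freqs <- matrix$freqs; levels <- matrix$levels
  raw <- matrix(FALSE, length(freqs), length(levels),
                dimnames = list(NULL, NULL))
  for (i in seq_along(freqs)) for (j in seq_along(levels)) {
    cell <- get_cell(matrix, freqs[i], levels[j])
    det <- detect_evoked(build_psth(cell), evoked_window, pre_window, k)
    raw[i, j] <- det$evoked
  }
  # supported evoked cells: the cell one level step up must also be evoked
  # (top row exempt); used for thresholds and bandwidth rows alike
  evoked <- raw & cbind(raw[, -1, drop = FALSE], TRUE)
  thresholds <- apply(evoked, 1, function(row) {
    hit <- which(row)
    if (length(hit)) levels[hit[1]] else NA_real_
  })
  out <- list(unit_id = matrix$unit_id, genotype = matrix$genotype,
              freqs = freqs, levels = levels, evoked = evoked,
              thresholds = thresholds, cf = NA_real_,
              min_threshold = NA_real_, bw = list(), q = numeric(),
              resolved = FALSE, tie = FALSE)
  if (all(is.na(thresholds))) return(structure(out, class = "fra_metrics"))
  minthr <- min(thresholds, na.rm = TRUE)
  cand <- which(!is.na(thresholds) & thresholds == minthr)
  tie <- length(cand) > 1
  if (tie) {
    rates <- vapply(cand, function(i)
      window_rate(get_cell(matrix, freqs[i], minthr), evoked_window),
      numeric(1))
    cand <- cand[rates == max(rates)]
  }
  cf_idx <- cand[1]
  out$cf <- freqs[cf_idx]; out$min_threshold <- minthr
  out$resolved <- TRUE; out$tie <- tie
  met <- structure(out, class = "fra_metrics")
  for (off in bw_offsets) {
    bw <- bandwidth_at(matrix, met, off, evoked_matrix = evoked)
    met$bw[[sprintf("+%d", off)]] <- bw
    met$q[[sprintf("+%d", off)]] <-
      if (is.na(bw$f_lo) || bw$f_hi <= bw$f_lo) NA_real_
      else q_value(met$cf, bw$f_lo, bw$f_hi)
  }
  met
}

#' @export
print.fra_metrics <- function(x, ...) {
  if (!x$resolved) {
    cat(sprintf("<fra_metrics> unit %s: unresolved (no evoked cells)\n",
                x$unit_id))
  } else {
    cat(sprintf("<fra_metrics> unit %s: CF %.2f kHz, threshold %g dB, Q40 %s\n",
                x$unit_id, x$cf, x$min_threshold,
                if (length(x$q) && !is.na(x$q[["+40"]]))
                  sprintf("%.2f", x$q[["+40"]]) else "unresolved"))
  }
  invisible(x)
}

#' Bandwidth of the evoked region at a suprathreshold level
#'
#' The row examined is `min_threshold + delta_db`; if that row is not on the
#' level grid the nearest tested row at or below is used (flagged), and rows
#' above the grid maximum are unresolved. Bandwidth edges are the first and
#' last frequencies in the row whose cells are evoked with support from the
#' row above (the same continuity rule as [extract_fra_metrics()]); there is
#' no contiguity requirement along the frequency axis. A warning (not an
#' error) is raised when the evoked span excludes the CF.
#'
#' @param matrix a [tuning_matrix].
#' @param metrics an [extract_fra_metrics()] result (CF must be resolved).
#' @param delta_db dB above minimum threshold (typically 10, 20, 30 or 40).
#' @param evoked_window,pre_window,k evoked-criterion settings.
#' @param evoked_matrix optional precomputed logical freq x level matrix.
#' @return list with `f_lo`, `f_hi` (kHz, `NA` when unresolved), `level`
#'   (the row actually used) and `flag` (`"ok"`, `"off_grid"`,
#'   `"zero_bandwidth"` or `"unresolved"`).
#' @export
bandwidth_at <- function(matrix, metrics, delta_db,
                         evoked_window = c(0, 40), pre_window = c(-40, 0),
                         k = 4, evoked_matrix = NULL) {
  if (!isTRUE(metrics$resolved)) stopf("CF unresolved; no bandwidth")
  target <- metrics$min_threshold + delta_db
  levels <- matrix$levels
  flag <- "ok"
  if (target > max(levels) + 1e-9)
    return(list(f_lo = NA_real_, f_hi = NA_real_, level = NA_real_,
                flag = "unresolved"))
  if (!any(abs(levels - target) < 1e-9)) {
    target <- max(levels[levels <= target])
    flag <- "off_grid"
  }
  j <- which(abs(levels - target) < 1e-9)[1]
  if (is.null(evoked_matrix)) {
    detect_row <- function(jj) vapply(matrix$freqs, function(f) {
      det <- detect_evoked(build_psth(get_cell(matrix, f, levels[jj])),
                           evoked_window, pre_window, k)
      det$evoked
    }, logical(1))
    row <- detect_row(j)
    if (j < length(levels)) row <- row & detect_row(j + 1)
  } else row <- evoked_matrix[, j]
  hit <- which(row)
  if (!length(hit))
    return(list(f_lo = NA_real_, f_hi = NA_real_, level = levels[j],
                flag = "unresolved"))
  f_lo <- matrix$freqs[hit[1]]; f_hi <- matrix$freqs[hit[length(hit)]]
  if (f_lo > metrics$cf + 1e-9 || f_hi < metrics$cf - 1e-9)
    warnf("evoked region at +%g dB excludes the CF (unit %s)", delta_db,
          matrix$unit_id)
  if (f_hi <= f_lo) flag <- "zero_bandwidth"
  list(f_lo = f_lo, f_hi = f_hi, level = levels[j], flag = flag)
}

#' Q-value: CF over bandwidth
#'
#' `Q = cf / (f_hi - f_lo)` with all quantities in kHz; larger Q means
#' sharper tuning, and the CF normalisation accounts for tuning differences
#' due to CF location. Undefined (NA) when the bandwidth is zero.
#'
#' @param cf characteristic frequency (kHz).
#' @param f_lo,f_hi bandwidth edges (kHz).
#' @return Q (dimensionless), `NA` when `f_hi == f_lo`.
#' @export
q_value <- function(cf, f_lo, f_hi) {
  if (f_hi < f_lo) stopf("negative bandwidth")
  if (f_hi == f_lo) return(NA_real_)
  cf / (f_hi - f_lo)
}

#' Tidy data.frame of FRA metrics
#'
#' @param metrics list of [fra_metrics] objects.
#' @return data.frame, one row per unit (the metrics CSV schema).
#' @export
fra_metrics_table <- function(metrics) {
  do.call(rbind, lapply(metrics, function(m) {
    row <- data.frame(unit_id = m$unit_id, genotype = m$genotype,
                      cf_khz = m$cf, min_threshold_db = m$min_threshold,
                      resolved = m$resolved, tie = m$tie,
                      stringsAsFactors = FALSE)
    for (off in c(10, 20, 30, 40)) {
      key <- sprintf("+%d", off)
      bw <- m$bw[[key]]
      row[[sprintf("bw%d_lo", off)]] <- if (is.null(bw)) NA else bw$f_lo
      row[[sprintf("bw%d_hi", off)]] <- if (is.null(bw)) NA else bw$f_hi
      row[[sprintf("q%d", off)]] <-
        if (length(m$q) && key %in% names(m$q)) m$q[[key]] else NA_real_
    }
    row
  }))
}
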