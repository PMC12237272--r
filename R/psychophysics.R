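#' Session-level response rates for a Go/No-Go trial table
#'
#' Hit rate is computed over Go trials. The false-alarm denominator is the
#' catch trials in detection sessions and the No-Go trials in discrimination
#' sessions (whichever is present; No-Go wins when both are).
#'
#' @param trials data.frame with at least `trial_type` (`go|nogo|catch`),
#'   `freq_khz`, `level_db` and `responded` columns.
#' @return an object of class `session_rates`: counts, `hit_rate`, `fa_rate`
#'   and a per-stimulus `breakdown` data.frame keyed by (freq, level).
#' @export
compute_session_rates <- function(trials) {
  bad <- setdiff(unique(trials$trial_type), c("go", "nogo", "catch"))
  if (length(bad)) stopf("unknown trial_type: %s", paste(bad, collapse = ", "))
  go <- trials[trials$trial_type == "go", , drop = FALSE]
  nogo <- trials[trials$trial_type == "nogo", , drop = FALSE]
  catch <- trials[trials$trial_type == "catch", , drop = FALSE]
  if (!nrow(go)) stopf("session has no go trials")
  ref <- if (nrow(nogo)) nogo else catch
  breakdown <- do.call(rbind, lapply(
    split(trials, list(trials$trial_type,
                       ifelse(is.na(trials$freq_khz), -1, trials$freq_khz),
                       ifelse(is.na(trials$level_db), -1, trials$level_db)),
          drop = TRUE),
    function(g) data.frame(trial_type = g$trial_type[1],
                           freq_khz = g$freq_khz[1], level_db = g$level_db[1],
                           n = nrow(g), response_rate = mean(g$responded))))
  rownames(breakdown) <- NULL
  structure(list(n_go = nrow(go), n_nogo = nrow(nogo), n_catch = nrow(catch),
                 hit_rate = mean(go$responded),
                 fa_rate = if (nrow(ref)) mean(ref$responded) else NA_real_,
                 n_ref = nrow(ref), breakdown = breakdown),
            class = "session_rates")
}

#' @export
print.session_rates <- function(x, ...) {
  cat(sprintf(
    "<session_rates> %d go / %d nogo / %d catch; hit %.3f, FA %.3f\n",
    x$n_go, x$n_nogo, x$n_catch, x$hit_rate, x$fa_rate))
  invisible(x)
}

#' Signal-detection sensitivity d-prime
#'
#' `d' = z(hit) - z(fa)` with each rate clipped to
#' `[1/(2n), 1 - 1/(2n)]` for its own trial count, so perfect rates remain
#' finite and `dprime(h, f) = -dprime(f, h)` under symmetric clipping.
#'
#' @param hit_rate,fa_rate proportions in `[0, 1]`.
#' @param n_go,n_ref trial counts behind each rate.
#' @return d-prime.
#' @export
dprime <- function(hit_rate, fa_rate, n_go, n_ref = n_go) {
  if (any(c(n_go, n_ref) <= 0)) stopf("trial counts must be positive")
  if (any(c(hit_rate, fa_rate) < 0 | c(hit_rate, fa_rate) > 1))
    stopf("rates must lie in [0, 1]")
  clip <- function(p, n) pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))
  stats::qnorm(clip(hit_rate, n_go)) - stats::qnorm(clip(fa_rate, n_ref))
}

#' Per-level d-prime psychometric table for a detection session
#'
#' @param trials detection trial table (go + catch trials).
#' @return data.frame with `level_db`, `n_go`, `hit_rate`, `fa_rate`, `dprime`
#'   (the session FA rate over catch trials is shared across levels).
#' @export
psychometric_table <- function(trials) {
  rates <- compute_session_rates(trials)
  go <- trials[trials$trial_type == "go", , drop = FALSE]
  per <- lapply(split(go, go$level_db), function(g)
    data.frame(level_db = g$level_db[1], n_go = nrow(g),
               hit_rate = mean(g$responded)))
  out <- do.call(rbind, per)
  out <- out[order(out$level_db), , drop = FALSE]
  out$fa_rate <- rates$fa_rate
  out$dprime <- mapply(dprime, out$hit_rate, out$fa_rate, out$n_go,
                       MoreArgs = list(n_ref = rates$n_ref))
  rownames(out) <- NULL
  out
}

#' Detection threshold at a d-prime criterion
#'
#' The threshold is the lowest level at which the d-prime curve, linearly
#' interpolated in dB, crosses the criterion from below. If d-prime exceeds
#' the criterion already at the lowest tested level that level is returned;
#' if the criterion is never reached the threshold is unresolved (`NA`).
#' Multiple crossings return the first, with a warning.
#'
#' @param psy data.frame with `level_db` and `dprime` columns (e.g. from
#'   [psychometric_table()]).
#' @param criterion d-prime criterion (default 1.5, the conservative cutoff
#'   used for behavioral thresholds).
#' @return list with `threshold_db` (`NA` if unresolved) and `resolved`.
#' @export
detection_threshold <- function(psy, criterion = 1.5) {
  psy <- psy[order(psy$level_db), , drop = FALSE]
  if (nrow(psy) < 2) stopf("need at least two levels")
  d <- psy$dprime; lev <- psy$level_db
  if (d[1] >= criterion)
    return(list(threshold_db = lev[1], resolved = TRUE))
  cross <- which(d[-length(d)] < criterion & d[-1] >= criterion)
  if (!length(cross)) return(list(threshold_db = NA_real_, resolved = FALSE))
  if (length(cross) > 1)
    warnf("d-prime crosses the criterion %d times; using the first",
          length(cross))
  i <- cross[1]
  thr <- lev[i] + (criterion - d[i]) / (d[i + 1] - d[i]) * (lev[i + 1] - lev[i])
  list(threshold_db = thr, resolved = TRUE)
}

#' False-alarm rates by octave distance from the Go tone
#'
#' No-Go trials are assigned a tonal distance `|log2(f / go_freq)|`, snapped
#' to the nearest 1/12-octave step. The per-step FA curve pools tones above
#' and below the Go frequency (side is retained); band means group steps into
#' near (< 1/3 octave), middle (1/3 to 2/3 octave inclusive) and far
#' (> 2/3 octave) bands.
#'
#' @param trials discrimination trial table.
#' @param go_freq Go tone frequency (kHz).
#' @return list with `per_step` (step_octaves, n, n_above, n_below, fa_rate)
#'   and `bands` (band, n, fa_rate) data.frames.
#' @export
fa_by_octave_band <- function(trials, go_freq) {
  nogo <- trials[trials$trial_type == "nogo", , drop = FALSE]
  if (!nrow(nogo)) stopf("no nogo trials present")
  oct <- log2(nogo$freq_khz / go_freq)
  if (any(abs(oct) < 1e-9))
    warnf("No-Go tone equal to the Go frequency (octave distance 0)")
  step <- round(abs(oct) * 12) / 12
  per_step <- do.call(rbind, lapply(split(seq_len(nrow(nogo)), step),
    function(idx) data.frame(step_octaves = step[idx[1]], n = length(idx),
                             n_above = sum(oct[idx] > 0),
                             n_below = sum(oct[idx] < 0),
                             fa_rate = mean(nogo$responded[idx]))))
  per_step <- per_step[order(per_step$step_octaves), , drop = FALSE]
  rownames(per_step) <- NULL
  band_of <- function(s) ifelse(s < 1 / 3 - 1e-9, "near",
                                ifelse(s <= 2 / 3 + 1e-9, "middle", "far"))
  band <- band_of(step)
  bands <- do.call(rbind, lapply(split(seq_len(nrow(nogo)), band),
    function(idx) data.frame(band = band[idx[1]], n = length(idx),
                             fa_rate = mean(nogo$responded[idx]))))
  bands$band <- factor(bands$band, levels = c("near", "middle", "far"))
  bands <- bands[order(bands$band), , drop = FALSE]
  rownames(bands) <- NULL
  list(per_step = per_step, bands = bands)
}
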