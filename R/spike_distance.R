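#' Pairwise dissimilarity profile between two spike trains
#'
#' Computes the rate-independent SPIKE-distance profile `S'(t)` between two
#' trains over an analysis window. For each train the instantaneous spike
#' timing difference is
#' `S_n(t) = (dtP * xF + dtF * xP) / xISI`, where `dtP`/`dtF` are the
#' distances from the preceding/following spike of train *n* to the nearest
#' spike of the other train, `xP`/`xF` are the intervals from `t` to the
#' preceding/following spike, and `xISI` is the current interspike interval.
#' The two contributions are averaged and normalised by the mean of the two
#' instantaneous ISIs (the rate-independent convention, unweighted by the
#' local ISI):
#' `S'(t) = (S1(t) + S2(t)) / (2 * mean(xISI1, xISI2))`.
#' Auxiliary spikes at the window edges make every term defined near the
#' boundaries. `S'` is piecewise linear with breakpoints at the spikes of
#' either train, so the profile is returned segment-wise and its time
#' integral is exact.
#'
#' @param train1,train2 [spike_train] objects or numeric spike-time vectors
#'   (ms).
#' @param window length-2 analysis window (ms); defaults to 0-100 ms
#'   post-onset, the evoked analysis span.
#' @return an object of class `dissimilarity_profile`: a data.frame
#'   `segments` with columns `t_start, t_end, s_start, s_end` (plus the
#'   per-train components `S1_*`, `S2_*`, `isi1`, `isi2`), the exact
#'   integral `D`, and the `window`.
#' @export
pair_profile <- function(train1, train2, window = c(0, 100)) {
  if (window[2] <= window[1]) stopf("empty analysis window")
  t1 <- clip_times(train1, window)
  t2 <- clip_times(train2, window)
  a <- sort(unique(c(window[1], t1[t1 > window[1] & t1 < window[2]],
                     window[2])))
  b <- sort(unique(c(window[1], t2[t2 > window[1] & t2 < window[2]],
                     window[2])))
  da <- nearest_distance(a, b)
  db <- nearest_distance(b, a)
  brk <- sort(unique(c(a, b)))
  seg <- lapply(seq_len(length(brk) - 1), function(s) {
    u <- brk[s]; v <- brk[s + 1]; mid <- (u + v) / 2
    ia <- findInterval(mid, a); ib <- findInterval(mid, b)
    S_n <- function(t, sp, dn, i) {
      x <- sp[i + 1] - sp[i]
      (dn[i] * (sp[i + 1] - t) + dn[i + 1] * (t - sp[i])) / x
    }
    isi1 <- a[ia + 1] - a[ia]; isi2 <- b[ib + 1] - b[ib]
    m <- (isi1 + isi2) / 2
    s1u <- S_n(u, a, da, ia); s1v <- S_n(v, a, da, ia)
    s2u <- S_n(u, b, db, ib); s2v <- S_n(v, b, db, ib)
    data.frame(t_start = u, t_end = v,
               s_start = (s1u + s2u) / (2 * m),
               s_end = (s1v + s2v) / (2 * m),
               S1_start = s1u, S1_end = s1v, S2_start = s2u, S2_end = s2v,
               isi1 = isi1, isi2 = isi2)
  })
  segments <- do.call(rbind, seg)
  D <- sum((segments$s_start + segments$s_end) / 2 *
             (segments$t_end - segments$t_start)) / (window[2] - window[1])
  structure(list(segments = segments, D = D, window = window),
            class = "dissimilarity_profile")
}

#' @export
print.dissimilarity_profile <- function(x, ...) {
  cat(sprintf("<dissimilarity_profile> %d segments on [%g, %g] ms, D = %.5f\n",
              nrow(x$segments), x$window[1], x$window[2], x$D))
  invisible(x)
}

clip_times <- function(train, window) {
  t <- if (inherits(train, "spike_train")) train$times else as.numeric(train)
  sort(t[t >= window[1] & t <= window[2]])
}

nearest_distance <- function(a, b) {
  vapply(a, function(x) min(abs(x - b)), numeric(1))
}

#' Rate-independent SPIKE-distance between two spike trains
#'
#' Scalar time integral of the pairwise dissimilarity profile,
#' `D = (1/T) * integral of S'(t) dt`, computed piecewise-exactly in
#' compiled code.
#'
#' @inheritParams pair_profile
#' @return nonnegative scalar dissimilarity; 0 for identical trains.
#' @export
pair_spike_distance <- function(train1, train2, window = c(0, 100)) {
  cpp_pair_spike_distance(clip_times(train1, window),
                          clip_times(train2, window),
                          window[1], window[2])
}

#' Multi-train SPIKE-distance
#'
#' The instantaneous multi-train profile is the average of the pairwise
#' profiles over all `N(N-1)/2` train pairs; because averaging and time
#' integration commute, the integrated multi-train distance equals the mean
#' of the pairwise distances, which is how it is computed.
#'
#' @param trains list of [spike_train] objects or numeric spike-time vectors
#'   (at least 2).
#' @param window length-2 analysis window (ms).
#' @param pair_matrix if `TRUE`, also return the full pairwise distance
#'   matrix.
#' @return an object of class `spike_distance_result` with `D`, `n_trains`,
#'   `window` and optionally `pair_matrix`.
#' @export
multitrain_distance <- function(trains, window = c(0, 100),
                                pair_matrix = FALSE) {
  if (length(trains) < 2) stopf("need at least 2 trains")
  tl <- lapply(trains, clip_times, window = window)
  if (pair_matrix) {
    M <- cpp_pairwise_spike_distance(tl, window[1], window[2])
    D <- mean(M[upper.tri(M)])
  } else {
    M <- NULL
    D <- cpp_multitrain_spike_distance(tl, window[1], window[2])
  }
  structure(list(D = D, n_trains = length(trains), window = window,
                 pair_matrix = M),
            class = "spike_distance_result")
}

#' @export
print.spike_distance_result <- function(x, ...) {
  cat(sprintf("<spike_distance_result> D = %.5f over %d trains on [%g, %g] ms\n",
              x$D, x$n_trains, x$window[1], x$window[2]))
  invisible(x)
}

#' Delta SPIKE-distance versus octave distance from CF
#'
#' For each frequency in the row 40 dB (by default) above the unit's minimum
#' threshold, the block of 30 CF-column trains is compared with the 30
#' trains at that frequency: the 30 x 30 matrix of pairwise distances
#' between the two blocks is averaged and reported relative to the within-CF
#' baseline (the mean pairwise distance inside the CF block), so
#' `Delta = 0` at zero separation by construction. The alternative of
#' pooling the 60 trains into one multi-train distance is available via
#' `method = "pooled"`; pooling mixes in the neighbour block's internal
#' similarity (sparse blocks are internally similar), which masks the
#' distance-dependence the cross comparison isolates.
#'
#' @param matrix a [tuning_matrix].
#' @param metrics an [extract_fra_metrics()] result with resolved CF.
#' @param level_offset dB above minimum threshold of the row compared.
#' @param window analysis window (ms); evoked span by default.
#' @param method `"cross"` (default; mean of the 30 x 30 cross-frequency
#'   pair distances, baseline the mean within-CF pair distance) or
#'   `"pooled"` (distance of the pooled 60-train block, baseline the
#'   within-CF 30-train distance).
#' @return data.frame with `unit_id, genotype, freq_khz, octave_distance,
#'   delta_distance, d_pooled, d_baseline`.
#' @export
delta_distance_vs_cf <- function(matrix, metrics, level_offset = 40,
                                 window = c(0, 100),
                                 method = c("cross", "pooled")) {
  method <- match.arg(method)
  if (!isTRUE(metrics$resolved))
    stopf("CF unresolved for unit %s; skipping", matrix$unit_id)
  target <- metrics$min_threshold + level_offset
  levels <- matrix$levels
  if (!any(abs(levels - target) < 1e-9)) {
    if (target > max(levels)) stopf("target row %g dB above grid", target)
    target <- max(levels[levels <= target])
  }
  cf_trains <- lapply(get_cell(matrix, metrics$cf, target)$trains,
                      clip_times, window = window)
  if (method == "pooled") {
    base <- cpp_multitrain_spike_distance(cf_trains, window[1], window[2])
  } else {
    M <- cpp_pairwise_spike_distance(cf_trains, window[1], window[2])
    base <- mean(M[upper.tri(M)])
  }
  rows <- lapply(matrix$freqs, function(f) {
    trains_f <- lapply(get_cell(matrix, f, target)$trains,
                       clip_times, window = window)
    if (abs(f - metrics$cf) < 1e-12) {
      d <- base
    } else if (method == "pooled") {
      d <- cpp_multitrain_spike_distance(c(cf_trains, trains_f),
                                         window[1], window[2])
    } else {
      n1 <- length(cf_trains)
      M <- cpp_pairwise_spike_distance(c(cf_trains, trains_f),
                                       window[1], window[2])
      d <- mean(M[seq_len(n1), n1 + seq_along(trains_f)])
    }
    data.frame(unit_id = matrix$unit_id, genotype = matrix$genotype,
               freq_khz = f,
               octave_distance = log2(f / metrics$cf),
               delta_distance = d - base, d_pooled = d, d_baseline = base,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
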