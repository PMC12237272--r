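#' Six-parameter rate-level-function model
#'
#' Logistic-plus-Gaussian curve
#' `y(x) = a + (d - a) / (1 + exp((b - x)/c)) + e * exp(-(x - f)^2 / (2 c^2))`
#' where `a` is the lower asymptote (spikes/s), `d` the upper asymptote,
#' `b` the inflection point (dB), `c` the shared slope/width parameter (dB),
#' `e` the Gaussian amplitude (spikes/s) and `f` the Gaussian center (dB).
#' One symbol `c` is shared between the logistic slope and the Gaussian
#' width, so monotone, saturating and non-monotone rate-level functions are
#' all representable with six parameters.
#'
#' @param x sound level (dB SPL).
#' @param a,b,c,d,e,f model parameters (see Description).
#' @return firing rate in spikes/s.
#' @export
rlf_model <- function(x, a, b, c, d, e, f) {
  a + (d - a) / (1 + exp((b - x) / c)) + e * exp(-(x - f)^2 / (2 * c^2))
}

#' Build the CF-column rate-level function of a tuning matrix
#'
#' The driven rate per level is the mean evoked-window spike count across
#' trials divided by the evoked-window duration, taken from the frequency
#' column at the unit's characteristic frequency. No baseline subtraction is
#' applied (the `subtract_baseline` switch removes the mean pre-stimulus rate
#' if wanted).
#'
#' @param matrix a [tuning_matrix].
#' @param cf characteristic frequency (kHz); must be on the matrix grid.
#' @param evoked_window window for the driven rate (ms).
#' @param subtract_baseline if `TRUE`, subtract the pre-stimulus rate
#'   (clamped at zero).
#' @return an object of class `rate_level_function` with `levels`, `rates`
#'   and `unit_id`.
#' @export
build_cf_rlf <- function(matrix, cf, evoked_window = c(0, 40),
                         subtract_baseline = FALSE) {
  if (!any(abs(matrix$freqs - cf) < 1e-9))
    stopf("cf %g kHz is not on the matrix frequency grid", cf)
  cf <- matrix$freqs[which.min(abs(matrix$freqs - cf))]
  rates <- vapply(matrix$levels, function(l) {
    cell <- get_cell(matrix, cf, l)
    r <- window_rate(cell, evoked_window)
    if (subtract_baseline) {
      pre <- window_rate(cell, c(cell$trains[[1]]$window[1], 0))
      r <- max(r - pre, 0)
    }
    r
  }, numeric(1))
  structure(list(levels = matrix$levels, rates = rates,
                 unit_id = matrix$unit_id, cf = cf,
                 genotype = matrix$genotype),
            class = "rate_level_function")
}

rlf_start_grid <- function(levels, rates) {
  ymin <- min(rates); ymax <- max(rates); rng <- max(ymax - ymin, 1e-3)
  xq <- stats::quantile(levels, c(0.25, 0.5, 0.75), names = FALSE)
  xmax <- levels[which.max(rates)]
  list(
    list(a = ymin, b = xq[2], c = 8, d = ymax, e = 1e-3, f = xq[2]),
    list(a = ymin, b = xq[1], c = 5, d = ymax, e = 1e-3, f = xq[3]),
    list(a = ymin, b = xq[3], c = 12, d = ymax, e = 1e-3, f = xq[1]),
    list(a = ymin, b = xq[2], c = 8, d = ymin + rng / 2, e = rng / 2,
         f = xmax),
    list(a = ymin, b = xq[1], c = 5, d = ymin, e = rng, f = xmax),
    list(a = ymin, b = xq[2], c = 15, d = ymax, e = rng / 4, f = xmax),
    list(a = ymin + rng / 4, b = xq[2], c = 10, d = ymax, e = rng / 2,
         f = xq[2]),
    list(a = ymin, b = xq[1], c = 3, d = ymax, e = rng / 3, f = xq[3]))
}

# best logistic-only (e = 0) description of the data; used both as a fit
# candidate and to seed the composite starts from its residuals
fit_logistic_stage <- function(x, y, lower, upper) {
  ymin <- min(y); ymax <- max(y)
  xq <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  best <- NULL
  for (st in list(list(a = ymin, b = xq[2], c = 8, d = ymax),
                  list(a = ymin, b = xq[1], c = 4, d = ymax),
                  list(a = ymin, b = xq[3], c = 15, d = ymax))) {
    fit <- tryCatch(suppressWarnings(minpack.lm::nlsLM(
      y ~ a + (d - a) / (1 + exp((b - x) / c)),
      start = st, lower = lower[c("a", "b", "c", "d")],
      upper = upper[c("a", "b", "c", "d")],
      control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    p <- as.list(stats::coef(fit))
    rmse <- sqrt(mean((y - rlf_model(x, p$a, p$b, p$c, p$d, 0, xq[2]))^2))
    if (is.null(best) || rmse < best$rmse) best <- list(par = p, rmse = rmse)
  }
  best
}

#' Fit the six-parameter rate-level model
#'
#' Bounded Levenberg-Marquardt least squares with eight heuristic starts
#' spanning monotone and non-monotone shapes; the fit with the lowest RMSE
#' wins (ties go to the smallest `c`). The derived threshold is the lowest
#' level (on a 1-dB evaluation grid) where the fitted curve first reaches 20%
#' of the range from the lower to the upper asymptote; the gain is the
#' maximum slope of the fitted curve over its ascending portion, evaluated
#' numerically on the same grid.
#'
#' @param rlf a [build_cf_rlf] result, or any list with `levels` and `rates`.
#' @return an object of class `rlf_fit`: parameters `a..f`, `rmse`,
#'   `resp_min`, `resp_max`, `threshold_db` (`NA` when unresolved), `gain`
#'   (spikes/s per dB) and `converged`.
#' @export
fit_rlf <- function(rlf) {
  x <- as.numeric(rlf$levels); y <- as.numeric(rlf$rates)
  if (length(x) < 6) stopf("fit_rlf needs at least 6 levels")
  if (stats::sd(y) < 1e-10) {
    # flat input: the model degenerates to a = d = mean(y), no gain
    return(structure(list(a = mean(y), b = stats::median(x), c = 8,
                          d = mean(y), e = 0, f = stats::median(x),
                          rmse = stats::sd(y) %||% 0, resp_min = mean(y),
                          resp_max = mean(y), threshold_db = NA_real_,
                          gain = 0, converged = TRUE,
                          unit_id = rlf$unit_id %||% NA,
                          genotype = rlf$genotype %||% NA),
                     class = "rlf_fit"))
  }
  # physical box bounds: the shared slope/width parameter cannot be finer
  # than the level-grid resolution, and the Gaussian amplitude cannot much
  # exceed the observed dynamic range (an oversized needle Gaussian would
  # only ever chase trial noise between grid points)
  # a and d are the derived response minimum and maximum, so they are boxed
  # near the observed floor and peak rather than left free
  step <- min(diff(sort(unique(x))))
  rng <- diff(range(y))
  lower <- c(a = 0, b = min(x) - 20, c = max(step / 3, 0.5), d = 0, e = 0,
             f = min(x) - 20)
  upper <- c(a = min(y) + 0.6 * rng + 5, b = max(x) + 20, c = 60,
             d = max(y) * 1.3 + 5, e = rng + 5, f = max(x) + 20)
  starts <- rlf_start_grid(x, y)
  logi <- fit_logistic_stage(x, y, lower, upper)
  best <- NULL
  if (!is.null(logi)) {
    # logistic-only candidate (e = 0), plus a composite start seeded from
    # the logistic residuals
    best <- list(par = c(logi$par, list(e = 0, f = stats::median(x))),
                 rmse = logi$rmse)
    r <- y - rlf_model(x, logi$par$a, logi$par$b, logi$par$c, logi$par$d,
                       0, 0)
    starts <- c(starts,
                list(c(logi$par, list(e = max(max(r), 1e-3),
                                      f = x[which.max(r)])),
                     c(logi$par, list(e = max(diff(range(y)) / 3, 1e-3),
                                      f = x[which.max(y)]))))
  }
  for (st in starts) {
    st <- mapply(function(v, lo, hi) min(max(v, lo), hi), st,
                 lower[names(st)], upper[names(st)], SIMPLIFY = FALSE)
    fit <- tryCatch(suppressWarnings(minpack.lm::nlsLM(
      y ~ rlf_model(x, a, b, c, d, e, f),
      start = st[c("a", "b", "c", "d", "e", "f")], lower = lower,
      upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    p <- as.list(stats::coef(fit))
    # a and d are the lower and upper asymptote by definition: candidates
    # where the roles invert are degenerate re-parameterisations, not fits
    if (p$d < p$a) next
    rmse <- sqrt(mean((y - rlf_model(x, p$a, p$b, p$c, p$d, p$e, p$f))^2))
    if (is.null(best) || rmse < best$rmse - 1e-12 ||
        (abs(rmse - best$rmse) <= 1e-12 && p$c < best$par$c)) {
      best <- list(par = p, rmse = rmse)
    }
  }
  if (is.null(best)) {
    return(structure(list(a = NA, b = NA, c = NA, d = NA, e = NA, f = NA,
                          rmse = NA_real_, resp_min = NA_real_,
                          resp_max = NA_real_, threshold_db = NA_real_,
                          gain = NA_real_, converged = FALSE,
                          unit_id = rlf$unit_id %||% NA,
                          genotype = rlf$genotype %||% NA),
                     class = "rlf_fit"))
  }
  p <- best$par
  grid <- seq(min(x), max(x), by = 1)
  curve <- rlf_model(grid, p$a, p$b, p$c, p$d, p$e, p$f)
  target <- p$a + 0.2 * (p$d - p$a)
  threshold <- NA_real_
  if ((p$d - p$a) > 1e-8) {
    hit <- which(curve >= target)
    if (length(hit)) threshold <- grid[hit[1]]
  }
  slopes <- diff(curve)  # per 1 dB
  amax <- which.max(curve)
  gain <- if (amax > 1) max(slopes[seq_len(amax - 1)], 0) else 0
  structure(list(a = p$a, b = p$b, c = p$c, d = p$d, e = p$e, f = p$f,
                 rmse = best$rmse, resp_min = p$a, resp_max = p$d,
                 threshold_db = threshold, gain = gain, converged = TRUE,
                 unit_id = rlf$unit_id %||% NA,
                 genotype = rlf$genotype %||% NA),
            class = "rlf_fit")
}

#' @export
print.rlf_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<rlf_fit> a=%.2f b=%.1f c=%.1f d=%.2f e=%.2f f=%.1f ",
           "rmse=%.3g thr=%s gain=%.3f\n"),
    x$a, x$b, x$c, x$d, x$e, x$f, x$rmse,
    if (is.na(x$threshold_db)) "unresolved" else sprintf("%.0f dB",
                                                         x$threshold_db),
    x$gain))
  invisible(x)
}

#' Filter rate-level fits by RMSE
#'
#' Keeps fits with `rmse < rmse_cutoff` (default 100 spikes/s) and that
#' converged; returns the admitted list plus an exclusion report by genotype.
#'
#' @param fits list of [rlf_fit] objects.
#' @param rmse_cutoff admission cutoff (spikes/s).
#' @return list with `admitted`, `excluded`, and `report` (data.frame with
#'   kept/excluded counts per genotype label).
#' @export
filter_fits <- function(fits, rmse_cutoff = 100) {
  ok <- vapply(fits, function(f) isTRUE(f$converged) &&
                 !is.na(f$rmse) && f$rmse < rmse_cutoff, logical(1))
  labels <- vapply(fits, function(f)
    as.character(f$genotype %||% NA), character(1))
  report <- do.call(rbind, lapply(split(seq_along(fits), labels), function(i)
    data.frame(genotype = labels[i[1]], kept = sum(ok[i]),
               excluded = sum(!ok[i]))))
  rownames(report) <- NULL
  list(admitted = fits[ok], excluded = fits[!ok], report = report)
}

#' Tidy data.frame of rate-level fits
#'
#' @param fits list of [rlf_fit] objects.
#' @return data.frame, one row per fit (the fits CSV schema).
#' @export
rlf_fits_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f)
    data.frame(unit_id = as.character(f$unit_id),
               genotype = as.character(f$genotype),
               a = f$a, b = f$b, c = f$c, d = f$d, e = f$e, f = f$f,
               rmse = f$rmse, resp_min = f$resp_min, resp_max = f$resp_max,
               threshold_db = f$threshold_db, gain = f$gain,
               converged = f$converged, stringsAsFactors = FALSE)))
}
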