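#' Generative parameters for Go/No-Go behavioral sessions
#'
#' Detection sessions follow an equal-variance Gaussian observer with a fixed
#' response criterion: on a Go trial at level L the hit probability is
#' `pnorm(dprime(L) - lambda)` and on a catch trial the false-alarm
#' probability is `pnorm(-lambda)`, with `lambda = -qnorm(fa_floor)`. The
#' generative sensitivity follows a logistic psychometric curve
#' `dprime(L) = d_max * plogis((L - midpoint) / slope)`, so recovered
#' `z(hit) - z(fa)` equals the generative d-prime exactly in expectation and
#' sessions are invertible by the psychophysics stage.
#'
#' Discrimination sessions are 50:50 Go/No-Go; the false-alarm probability on
#' a No-Go trial falls sigmoidally with octave distance from the Go tone.
#'
#' @param go_freq Go tone frequency (kHz).
#' @param d_midpoint,d_slope,d_max psychometric midpoint (dB), slope (dB) and
#'   asymptotic d-prime for detection.
#' @param fa_floor,fa_ceiling,fa_midpoint,fa_slope false-alarm curve for
#'   discrimination: floor and ceiling probabilities, midpoint (octaves) and
#'   slope (octaves).
#' @param levels detection levels tested (dB SPL).
#' @param n_trials trials per session.
#' @param catch_fraction proportion of catch trials in detection sessions.
#' @param hit_p Go-trial hit probability in discrimination sessions.
#' @return an object of class `behavior_gen_params`.
#' @export
behavior_gen_params <- function(go_freq = 8, d_midpoint = 30, d_slope = 4,
                                d_max = 3.5, fa_floor = 0.1,
                                fa_ceiling = 0.85, fa_midpoint = 0.5,
                                fa_slope = 0.1, levels = seq(10, 60, by = 5),
                                n_trials = 300, catch_fraction = 0.30,
                                hit_p = 0.95) {
  stopifnot(fa_floor >= 0, fa_ceiling <= 1, fa_floor <= fa_ceiling,
            catch_fraction >= 0, catch_fraction < 1)
  structure(list(go_freq = go_freq, d_midpoint = d_midpoint,
                 d_slope = d_slope, d_max = d_max, fa_floor = fa_floor,
                 fa_ceiling = fa_ceiling, fa_midpoint = fa_midpoint,
                 fa_slope = fa_slope, levels = levels, n_trials = n_trials,
                 catch_fraction = catch_fraction, hit_p = hit_p),
            class = "behavior_gen_params")
}

#' Generative detection d-prime at a level
#' @param params a [behavior_gen_params].
#' @param level dB SPL.
#' @return generative d-prime.
#' @export
gen_dprime_at <- function(params, level) {
  params$d_max * stats::plogis((level - params$d_midpoint) / params$d_slope)
}

#' Level at which the generative detection d-prime crosses a criterion
#' @param params a [behavior_gen_params].
#' @param criterion d-prime criterion (default 1.5).
#' @return level in dB SPL.
#' @export
gen_threshold_level <- function(params, criterion = 1.5) {
  p <- criterion / params$d_max
  if (p <= 0 || p >= 1) return(NA_real_)
  params$d_midpoint + params$d_slope * stats::qlogis(p)
}

#' Generative discrimination false-alarm probability at an octave distance
#' @param params a [behavior_gen_params].
#' @param oct absolute octave distance from the Go tone.
#' @return false-alarm probability.
#' @export
gen_fa_at <- function(params, oct) {
  params$fa_floor + (params$fa_ceiling - params$fa_floor) *
    stats::plogis(-(oct - params$fa_midpoint) / params$fa_slope)
}

#' Generate a Go/No-Go behavioral session
#'
#' @param params a [behavior_gen_params].
#' @param mode `"detection"` (Go + catch trials, levels varied) or
#'   `"discrimination"` (50:50 Go/No-Go, No-Go tones at 1/12-octave steps).
#' @param steps for discrimination, the signed twelfth-octave steps of the
#'   No-Go tones (default both sides, 1..12).
#' @param seed integer seed.
#' @param session_id identifier stored in the table.
#' @return data.frame with columns `session_id, trial_index, trial_type,
#'   freq_khz, level_db, responded, latency_ms`.
#' @export
gen_behavior_session <- function(params, mode = c("detection",
                                                  "discrimination"),
                                 steps = c(-12:-1, 1:12), seed = 1,
                                 session_id = "s1") {
  mode <- match.arg(mode)
  if (params$n_trials <= 0) stopf("n_trials must be positive")
  set.seed(derive_seed(seed, "behavior", session_id, mode))
  n <- params$n_trials
  if (mode == "detection") {
    is_catch <- stats::runif(n) < params$catch_fraction
    level <- ifelse(is_catch, NA,
                    sample(params$levels, n, replace = TRUE))
    lambda <- -stats::qnorm(max(params$fa_floor, 1e-12))
    p <- ifelse(is_catch, stats::pnorm(-lambda),
                stats::pnorm(gen_dprime_at(params, level) - lambda))
    if (params$fa_floor == 0) p[is_catch] <- 0
    trial_type <- ifelse(is_catch, "catch", "go")
    freq <- ifelse(is_catch, NA, params$go_freq)
  } else {
    is_go <- stats::runif(n) < 0.5
    step <- ifelse(is_go, 0L, sample(steps, n, replace = TRUE))
    freq <- params$go_freq * 2^(step / 12)
    level <- rep(40, n)  # 40 dB above sensation level by protocol
    oct <- abs(step) / 12
    p <- ifelse(is_go, params$hit_p, gen_fa_at(params, oct))
    if (params$fa_floor == 0 && params$fa_ceiling == 0) p[!is_go] <- 0
    trial_type <- ifelse(is_go, "go", "nogo")
  }
  responded <- as.integer(stats::runif(n) < p)
  latency <- ifelse(responded == 1,
                    round(stats::rlnorm(n, log(450), 0.3), 1), NA)
  data.frame(session_id = session_id, trial_index = seq_len(n),
             trial_type = trial_type, freq_khz = freq, level_db = level,
             responded = responded, latency_ms = latency,
             stringsAsFactors = FALSE)
}
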