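#' Derive a child RNG seed from a master seed and a tag
#'
#' All stochastic stages take a single master seed; per-stage / per-run seeds
#' are derived deterministically from it so that reruns are bit-reproducible
#' and independent stages do not share RNG streams. The result always fits a
#' 32-bit signed integer.
#'
#' @param master integer master seed.
#' @param ... further integers or strings mixed into the derived seed.
#' @return an integer usable with [set.seed()].
#' @export
derive_seed <- function(master, ...) {
  parts <- list(...)
  h <- as.double(master) %% 2147483647
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p)))
    for (v in as.double(p)) {
      h <- (h * 69069 + v * 2654435761 + 1013904223) %% 2147483647
    }
  }
  as.integer(h)
}

#' Octave distance between two frequencies
#'
#' @param f,ref frequencies in kHz (or any common unit).
#' @return signed octave distance `log2(f / ref)`.
#' @export
octaves <- function(f, ref) log2(f / ref)

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
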