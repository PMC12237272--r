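# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive implementations (dense-grid evaluation, exhaustive
# enumeration) kept separate from the package's own algorithms.

# Dense-grid brute force for the rate-independent SPIKE-distance profile:
# evaluates S'(t) pointwise on a dt grid directly from the definitions and
# integrates with the trapezoid rule.
brute_spike_profile <- function(t1, t2, window = c(0, 100), dt = 0.01) {
  aug <- function(t) sort(unique(c(window[1],
                                   t[t > window[1] & t < window[2]],
                                   window[2])))
  a <- aug(t1)
  b <- aug(t2)
  S_of <- function(tt, sp, other) {
    i <- pmin(pmax(findInterval(tt, sp), 1), length(sp) - 1)
    tP <- sp[i]; tF <- sp[i + 1]
    dP <- vapply(tP, function(x) min(abs(x - other)), numeric(1))
    dF <- vapply(tF, function(x) min(abs(x - other)), numeric(1))
    (dP * (tF - tt) + dF * (tt - tP)) / (tF - tP)
  }
  isi_of <- function(tt, sp) {
    i <- pmin(pmax(findInterval(tt, sp), 1), length(sp) - 1)
    sp[i + 1] - sp[i]
  }
  tt <- seq(window[1], window[2], by = dt)
  s <- (S_of(tt, a, b) + S_of(tt, b, a)) /
    (2 * (isi_of(tt, a) + isi_of(tt, b)) / 2)
  list(t = tt, s = s,
       D = sum((s[-1] + s[-length(s)]) / 2 * dt) / diff(window))
}

brute_spike_distance <- function(t1, t2, window = c(0, 100), dt = 0.01) {
  brute_spike_profile(t1, t2, window, dt)$D
}

# Exhaustive-enumeration Bayes classifier for tiny censored-Poisson
# populations: enumerates raw Poisson counts up to a cap, maps them through
# the censoring rule, accumulates exact outcome probabilities per hypothesis
# and labels each outcome vector by the larger posterior.
enum_bayes <- function(lambda_go, lambda_nogo, theta, prior = 0.5,
                       kmax = 30) {
  n <- length(lambda_go)
  obs_of <- function(k, th) ifelse(k < th, 0L, k)
  # per neuron: P(obs = v | lambda) by enumeration over raw counts
  obs_pmf <- function(lambda, th) {
    k <- 0:kmax
    p <- stats::dpois(k, lambda)
    v <- obs_of(k, th)
    tapply(p, v, sum)
  }
  pmf_go <- lapply(seq_len(n), function(j) obs_pmf(lambda_go[j], theta[j]))
  pmf_no <- lapply(seq_len(n), function(j) obs_pmf(lambda_nogo[j], theta[j]))
  values <- lapply(seq_len(n), function(j)
    sort(unique(c(as.integer(names(pmf_go[[j]])),
                  as.integer(names(pmf_no[[j]]))))))
  grid <- expand.grid(lapply(values, identity))
  lab <- apply(grid, 1, function(v) {
    lg <- prod(vapply(seq_len(n), function(j) {
      p <- pmf_go[[j]][as.character(v[j])]
      if (is.na(p)) 0 else p
    }, numeric(1))) * prior
    ln <- prod(vapply(seq_len(n), function(j) {
      p <- pmf_no[[j]][as.character(v[j])]
      if (is.na(p)) 0 else p
    }, numeric(1))) * (1 - prior)
    if (lg > ln) "go" else if (ln > lg) "nogo" else "tie"
  })
  data.frame(grid, label = lab, stringsAsFactors = FALSE)
}
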