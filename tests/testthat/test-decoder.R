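test_that("the tuning-width solver matches the normal-quantile oracle", {
  z99 <- qnorm(0.99)
  expect_lt(abs(sigma_from_bandwidth(2 * z99) - 1), 1e-6)
  # linearity: halving the bandwidth halves sigma
  s1 <- sigma_from_bandwidth(1.7)
  expect_equal(sigma_from_bandwidth(0.85), s1 / 2, tolerance = 1e-9)
  # round trip through the CDF edge definition
  expect_lt(abs(bandwidth_from_sigma(sigma_from_bandwidth(0.8)) - 0.8), 1e-9)
  # general agreement with the quantile form
  for (bw in c(0.3, 1, 2.4, 5)) {
    expect_lt(abs(sigma_from_bandwidth(bw) - (bw / 2) / z99), 1e-6)
  }
  expect_error(sigma_from_bandwidth(0), "positive")
})

test_that("decoder populations sit on the log-frequency grid", {
  s <- tuning_summary(A = 10, sigma = 0.5, N_base = 2)
  pop <- build_population(s, n = 4, f_range = c(1, 8))
  expect_equal(pop$B, c(0, 1, 2, 3))
  # a tone at neuron i's preferred frequency drives A + N
  rates <- population_rates(pop, 2) # 1 octave re 1 kHz = neuron 2
  expect_equal(rates[2], s$A + s$N_base)
  expect_true(all(rates[-2] < rates[2]))
})

test_that("summaries derived from the synthetic pipeline are wider for
          KO-like cohorts", {
  summ_of <- function(label) {
    co <- fixture_cohort(label, 12, 3)
    mets <- fixture_metrics(label, 12, 3)
    fits <- list()
    for (i in seq_along(mets)) {
      if (!mets[[i]]$resolved) next
      fits[[length(fits) + 1]] <- fit_rlf(build_cf_rlf(co$matrices[[i]],
                                                       mets[[i]]$cf))
    }
    tuning_summary_from_analysis(fra_metrics_table(mets),
                                 rlf_fits_table(filter_fits(fits)$admitted),
                                 label = label)
  }
  wt <- summ_of("WT")
  ko <- summ_of("KO-ACx")
  expect_gt(ko$sigma, wt$sigma)
  expect_gt(ko$N_base, wt$N_base)
})

test_that("censored readout propagation matches the Poisson-CDF oracle", {
  # A = 0: every neuron sits at baseline; propagation probability is the
  # upper tail of Poisson(N * window) at ceiling(0.9 * N * window)
  s <- tuning_summary(A = 0, sigma = 0.5, N_base = 40)
  pop <- build_population(s, n = 50, f_range = c(1, 64),
                          count_window_s = 0.05)
  act <- simulate_readout(pop, 8, n_trials = 400, seed = 2)
  lam <- 40 * 0.05
  p_prop <- 1 - ppois(ceiling(0.9 * lam) - 1, lam)
  emp <- mean(act > 0)
  se <- sqrt(p_prop * (1 - p_prop) / (400 * 50))
  expect_lt(abs(emp - p_prop), 3 * se)

  # N = 0: no censoring threshold, all draws propagate
  s0 <- tuning_summary(A = 50, sigma = 0.5, N_base = 0)
  pop0 <- build_population(s0, n = 20, f_range = c(4, 16),
                           count_window_s = 0.1)
  act0 <- simulate_readout(pop0, 8, n_trials = 200, seed = 3)
  expect_lt(abs(mean(act0[, 10]) - population_counts(pop0, 8)[10]),
            3 * sqrt(5 / 200))

  # a stimulus far outside every tuning curve leaves censored baseline
  far <- simulate_readout(pop, 0.001, n_trials = 400, seed = 4)
  mean_censored <- sum(dpois(0:50, lam) * ifelse(0:50 < 0.9 * lam, 0, 0:50))
  expect_lt(abs(mean(far) - mean_censored), 0.05)
})

test_that("classification agrees exactly with enumeration Bayes on tiny
          populations", {
  # 2 and 3 neurons, small integer means, count window 1 so rates are counts
  cases <- list(
    list(A = 3, N = 1, sigma = 0.4, n = 2, f_range = c(4, 8)),
    list(A = 4, N = 2, sigma = 0.6, n = 3, f_range = c(4, 16)))
  for (cs in cases) {
    s <- tuning_summary(A = cs$A, sigma = cs$sigma, N_base = cs$N)
    pop <- build_population(s, n = cs$n, f_range = cs$f_range,
                            count_window_s = 1)
    go <- cs$f_range[1] * 2^(1 / 4)
    nogo <- go * 2^(1 / 3)
    lam_go <- population_counts(pop, go)
    lam_no <- population_counts(pop, nogo)
    theta <- 0.9 * pop$N_base
    oracle <- enum_bayes(lam_go, lam_no, theta)
    decided <- oracle[oracle$label != "tie", , drop = FALSE]
    acts <- as.matrix(decided[, seq_len(cs$n), drop = FALSE])
    cls <- bayes_classify(acts, pop, go, nogo)
    expect_identical(cls$label, decided$label)
    # degenerate hypothesis pair: posterior exactly one half
    cls_eq <- bayes_classify(acts, pop, go, go)
    expect_true(all(cls_eq$posterior_go == 0.5))
  }
})

test_that("error at zero Go/No-Go separation is chance", {
  pop <- build_population(wt_summary())
  res <- run_discrimination_experiment(pop, go_freqs = 8, offsets = 0,
                                       n_trials = 10000, n_runs = 1, seed = 6)
  ci <- qnorm(0.995) * sqrt(0.25 / 10000) # binomial 99% CI on each rate
  expect_lt(abs(res$error_rate - 0.5), ci)
})

test_that("decoder error declines with octave distance", {
  pop <- build_population(wt_summary())
  res <- run_discrimination_experiment(pop, go_freqs = c(8, 16),
                                       offsets = c(1:3 * 2, 12),
                                       n_trials = 800, n_runs = 2, seed = 7)
  for (r in unique(res$run)) {
    a <- aggregate(error_rate ~ octave_distance, res[res$run == r, ], mean)
    expect_lt(cor(a$octave_distance, a$error_rate, method = "spearman"), 0)
  }
})

test_that("expected error is nondecreasing in tuning width", {
  errs <- vapply(c(0.3, 0.5, 0.8, 1.2), function(sg) {
    s <- tuning_summary(A = 100, sigma = sg, N_base = 12)
    pop <- build_population(s, n = 320)
    r <- run_discrimination_experiment(pop, go_freqs = 8, offsets = c(4, 6),
                                       n_trials = 1500, n_runs = 1, seed = 11)
    mean(r$error_rate)
  }, numeric(1))
  expect_true(all(diff(errs) > -0.01)) # monotone up to simulation noise
})

test_that("decoding is invariant to a common rescaling of frequency units", {
  s <- wt_summary()
  for (scale in c(1, 2.5)) {
    pop <- build_population(s, n = 160, f_range = c(1, 64) * scale)
    r <- run_discrimination_experiment(pop, go_freqs = 8 * scale,
                                       offsets = c(2, 6), n_trials = 500,
                                       n_runs = 1, seed = 13)
    if (scale == 1) ref <- r else {
      expect_equal(r$error_rate, ref$error_rate, tolerance = 1e-12)
      expect_equal(r$miss_rate, ref$miss_rate, tolerance = 1e-12)
    }
  }
})
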