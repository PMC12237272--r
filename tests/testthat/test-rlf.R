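levels10 <- seq(0, 90, by = 10)

test_that("noiseless rate-level curves are recovered to high precision", {
  set.seed(101)
  for (i in 1:8) {
    par <- list(a = runif(1, 0, 15), b = runif(1, 25, 60), c = runif(1, 4, 12),
                d = NA, e = runif(1, 10, 60), f = NA)
    par$d <- par$a + runif(1, 25, 90)
    par$f <- runif(1, par$b, 85)
    y <- rlf_model(levels10, par$a, par$b, par$c, par$d, par$e, par$f)
    fit <- fit_rlf(list(levels = levels10, rates = y))
    expect_true(fit$converged)
    expect_lt(fit$rmse, 1e-6)
    for (p in c("a", "b", "c", "d", "e", "f")) {
      expect_lt(abs(fit[[p]] - par[[p]]) / abs(par[[p]]), 0.01)
    }
  }
})

test_that("refitting a fitted curve reproduces the parameters", {
  y <- rlf_model(levels10, 5, 40, 8, 60, 30, 70)
  f1 <- fit_rlf(list(levels = levels10, rates = y))
  y2 <- rlf_model(levels10, f1$a, f1$b, f1$c, f1$d, f1$e, f1$f)
  f2 <- fit_rlf(list(levels = levels10, rates = y2))
  for (p in c("a", "b", "c", "d", "e", "f")) {
    expect_lt(abs(f2[[p]] - f1[[p]]) / max(abs(f1[[p]]), 1e-6), 1e-3)
  }
})

test_that("degenerate rate-level shapes yield flagged derived metrics", {
  flat <- fit_rlf(list(levels = levels10, rates = rep(7, 10)))
  expect_equal(flat$gain, 0)
  expect_true(is.na(flat$threshold_db))

  # pure sigmoid from 0 to 10: threshold where the curve reaches 2 spikes/s
  y <- 0 + (10 - 0) / (1 + exp((45 - levels10) / 6))
  fit <- fit_rlf(list(levels = levels10, rates = y))
  analytic <- 45 - 6 * log((10 - 2) / 2) # logistic crosses 2.0 here
  expect_lt(abs(fit$threshold_db - analytic), 1.01) # 1-dB evaluation grid
  expect_error(fit_rlf(list(levels = c(0, 10), rates = c(0, 1))), "6 levels")
})

test_that("additive rate shifts move the asymptotes but not the gain", {
  y <- rlf_model(levels10, 4, 40, 7, 50, 20, 75)
  f0 <- fit_rlf(list(levels = levels10, rates = y))
  f1 <- fit_rlf(list(levels = levels10, rates = y + 9))
  expect_equal(f1$a, f0$a + 9, tolerance = 0.02)
  expect_equal(f1$d, f0$d + 9, tolerance = 0.02)
  expect_equal(f1$gain, f0$gain, tolerance = 0.01)
})

test_that("multiplicative rate scaling scales the range and the gain", {
  y <- rlf_model(levels10, 4, 40, 7, 50, 20, 75)
  f0 <- fit_rlf(list(levels = levels10, rates = y))
  f2 <- fit_rlf(list(levels = levels10, rates = 3 * y))
  expect_equal(f2$d - f2$a, 3 * (f0$d - f0$a), tolerance = 0.02)
  expect_equal(f2$gain, 3 * f0$gain, tolerance = 0.02)
})

test_that("the RMSE filter admits good fits and reports exclusions", {
  mk_fit <- function(rmse, genotype) {
    structure(list(a = 1, b = 40, c = 8, d = 50, e = 0, f = 40, rmse = rmse,
                   resp_min = 1, resp_max = 50, threshold_db = 30, gain = 1,
                   converged = TRUE, unit_id = "u", genotype = genotype),
              class = "rlf_fit")
  }
  fits <- list(mk_fit(0, "WT"), mk_fit(12, "WT"), mk_fit(150, "KO"),
               mk_fit(3, "KO"))
  out <- filter_fits(fits)
  expect_length(out$admitted, 3)
  expect_length(out$excluded, 1)
  expect_equal(out$excluded[[1]]$rmse, 150)
  rep_ko <- out$report[out$report$genotype == "KO", ]
  expect_equal(c(rep_ko$kept, rep_ko$excluded), c(1, 1))
})

test_that("CF-column rate-level functions are exact on deterministic data and
          invariant to trial order", {
  freqs <- c(4, 8, 16)
  levels <- seq(0, 50, by = 10)
  cells <- list()
  for (f in freqs) for (l in levels) {
    n_spk <- if (f == 8) round(l / 10) else 0
    times <- if (n_spk > 0) seq(5, 35, length.out = n_spk) else numeric()
    cells[[cell_key(f, l)]] <- det_train_set(times, 30, freq = f, level = l)
  }
  m <- tuning_matrix(cells, freqs, levels, unit_id = "t")
  rlf <- build_cf_rlf(m, 8)
  expect_equal(rlf$rates, round(levels / 10) / 0.04)

  silent <- build_cf_rlf(m, 4)
  expect_true(all(silent$rates == 0))
  expect_error(build_cf_rlf(m, 5), "not on the matrix")

  # permuting trials leaves the mean rate unchanged
  m2 <- m
  m2$cells[[cell_key(8, 50)]]$trains <-
    rev(m2$cells[[cell_key(8, 50)]]$trains)
  expect_equal(build_cf_rlf(m2, 8)$rates, rlf$rates)
})

test_that("threshold recovery survives Poisson noise at 30 trials", {
  set.seed(77)
  ok <- 0
  n_units <- 15
  for (i in 1:n_units) {
    par <- list(a = runif(1, 8, 16), b = runif(1, 25, 55), c = runif(1, 4, 8),
                e = runif(1, 10, 40))
    par$d <- par$a + runif(1, 60, 150)
    par$f <- runif(1, par$b + 10, 85)
    mu <- rlf_model(levels10, par$a, par$b, par$c, par$d, par$e, par$f)
    noisy <- rpois(10 * 30, rep(mu * 0.04, each = 30)) / 0.04
    y <- colMeans(matrix(noisy, nrow = 30))
    fit_true <- fit_rlf(list(levels = levels10, rates = mu))
    fit_noisy <- fit_rlf(list(levels = levels10, rates = y))
    if (!is.na(fit_noisy$threshold_db) && !is.na(fit_true$threshold_db) &&
        abs(fit_noisy$threshold_db - fit_true$threshold_db) <= 5) ok <- ok + 1
  }
  expect_gte(ok / n_units, 0.9)
})
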