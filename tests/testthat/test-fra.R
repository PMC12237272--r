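test_that("Q is CF over linear bandwidth with flagged degenerate cases", {
  expect_equal(q_value(8, 4, 12), 1)
  expect_equal(q_value(8, 6, 10), 2)
  expect_true(is.na(q_value(8, 6, 6)))
  expect_error(q_value(8, 10, 6), "negative")
  # scale-free: multiplying all frequencies by s leaves Q unchanged
  s <- 3.7
  expect_equal(q_value(8 * s, 6 * s, 10 * s), q_value(8, 6, 10))
})

test_that("CF takes the minimum-threshold frequency with the documented tie
          rule", {
  freqs <- c(4, 8, 16)
  levels <- seq(20, 60, by = 10)
  # 8 kHz responds from 30 dB, 16 kHz from 40 dB: CF must be 8
  evoked <- list()
  for (l in c(30, 40, 50, 60)) evoked[[cell_key(8, l)]] <- 4
  for (l in c(40, 50, 60)) evoked[[cell_key(16, l)]] <- 4
  m <- toy_matrix(freqs, levels, evoked)
  met <- extract_fra_metrics(m)
  expect_true(met$resolved)
  expect_equal(met$cf, 8)
  expect_equal(met$min_threshold, 30)
  expect_false(met$tie)

  # tie at 30 dB: 16 kHz fires more spikes at threshold, so it wins
  evoked2 <- evoked
  for (l in c(30, 40, 50, 60)) evoked2[[cell_key(16, l)]] <- 8
  met2 <- suppressWarnings(extract_fra_metrics(toy_matrix(freqs, levels,
                                                          evoked2)))
  expect_true(met2$tie)
  expect_equal(met2$cf, 16)

  # equal rates: the lower frequency is returned
  evoked3 <- evoked
  for (l in c(30, 40, 50, 60)) evoked3[[cell_key(16, l)]] <- 4
  met3 <- suppressWarnings(extract_fra_metrics(toy_matrix(freqs, levels,
                                                          evoked3)))
  expect_true(met3$tie)
  expect_equal(met3$cf, 8)
})

test_that("silent units come back unresolved rather than erroring", {
  m <- toy_matrix(c(4, 8), c(30, 50), list())
  met <- extract_fra_metrics(m)
  expect_false(met$resolved)
  expect_true(is.na(met$cf))
  expect_error(bandwidth_at(m, met, 10), "unresolved")
})

test_that("bandwidth rows take the first and last evoked cells", {
  freqs <- c(2, 4, 8, 16, 32)
  levels <- seq(20, 70, by = 10)
  evoked <- list()
  for (l in levels[-1]) evoked[[cell_key(8, l)]] <- 5       # CF column
  for (f in c(4, 16)) for (l in c(50, 60, 70)) evoked[[cell_key(f, l)]] <- 3
  m <- toy_matrix(freqs, levels, evoked)
  met <- extract_fra_metrics(m)
  expect_equal(met$cf, 8)
  expect_equal(met$min_threshold, 30)

  # +10 dB row (40 dB): only the CF cell is evoked -> zero bandwidth
  bw10 <- met$bw[["+10"]]
  expect_equal(c(bw10$f_lo, bw10$f_hi), c(8, 8))
  expect_equal(bw10$flag, "zero_bandwidth")
  expect_true(is.na(met$q[["+10"]]))
  # +30 dB row (60 dB): evoked 4-16 kHz
  bw30 <- met$bw[["+30"]]
  expect_equal(c(bw30$f_lo, bw30$f_hi), c(4, 16))
  expect_equal(met$q[["+30"]], 8 / 12)
  # +40 dB row (70 dB) on-grid
  expect_equal(met$bw[["+40"]]$flag, "ok")

  # a unit whose threshold is high: +40 exceeds the grid -> unresolved
  evoked_hi <- list()
  for (l in c(40, 50, 60, 70)) evoked_hi[[cell_key(8, l)]] <- 5
  for (l in c(50, 60, 70)) evoked_hi[[cell_key(4, l)]] <- 3
  met_hi <- suppressWarnings(extract_fra_metrics(toy_matrix(freqs, levels,
                                                            evoked_hi)))
  expect_equal(met_hi$min_threshold, 40)
  expect_equal(met_hi$bw[["+40"]]$flag, "unresolved")
  # an off-grid row request falls back to the nearest row at or below
  bw_off <- bandwidth_at(toy_matrix(freqs, levels, evoked_hi), met_hi, 15)
  expect_equal(bw_off$level, 50)
  expect_equal(bw_off$flag, "off_grid")
  expect_equal(c(bw_off$f_lo, bw_off$f_hi), c(4, 8))
})

test_that("synthetic cohorts recover CF and threshold within one grid step", {
  co <- fixture_cohort("WT", 12, 3)
  mets <- fixture_metrics("WT", 12, 3)
  gstep <- diff(log2(default_grid()$freqs))[1]
  ok_cf <- ok_thr <- logical(12)
  for (i in 1:12) {
    m <- mets[[i]]; p <- co$params[[i]]
    ok_cf[i] <- m$resolved && abs(log2(m$cf / p$cf)) <= gstep + 1e-9
    ok_thr[i] <- m$resolved && abs(m$min_threshold - p$min_threshold) <= 10
  }
  expect_gte(mean(ok_cf), 0.9)
  expect_gte(mean(ok_thr), 0.9)
})

test_that("V-shaped tuning widens with level and sharpness falls with level", {
  mets <- fixture_metrics("WT", 12, 3)
  widen <- vapply(mets, function(m) {
    if (!m$resolved) return(NA)
    b10 <- m$bw[["+10"]]; b40 <- m$bw[["+40"]]
    if (is.na(b10$f_lo) || is.na(b40$f_lo)) return(NA)
    (b40$f_hi - b40$f_lo) >= (b10$f_hi - b10$f_lo)
  }, logical(1))
  expect_gte(mean(widen, na.rm = TRUE), 0.95)

  qmat <- vapply(mets, function(m)
    vapply(c("+10", "+20", "+30", "+40"), function(k)
      if (m$resolved && k %in% names(m$q)) m$q[[k]] else NA_real_,
      numeric(1)), numeric(4))
  qmean <- rowMeans(qmat, na.rm = TRUE)
  expect_true(all(diff(qmean) < 0))
})

test_that("broadened KO-like tuning lowers mean Q at every offset", {
  q_of <- function(label) {
    mets <- fixture_metrics(label, 12, 3)
    vapply(c("+10", "+20", "+30", "+40"), function(k)
      mean(vapply(mets, function(m)
        if (m$resolved && k %in% names(m$q)) m$q[[k]] else NA_real_,
        numeric(1)), na.rm = TRUE), numeric(1))
  }
  q_wt <- q_of("WT")
  q_ko <- q_of("KO-ACx")
  expect_true(all(q_ko < q_wt))
})
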