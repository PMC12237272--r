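mk_trials <- function(type, n, resp, freq = 8, level = 40) {
  data.frame(trial_type = type, freq_khz = freq, level_db = level,
             responded = resp, stringsAsFactors = FALSE)[rep(1, n), ]
}

test_that("session rates split hits and false alarms by trial type", {
  tr <- rbind(mk_trials("go", 70, 1), mk_trials("catch", 30, 0, freq = NA,
                                                level = NA))
  r <- compute_session_rates(tr)
  expect_equal(r$hit_rate, 1)
  expect_equal(r$fa_rate, 0)
  expect_equal(c(r$n_go, r$n_catch), c(70, 30))

  expect_error(compute_session_rates(mk_trials("catch", 5, 0)), "no go")
  expect_error(compute_session_rates(mk_trials("oops", 5, 0)), "unknown")

  # responses independent of trial type: hit ~ fa ~ p
  set.seed(8)
  p <- 0.4
  tr2 <- rbind(mk_trials("go", 500, 0), mk_trials("nogo", 500, 0))
  tr2$responded <- rbinom(1000, 1, p)
  r2 <- compute_session_rates(tr2)
  expect_lt(abs(r2$hit_rate - p), 3 * sqrt(p * (1 - p) / 500))
  expect_lt(abs(r2$fa_rate - p), 3 * sqrt(p * (1 - p) / 500))
})

test_that("d-prime matches the normal-quantile oracle and clipping rules", {
  expect_equal(dprime(0.5, 0.5, 100), 0)
  # z(0.9) + z(0.75)
  expect_equal(dprime(0.9, 0.25, 1e7, 1e7), qnorm(0.9) - qnorm(0.25),
               tolerance = 1e-3)
  expect_equal(dprime(0.9, 0.25, 1e7, 1e7), 1.956, tolerance = 1e-3)
  # perfect hit rate clipped to 1 - 1/(2*50) = 0.99
  expect_equal(dprime(1, 0.2, 50, 1e7), qnorm(0.99) - qnorm(0.2),
               tolerance = 1e-4)
  expect_error(dprime(0.5, 0.5, 0), "positive")
  expect_error(dprime(1.2, 0.5, 10), "0, 1")
})

test_that("d-prime is antisymmetric under swapping hit and FA rates", {
  set.seed(2)
  for (i in 1:25) {
    h <- runif(1); f <- runif(1); n <- sample(10:500, 2)
    expect_equal(dprime(h, f, n[1], n[2]), -dprime(f, h, n[2], n[1]),
                 tolerance = 1e-12)
  }
})

test_that("detection threshold interpolates the criterion crossing", {
  psy <- data.frame(level_db = c(20, 30), dprime = c(0.5, 2.5))
  expect_equal(detection_threshold(psy)$threshold_db, 25)

  none <- data.frame(level_db = c(20, 30, 40), dprime = c(0.2, 0.6, 1.2))
  res <- detection_threshold(none)
  expect_false(res$resolved)
  expect_true(is.na(res$threshold_db))

  high <- data.frame(level_db = c(20, 30), dprime = c(2, 3))
  expect_equal(detection_threshold(high)$threshold_db, 20)

  wobble <- data.frame(level_db = c(10, 20, 30, 40),
                       dprime = c(0.5, 2, 1, 2.5))
  expect_warning(res <- detection_threshold(wobble), "first")
  expect_equal(res$threshold_db, 10 + 10 * (1.5 - 0.5) / 1.5)

  expect_error(detection_threshold(psy[1, , drop = FALSE]), "two levels")
})

test_that("raising the d-prime curve weakly lowers the threshold", {
  set.seed(5)
  levels <- seq(10, 60, by = 10)
  for (i in 1:20) {
    d <- sort(runif(6, 0, 4))
    t1 <- detection_threshold(data.frame(level_db = levels, dprime = d))
    t2 <- detection_threshold(data.frame(level_db = levels,
                                         dprime = d + runif(1, 0, 1)))
    if (t1$resolved) {
      expect_true(t2$resolved)
      expect_lte(t2$threshold_db, t1$threshold_db + 1e-9)
    }
  }
})

test_that("false alarms bin by octave distance with the documented band
          edges", {
  go <- 8
  freqs <- go * 2^(c(1, 3, 4, 6, 8, 9, 12) / 12)
  tr <- do.call(rbind, lapply(freqs, function(f) mk_trials("nogo", 10, 1,
                                                           freq = f)))
  tr <- rbind(tr, mk_trials("go", 10, 1))
  fb <- fa_by_octave_band(tr, go)
  expect_true(all(fb$bands$fa_rate == 1))
  # 16 kHz is one octave away, in the far band
  fb2 <- fa_by_octave_band(rbind(mk_trials("nogo", 5, 1, freq = 16),
                                 mk_trials("go", 5, 1)), go)
  expect_equal(fb2$per_step$step_octaves, 1)
  expect_equal(as.character(fb2$bands$band[fb2$bands$n > 0]), "far")
  # 1/3- and 2/3-octave steps belong to the middle band
  fb3 <- fa_by_octave_band(rbind(mk_trials("nogo", 5, 1, freq = go * 2^(1/3)),
                                 mk_trials("nogo", 5, 1, freq = go * 2^(-2/3)),
                                 mk_trials("go", 5, 1)), go)
  expect_equal(as.character(fb3$bands$band[fb3$bands$n > 0]), "middle")
  expect_equal(fb3$bands$n[fb3$bands$band == "middle"], 10)
})

test_that("band means equal trial-weighted averages of the per-step curve", {
  bp <- behavior_gen_params(n_trials = 600)
  tr <- gen_behavior_session(bp, "discrimination", seed = 31)
  fb <- fa_by_octave_band(tr, bp$go_freq)
  band_of <- function(s) ifelse(s < 1 / 3 - 1e-9, "near",
                                ifelse(s <= 2 / 3 + 1e-9, "middle", "far"))
  ps <- fb$per_step
  ps$band <- band_of(ps$step_octaves)
  manual <- tapply(ps$fa_rate * ps$n, ps$band, sum) /
    tapply(ps$n, ps$band, sum)
  for (b in names(manual)) {
    expect_equal(fb$bands$fa_rate[fb$bands$band == b], unname(manual[b]),
                 tolerance = 1e-12)
  }
})

test_that("generated sigmoidal FA curves order the three bands", {
  bp <- behavior_gen_params(fa_midpoint = 0.5, n_trials = 600)
  fam <- vapply(1:20, function(s) {
    tab <- gen_behavior_session(bp, "discrimination", seed = 200 + s)
    fb <- fa_by_octave_band(tab, bp$go_freq)
    v <- fb$bands$fa_rate[match(c("near", "middle", "far"), fb$bands$band)]
    v
  }, numeric(3))
  m <- rowMeans(fam)
  expect_gt(m[1], m[2])
  expect_gt(m[2], m[3])
})

test_that("detection thresholds recover the generative psychometric", {
  bp <- behavior_gen_params()
  truth <- gen_threshold_level(bp, criterion = 1.5)
  thr <- vapply(1:20, function(s) {
    tab <- gen_behavior_session(bp, "detection", seed = s,
                                session_id = sprintf("s%d", s))
    detection_threshold(psychometric_table(tab))$threshold_db
  }, numeric(1))
  expect_lt(abs(mean(thr) - truth), 2.5)
})
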