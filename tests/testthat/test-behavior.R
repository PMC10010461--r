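# --- press detection -------------------------------------------------------

test_that("a silent trace yields no presses", {
  trace <- matrix(0, 2000, 10)
  expect_equal(nrow(detect_presses(trace, threshold = 1)), 0)
})

test_that("a ramp crossing threshold at a known time is detected there", {
  # flat baseline for 600 ms, then a linear ramp reaching 1 N at t = 1000 ms;
  # Gaussian smoothing preserves linear segments so the onset shift is small
  t <- seq_len(3000)
  force <- pmax(0, (t - 600) / 400)
  trace <- matrix(0, 3000, 10)
  trace[, 3] <- force
  presses <- detect_presses(trace, threshold = 1)
  expect_equal(nrow(presses), 1)
  expect_equal(presses$channel, 3)
  expect_lt(abs(presses$onset_ms - 1000), 60)
})

test_that("sub-threshold peaks are not detected and detection is monotone in threshold", {
  t <- seq_len(2000)
  trace <- matrix(0, 2000, 2)
  trace[, 1] <- 2.0 * exp(-(t - 1200)^2 / (2 * 80^2))
  expect_equal(nrow(detect_presses(trace, threshold = 2.5)), 0)
  expect_equal(nrow(detect_presses(trace, threshold = 1)), 1)
  set.seed(7)
  noisy <- matrix(abs(stats::rnorm(3000 * 3, 0, 0.8)), 3000, 3)
  counts <- vapply(c(0.5, 1, 1.5, 2.5), function(th)
    nrow(detect_presses(noisy, threshold = th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("a press episode ends only when force falls below threshold", {
  trace <- matrix(0, 4000, 1)
  trace[1000:1400, 1] <- 3   # one sustained press
  trace[2000:2300, 1] <- 3   # a second, separate press
  presses <- detect_presses(trace, threshold = 1)
  expect_equal(nrow(presses), 2)
  # merging the episodes (no below-threshold gap) yields a single press
  trace[1400:2000, 1] <- 3
  expect_equal(nrow(detect_presses(trace, threshold = 1)), 1)
})

test_that("synthetic force traces round-trip through press detection", {
  times <- c(300, 1500, 2310, 2660, 3310)
  fingers <- c(1, 3, 5, 2, 4)
  trace <- simulate_force_trace(times, fingers, peak_force = 3)
  presses <- detect_presses(trace, threshold = 1)
  expect_equal(nrow(presses), 5)
  expect_equal(presses$channel, fingers)
  # onsets (cue-relative) near the nominal press times
  expect_true(all(abs(presses$onset_ms - 500 - times) < 40))
})

test_that("traces shorter than the baseline window are rejected", {
  expect_error(detect_presses(matrix(0, 300, 10)), "baseline")
})

# --- interpress intervals --------------------------------------------------

test_that("IPIs are consecutive press-time differences", {
  expect_equal(compute_ipis(c(0, 1200, 2010, 2360, 3010)), TIMING1)
  expect_equal(compute_ipis(cumsum(c(0, TIMING2))), TIMING2)
  expect_equal(compute_ipis(seq(0, 2000, by = 500)), rep(500, 4))
})

test_that("wrong press counts and non-monotone times are rejected", {
  expect_error(compute_ipis(c(0, 100, 200, 300)), "exactly 5")
  expect_error(compute_ipis(c(0, 100, 90, 300, 400)), "increasing")
})

# --- timing error ----------------------------------------------------------

test_that("timing error is zero at target and under uniform tempo scaling", {
  expect_equal(timing_error(TIMING1, TIMING1, 3010)$cumulative, 0)
  # a participant playing 10% slow overall, normalized by their own length
  expect_equal(timing_error(TIMING1 * 1.1, TIMING1 * 1.1, 3010 * 1.1)$cumulative,
               timing_error(TIMING1, TIMING1, 3010)$cumulative)
  scaled <- timing_error(TIMING1 * 1.1, TIMING1, 3010)
  rescaled <- timing_error(TIMING1 * 2.2, TIMING1 * 2, 6020)
  expect_equal(scaled$cumulative, rescaled$cumulative)
})

test_that("cumulative deviation matches the normalization formula", {
  res <- timing_error(c(1300, 810, 350, 650), TIMING1, 3010)
  expect_equal(res$cumulative, 100 / 3010 * 100)
  expect_equal(res$per_interval, c(100, 0, 0, 0) / 3010 * 100)
  expect_error(timing_error(TIMING1, TIMING1, 0), "positive")
  expect_error(timing_error(TIMING1[1:3], TIMING1, 3010), "length 4")
})

# --- trial scoring ---------------------------------------------------------

perfect_trial <- function(rt = 150, dev = 0, fingers = c(1, 3, 5, 2, 4)) {
  target <- sequence_spec(c(1, 3, 5, 2, 4), TIMING1)
  list(trial_type = "memory", rt = rt,
       press_times = rt + cumsum(c(0, TIMING1 * (1 + dev / 100))),
       press_fingers = fingers, target = target)
}

test_that("reaction-time and timing points follow the printed bands", {
  rts <- c(100, 199, 200, 359, 360, 479, 480, 559, 560, 599, 600, 1000)
  rt_pts <- c(5, 5, 4, 4, 3, 3, 2, 2, 1, 1, 0, 0)
  for (i in seq_along(rts))
    expect_equal(score_trial(perfect_trial(rt = rts[i])), 5 + rt_pts[i],
                 info = paste("rt", rts[i]))
  devs <- c(5, 9.9, 10, 15, 25, 35, 45, 55)
  dev_pts <- c(5, 5, 4, 4, 3, 2, 1, 0)
  for (i in seq_along(devs))
    expect_equal(score_trial(perfect_trial(rt = 100, dev = devs[i])),
                 5 + dev_pts[i], info = paste("dev", devs[i]))
})

test_that("worked scoring examples give the documented totals", {
  expect_equal(score_trial(perfect_trial(rt = 150, dev = 5)), 10)
  wrong <- perfect_trial(rt = 150, dev = 0)
  wrong$press_fingers <- c(1, 3, 5, 4, 2)
  expect_equal(score_trial(wrong), 0)
  expect_equal(score_trial(list(trial_type = "nogo", press_times = NULL)), 5)
  expect_equal(score_trial(list(trial_type = "nogo", press_times = 1200)), 0)
  expect_equal(score_trial(perfect_trial(), prep_force_exceeded = TRUE), 0)
  expect_error(score_trial(list(trial_type = "memory", press_times = 1:5 * 100,
                                press_fingers = c(1, 3, 5, 2, 4), rt = NA,
                                target = spec_t1())),
               "reaction time")
})

test_that("points are monotone non-increasing in RT and timing deviation", {
  pts_rt <- vapply(seq(0, 800, by = 40), function(r)
    score_trial(perfect_trial(rt = r)), integer(1))
  expect_true(all(diff(pts_rt) <= 0))
  pts_dev <- vapply(seq(0, 70, by = 5), function(d)
    score_trial(perfect_trial(rt = 100, dev = d)), integer(1))
  expect_true(all(diff(pts_dev) <= 0))
  expect_true(all(c(pts_rt, pts_dev) >= 0 & c(pts_rt, pts_dev) <= 10))
})

# --- behavioral simulation -------------------------------------------------

test_that("noise-free simulated trials hit target IPIs exactly", {
  tr <- simulate_behavior(spec_t1(), 10, ipi_jitter_sd = 0, error_rate = 0,
                          seed = 1)
  for (i in seq_len(nrow(tr))) {
    pt <- as.numeric(tr[i, paste0("press", 1:5, "_time")])
    expect_equal(compute_ipis(pt), TIMING1)
  }
  expect_false(any(tr$error))
})

test_that("forced errors score zero downstream and No-Go trials have no presses", {
  tr <- simulate_behavior(spec_t1(), 20, error_rate = 1, seed = 3)
  expect_true(all(tr$error))
  pts <- vapply(seq_len(nrow(tr)), function(i) {
    score_trial(list(trial_type = tr$trial_type[i], rt = tr$rt[i],
                     press_times = as.numeric(tr[i, paste0("press", 1:5, "_time")]),
                     press_fingers = as.integer(tr[i, paste0("press", 1:5, "_finger")]),
                     target = spec_t1()))
  }, integer(1))
  expect_true(all(pts == 0))
  ng <- simulate_behavior(spec_t1(), 6, trial_type = "nogo", seed = 2)
  expect_true(all(is.na(ng$press1_time)))
})

test_that("mean timing error under jitter matches the half-normal oracle", {
  sd_ms <- 50; n <- 500
  tr <- simulate_behavior(spec_t1(), n, ipi_jitter_sd = sd_ms, seed = 8)
  ipis <- t(apply(tr[, paste0("press", 1:5, "_time")], 1,
                  function(p) compute_ipis(as.numeric(p))))
  avg_len <- mean(rowSums(ipis))
  errs <- vapply(seq_len(n), function(i)
    timing_error(ipis[i, ], TIMING1, avg_len)$cumulative, numeric(1))
  # each interval deviates by |N(0, sd)|, mean sd*sqrt(2/pi); four intervals
  expected <- 4 * sd_ms * sqrt(2 / pi) / avg_len * 100
  se <- stats::sd(errs) / sqrt(n)
  expect_lt(abs(mean(errs) - expected), 3 * se)
})

test_that("simulation rejects invalid noise and error parameters", {
  expect_error(simulate_behavior(spec_t1(), 5, ipi_jitter_sd = -1), ">= 0")
  expect_error(simulate_behavior(spec_t1(), 5, error_rate = 1.5), "\\[0, 1\\]")
})

test_that("sequence specs enforce shape and shared first finger", {
  expect_error(sequence_spec(1:4, TIMING1), "length 5")
  expect_error(sequence_spec(1:5, TIMING1[1:3]), "length 4")
  seqs <- default_sequences()
  expect_equal(seqs[[1]][[1]]$target_ipis, TIMING1)
  expect_equal(seqs[[2]][[2]]$target_ipis, TIMING2)
  firsts <- c(seqs[[1]][[1]]$finger_order[1], seqs[[2]][[1]]$finger_order[1])
  expect_equal(firsts[1], firsts[2])
  expect_error(default_sequences(list(c(1, 2, 3, 4, 5), c(2, 1, 3, 4, 5))),
               "same finger")
})
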