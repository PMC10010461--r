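# Shared fixtures for the test suite. Everything is generated in code.

TIMING1 <- c(1200, 810, 350, 650)
TIMING2 <- c(350, 1200, 650, 810)

spec_t1 <- function() sequence_spec(c(1L, 3L, 5L, 2L, 4L), TIMING1)
spec_t2 <- function() sequence_spec(c(1L, 3L, 5L, 2L, 4L), TIMING2)

tiny_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_voxels = 40L, order_amp = 1, timing_amp = 1,
                   integ_amp = 0, run_sd = 0.5, noise_sd = 0.5, seed = 1L)
  defaults[names(args)] <- args
  do.call(sim_config, defaults)
}

# Mean decoding z (and accuracy) over replicate simulated datasets.
mc_decode <- function(n_rep, scheme, base_seed = 100L, ...) {
  vals <- vapply(seq_len(n_rep), function(i) {
    ds <- simulate_patterns(tiny_cfg(seed = base_seed + i, ...))
    res <- decode(ds, scheme)
    c(res$z, res$accuracy)
  }, numeric(2))
  list(z = vals[1, ], accuracy = vals[2, ])
}

# A small event table for one run: n_per Go and n_per No-Go trials per
# condition. Onsets and reaction times cycle through jittered values, as in
# the paradigm, which keeps the regressors estimable.
make_events <- function(n_per = 2L) {
  grid <- expand.grid(order = 1:2, timing = 1:2)
  gaps <- c(10, 13, 11, 14)
  rts <- c(0.25, 0.4, 0.3, 0.45)
  rows <- list()
  k <- 0L; onset <- 5
  for (i in seq_len(nrow(grid))) {
    for (j in seq_len(n_per)) {
      for (go in c(TRUE, FALSE)) {
        k <- k + 1L
        rt <- rts[(k - 1L) %% 4L + 1L]
        rows[[k]] <- data.frame(onset = onset, order = grid$order[i],
                                timing = grid$timing[i], go = go,
                                first_press = if (go) onset + 2.5 + rt else NA_real_,
                                error = FALSE)
        onset <- onset + gaps[(k - 1L) %% 4L + 1L]
      }
    }
  }
  do.call(rbind, rows)
}

# One simulated subject end to end: planted voxel patterns -> event
# schedule -> BOLD synthesis -> per-run GLM -> beta collection -> decoding.
simulate_subject_z <- function(seed, integ_amp = 0, order_amp = 1,
                               timing_amp = 1, n_voxels = 40,
                               bold_noise = 0.3) {
  ds <- simulate_patterns(sim_config(
    n_voxels = n_voxels, order_amp = order_amp, timing_amp = timing_amp,
    integ_amp = integ_amp, run_sd = 0.3, noise_sd = 0.2, seed = seed))
  ev <- make_events(n_per = 2)
  dm <- build_design(ev, n_scans = 100, TR = 2)
  fits <- lapply(1:6, function(r) {
    rows <- which(ds$run == r)
    B <- ds$betas[rows, , drop = FALSE]
    rownames(B) <- sprintf("prod_o%dt%d", ds$order[rows], ds$timing[rows])
    Y <- simulate_bold(dm, B, noise_sd = bold_noise, seed = seed * 100 + r)
    fit_glm(Y, dm)
  })
  betas <- collect_run_betas(fits, phase = "prod")
  c(order = decode(betas, "order")$z,
    timing = decode(betas, "timing")$z,
    integrated = decode(betas, "integrated")$z)
}
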