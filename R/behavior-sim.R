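#' Simulate behavioral trials for one target sequence
#'
#' Generates trial records with presses jittered around the target timing
#' structure: on correct Go trials the five presses follow the target finger
#' order with IPIs equal to target plus Gaussian jitter, initiated after a
#' Gaussian reaction time; on error trials one press at a random position is
#' replaced by a wrong finger; No-Go trials contain no presses.
#'
#' @param spec A [sequence_spec()].
#' @param n_trials Number of trials.
#' @param ipi_jitter_sd SD of the Gaussian jitter added to each target IPI
#'   (ms, >= 0).
#' @param rt_mean,rt_sd Mean and SD of the initiation reaction time (ms).
#' @param error_rate Probability that a Go trial contains a wrong finger.
#' @param trial_type Either a single type recycled to all trials or a
#'   length-`n_trials` vector with entries `"instructed"`, `"memory"` or
#'   `"nogo"`. Default `"memory"`.
#' @param seed Integer RNG seed.
#' @return A data frame with one row per trial: `trial`, `trial_type`,
#'   `error`, `rt` (ms), `press1_time` .. `press5_time` (ms from Go cue),
#'   `press1_finger` .. `press5_finger`; press columns are `NA` on No-Go
#'   trials.
#' @export
simulate_behavior <- function(spec, n_trials, ipi_jitter_sd = 0,
                              rt_mean = 300, rt_sd = 0, error_rate = 0,
                              trial_type = "memory", seed = 1L) {
  if (!inherits(spec, "sequence_spec")) stop("'spec' must be a sequence_spec")
  if (ipi_jitter_sd < 0) stop("'ipi_jitter_sd' must be >= 0")
  if (rt_sd < 0) stop("'rt_sd' must be >= 0")
  if (error_rate < 0 || error_rate > 1) stop("'error_rate' must be in [0, 1]")
  n_trials <- as.integer(n_trials)
  trial_type <- rep_len(trial_type, n_trials)
  if (!all(trial_type %in% c("instructed", "memory", "nogo")))
    stop("unknown trial type")

  with_seed(seed, {
    rows <- lapply(seq_len(n_trials), function(i) {
      rec <- data.frame(trial = i, trial_type = trial_type[i], error = FALSE,
                        rt = NA_real_, stringsAsFactors = FALSE)
      pt <- rep(NA_real_, 5); pf <- rep(NA_integer_, 5)
      if (trial_type[i] != "nogo") {
        rt <- max(1, stats::rnorm(1, rt_mean, rt_sd))
        ipis <- spec$target_ipis + stats::rnorm(4, 0, ipi_jitter_sd)
        ipis <- pmax(ipis, 1)  # presses must stay strictly ordered
        pt <- rt + cumsum(c(0, ipis))
        pf <- spec$finger_order
        if (stats::runif(1) < error_rate) {
          pos <- sample.int(5, 1)
          wrong <- setdiff(1:5, spec$finger_order[pos])
          pf[pos] <- wrong[sample.int(length(wrong), 1)]
          rec$error <- TRUE
        }
        rec$rt <- rt
      }
      for (k in 1:5) {
        rec[[paste0("press", k, "_time")]] <- pt[k]
        rec[[paste0("press", k, "_finger")]] <- pf[k]
      }
      rec
    })
    do.call(rbind, rows)
  })
}

#' Synthesize a force trace from press events
#'
#' Builds a multi-channel force recording like the ones produced by a
#' 10-channel force-transducer keyboard sampled at 1000 Hz: each press is a
#' smooth unimodal force pulse on its finger's channel, rising through the
#' detection threshold near the nominal press time, on top of a baseline
#' offset and optional sensor noise. Useful for exercising
#' [detect_presses()] on ground-truth events.
#'
#' @param press_times Press times in ms relative to the Sequence cue.
#' @param press_fingers Channel (finger) index of each press.
#' @param n_channels Number of channels (default 10).
#' @param duration_ms Total trace length in ms, including the baseline.
#' @param baseline_ms Pre-cue baseline length (default 500 ms).
#' @param peak_force Peak force of each press pulse in Newton.
#' @param press_width_ms Approximate rise time (ms) from rest to peak.
#' @param baseline_force Constant resting force per channel (N).
#' @param noise_sd Sensor noise SD (N).
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @return A numeric matrix (`duration_ms` rows x `n_channels` columns) of
#'   forces in Newton; time 0 of the Sequence cue corresponds to row
#'   `baseline_ms + 1`.
#' @export
simulate_force_trace <- function(press_times, press_fingers,
                                 n_channels = 10L, duration_ms = NULL,
                                 baseline_ms = 500, peak_force = 3,
                                 press_width_ms = 60, baseline_force = 0.1,
                                 noise_sd = 0, seed = 1L) {
  press_times <- as.numeric(press_times)
  press_fingers <- as.integer(press_fingers)
  if (length(press_times) != length(press_fingers))
    stop("'press_times' and 'press_fingers' must have equal length")
  if (length(press_fingers) && max(press_fingers) > n_channels)
    stop("finger index exceeds 'n_channels'")
  if (is.null(duration_ms))
    duration_ms <- baseline_ms + (if (length(press_times))
      max(press_times) else 0) + 1000
  t <- seq_len(duration_ms)
  trace <- matrix(baseline_force, duration_ms, n_channels)
  for (k in seq_along(press_times)) {
    onset <- baseline_ms + press_times[k]
    # raised-cosine pulse peaking press_width_ms after onset
    pulse <- peak_force * 0.5 *
      (1 - cos(pi * pmin(pmax(t - onset, 0), 2 * press_width_ms) / press_width_ms))
    pulse[t - onset > 2 * press_width_ms] <- 0
    trace[, press_fingers[k]] <- trace[, press_fingers[k]] + pulse
  }
  if (noise_sd > 0)
    trace <- trace + with_seed(seed,
      matrix(stats::rnorm(length(trace), 0, noise_sd), nrow(trace)))
  trace
}
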