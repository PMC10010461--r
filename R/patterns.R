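#' Configuration for the synthetic pattern generator
#'
#' Bundles the parameters of the generative model behind
#' [simulate_patterns()]: a fully crossed order-by-timing design measured in
#' several imaging runs, with additive feature components, a pure-interaction
#' (integration) component, additive run effects and observation noise.
#'
#' @param n_orders,n_timings Number of levels of the finger-order and timing
#'   factors. The decoding machinery assumes the 2 x 2 design used throughout;
#'   both default to 2.
#' @param n_runs Number of imaging runs (default 6).
#' @param n_voxels Number of voxels (features) per pattern.
#' @param order_amp,timing_amp Amplitudes (signal units, per-voxel SD) of the
#'   additive order and timing pattern components.
#' @param integ_amp Amplitude of the per-condition interaction component
#'   before double-centering. Double-centering a 2 x 2 grid of i.i.d. patterns
#'   halves the per-voxel SD of what remains, so the effective interaction SD
#'   is `integ_amp / 2`.
#' @param mean_amp Amplitude of the grand-mean pattern shared by all rows.
#' @param run_sd SD of the additive per-run pattern shared across conditions.
#' @param noise_sd SD of the i.i.d. Gaussian observation noise.
#' @param noise_rho Optional AR(1) correlation of the noise across neighboring
#'   voxels (0 = white noise, the default).
#' @param seed Integer RNG seed; the same seed reproduces the dataset
#'   bit-identically.
#'
#' @return An object of class `"sim_config"` (a validated list).
#' @seealso [simulate_patterns()]
#' @export
sim_config <- function(n_orders = 2L, n_timings = 2L, n_runs = 6L,
                       n_voxels = 160L,
                       order_amp = 1, timing_amp = 1, integ_amp = 0,
                       mean_amp = 1, run_sd = 0.5, noise_sd = 0.5,
                       noise_rho = 0, seed = 1L) {
  cfg <- list(n_orders = as.integer(n_orders),
              n_timings = as.integer(n_timings),
              n_runs = as.integer(n_runs),
              n_voxels = as.integer(n_voxels),
              order_amp = order_amp, timing_amp = timing_amp,
              integ_amp = integ_amp, mean_amp = mean_amp,
              run_sd = run_sd, noise_sd = noise_sd, noise_rho = noise_rho,
              seed = as.integer(seed))
  if (cfg$n_orders < 2L || cfg$n_timings < 2L || cfg$n_runs < 2L)
    stop("factor dimensions ('n_orders', 'n_timings', 'n_runs') must all be >= 2")
  if (is.na(cfg$n_voxels) || cfg$n_voxels < 1L)
    stop("'n_voxels' must be a positive integer")
  amps <- c(cfg$order_amp, cfg$timing_amp, cfg$integ_amp, cfg$mean_amp)
  if (any(amps < 0)) stop("pattern amplitudes must be >= 0")
  if (cfg$run_sd < 0 || cfg$noise_sd < 0) stop("SDs must be >= 0")
  if (cfg$noise_rho < 0 || cfg$noise_rho >= 1)
    stop("'noise_rho' must lie in [0, 1)")
  structure(cfg, class = "sim_config")
}

#' Construct a condition-by-run pattern dataset
#'
#' A `pattern_dataset` holds one beta pattern (row) per condition-by-run cell
#' together with its factor labels. Every (order, timing, run) cell must
#' appear exactly once.
#'
#' @param betas Numeric matrix, one row per condition-run cell, one column
#'   per voxel.
#' @param order,timing,run Integer factor labels, one per row.
#' @return An object of class `"pattern_dataset"`.
#' @export
pattern_dataset <- function(betas, order, timing, run) {
  betas <- as.matrix(betas)
  order <- as.integer(order); timing <- as.integer(timing); run <- as.integer(run)
  n <- nrow(betas)
  if (length(order) != n || length(timing) != n || length(run) != n)
    stop("factor labels must each have one entry per row of 'betas'")
  if (anyNA(betas) || anyNA(order) || anyNA(timing) || anyNA(run))
    stop("pattern dataset must not contain missing values")
  cells <- paste(order, timing, run, sep = ":")
  if (anyDuplicated(cells))
    stop("each (order, timing, run) cell must appear exactly once")
  expected <- length(unique(order)) * length(unique(timing)) * length(unique(run))
  if (n != expected)
    stop("incomplete design: expected ", expected, " rows, got ", n)
  structure(list(betas = betas, order = order, timing = timing, run = run),
            class = "pattern_dataset")
}

#' @export
print.pattern_dataset <- function(x, ...) {
  cat("pattern_dataset:",
      length(unique(x$order)), "orders x",
      length(unique(x$timing)), "timings x",
      length(unique(x$run)), "runs,",
      ncol(x$betas), "voxels\n")
  invisible(x)
}

#' @export
dim.pattern_dataset <- function(x) dim(x$betas)

# Run a block of code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# AR(1)-correlated Gaussian noise across the voxel dimension.
ar1_noise <- function(n, p, sd, rho) {
  z <- matrix(stats::rnorm(n * p), n, p)
  if (rho > 0 && p > 1) {
    for (j in 2:p) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
  }
  z * sd
}

#' Simulate condition-by-run voxel patterns with known ground truth
#'
#' Generates beta patterns for a fully crossed order-by-timing design over
#' several runs. Each row is the sum of: a grand-mean pattern; an additive
#' order component (one fixed random pattern per order level, scaled by
#' `order_amp`); an additive timing component; an interaction component built
#' by drawing one random pattern per condition and double-centering across the
#' 2 x 2 factor grid so that its marginal means over orders (at fixed timing)
#' and over timings (at fixed order) are exactly zero; an additive per-run
#' pattern shared across conditions; and i.i.d. (optionally AR(1)-correlated)
#' Gaussian noise. All structural components are drawn once and shared across
#' runs, so genuine signal generalizes across runs while run effects and
#' noise do not.
#'
#' With `integ_amp = 0` the four condition means are exactly additive in order
#' and timing, so the integrated (residual) classifier has nothing to decode:
#' this is the null used to validate the specificity of integration decoding.
#'
#' @param cfg A [sim_config()].
#' @return A [pattern_dataset()] with `n_orders * n_timings * n_runs` rows.
#'   The ground-truth components are attached as attribute `"truth"` (a list
#'   with elements `mean`, `order_patterns`, `timing_patterns`,
#'   `interaction_patterns`, `run_patterns`).
#' @examples
#' ds <- simulate_patterns(sim_config(n_voxels = 40, seed = 7))
#' dim(ds)
#' @export
simulate_patterns <- function(cfg) {
  if (!inherits(cfg, "sim_config")) cfg <- do.call(sim_config, cfg)
  p <- cfg$n_voxels
  with_seed(cfg$seed, {
    grand <- stats::rnorm(p) * cfg$mean_amp
    ord_pat <- matrix(stats::rnorm(cfg$n_orders * p), cfg$n_orders, p) * cfg$order_amp
    tim_pat <- matrix(stats::rnorm(cfg$n_timings * p), cfg$n_timings, p) * cfg$timing_amp
    # one raw pattern per condition, then double-center across the factor grid
    raw <- array(stats::rnorm(cfg$n_orders * cfg$n_timings * p),
                 dim = c(cfg$n_orders, cfg$n_timings, p)) * cfg$integ_amp
    om <- apply(raw, c(1, 3), mean)              # order x voxel marginals
    tm <- apply(raw, c(2, 3), mean)              # timing x voxel marginals
    gm <- apply(raw, 3, mean)                    # grand marginal
    inter <- raw
    for (o in seq_len(cfg$n_orders))
      for (t in seq_len(cfg$n_timings))
        inter[o, t, ] <- raw[o, t, ] - om[o, ] - tm[t, ] + gm
    run_pat <- matrix(stats::rnorm(cfg$n_runs * p), cfg$n_runs, p) * cfg$run_sd

    grid <- expand.grid(order = seq_len(cfg$n_orders),
                        timing = seq_len(cfg$n_timings),
                        run = seq_len(cfg$n_runs))
    n <- nrow(grid)
    betas <- matrix(0, n, p)
    for (i in seq_len(n)) {
      o <- grid$order[i]; t <- grid$timing[i]; r <- grid$run[i]
      betas[i, ] <- grand + ord_pat[o, ] + tim_pat[t, ] + inter[o, t, ] + run_pat[r, ]
    }
    betas <- betas + ar1_noise(n, p, cfg$noise_sd, cfg$noise_rho)
    ds <- pattern_dataset(betas, grid$order, grid$timing, grid$run)
    attr(ds, "truth") <- list(mean = grand, order_patterns = ord_pat,
                              timing_patterns = tim_pat,
                              interaction_patterns = inter,
                              run_patterns = run_pat)
    ds
  })
}
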