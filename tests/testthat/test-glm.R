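# --- HRF -------------------------------------------------------------------

test_that("canonical HRF has the expected shape", {
  h <- canonical_hrf(0.01)
  expect_equal(h[1], 0)
  expect_gt(sum(h), 0)
  expect_equal(max(h), 1)
  peak_s <- (which.max(h) - 1) * 0.01
  expect_lt(abs(peak_s - 5), 0.25)
  # undershoot minimum around 15 s
  trough_s <- (which.min(h) - 1) * 0.01
  expect_lt(abs(trough_s - 15), 1.5)
  expect_error(canonical_hrf(0), "> 0")
})

# --- design construction ---------------------------------------------------

test_that("regressor bookkeeping follows the scheme", {
  ev <- make_events(n_per = 2)
  dm <- build_design(ev, n_scans = 120, TR = 2)
  # 4 conditions x (prep + prod) + go_prep, doubled by derivatives, + intercept
  expect_equal(ncol(dm$X), (4 * 2 + 1) * 2 + 1)
  expect_false(anyDuplicated(colnames(dm$X)) > 0)
  task <- dm$X[, grep("^(prep|prod)_", colnames(dm$X))]
  expect_true(all(colSums(abs(task)) > 0))
  # with error trials present, the error regressor family appears
  ev2 <- ev
  ev2$error[1] <- TRUE
  ev2$trial_end <- ev2$onset + 10
  dm2 <- build_design(ev2, n_scans = 120, TR = 2)
  expect_true(all(c("err", "d_err") %in% colnames(dm2$X)))
  expect_error(build_design(within(ev, error <- TRUE), 120), "trial_end")
})

test_that("a constant-impulse regressor is the HRF shifted to press onset", {
  ev <- data.frame(onset = 4, order = 1, timing = 1, go = TRUE,
                   first_press = 8, error = FALSE)
  expect_warning(dm <- build_design(ev, n_scans = 40, TR = 2,
                                    derivatives = FALSE),
                 "preparation regressor omitted")
  reg <- dm$X[, "prod_o1t1"]
  h <- canonical_hrf(2 / 16)
  scan_t <- (seq_len(40) - 1) * 2
  expected <- vapply(scan_t, function(ts) {
    lag <- ts - 8
    if (lag < 0 || lag > 32) 0 else h[round(lag / (2 / 16)) + 1]
  }, numeric(1))
  expect_equal(unname(reg), expected, tolerance = 1e-10)
})

test_that("empty conditions are warned about and omitted", {
  ev <- make_events(n_per = 1)
  ev <- ev[!(ev$order == 2 & ev$timing == 2 & !ev$go), ]  # drop one prep cell
  expect_warning(dm <- build_design(ev, n_scans = 120, TR = 2),
                 "o2t2.*preparation")
  expect_false("prep_o2t2" %in% colnames(dm$X))
  expect_true("prod_o2t2" %in% colnames(dm$X))
})

test_that("event tables round-trip through TSV unchanged", {
  ev <- make_events(n_per = 2)
  path <- tempfile(fileext = ".tsv")
  write_trials_tsv(ev, path)
  back <- read_trials_tsv(path)
  expect_equal(back, ev, tolerance = 1e-12)
  d1 <- build_design(ev, n_scans = 120)$X
  d2 <- build_design(back, n_scans = 120)$X
  expect_equal(d1, d2)
})

# --- GLM estimation --------------------------------------------------------

test_that("noiseless data recover betas to machine precision", {
  ev <- make_events(n_per = 2)
  dm <- build_design(ev, n_scans = 120)
  set.seed(1)
  B <- matrix(stats::rnorm(ncol(dm$X) * 6), ncol(dm$X), 6,
              dimnames = list(colnames(dm$X), NULL))
  fit <- fit_glm(dm$X %*% B, dm)
  expect_lt(max(abs(fit$betas - B)), 1e-10)
  expect_lt(max(fit$sigma2), 1e-20)
})

test_that("beta RMSE scales linearly with the noise SD (OLS theory)", {
  ev <- make_events(n_per = 2)
  dm <- build_design(ev, n_scans = 120)
  B <- matrix(0, ncol(dm$X), 30, dimnames = list(colnames(dm$X), NULL))
  rmse_at <- function(sd, seed) {
    Y <- simulate_bold(dm, B[1, , drop = FALSE] * 0 + 0, noise_sd = sd,
                       seed = seed)
    sqrt(mean(fit_glm(Y, dm)$betas^2))
  }
  r1 <- mean(vapply(1:10, function(s) rmse_at(0.5, s), numeric(1)))
  r2 <- mean(vapply(1:10, function(s) rmse_at(1.0, s + 100), numeric(1)))
  expect_lt(abs(r2 / r1 - 2), 0.25)
})

test_that("voxel permutation equivariance holds", {
  ev <- make_events(n_per = 2)
  dm <- build_design(ev, n_scans = 120)
  Y <- simulate_bold(dm, matrix(1, 1, 8, dimnames = list("prod_o1t1", NULL)),
                     noise_sd = 1, seed = 4)
  perm <- c(3, 1, 8, 2, 5, 7, 4, 6)
  f1 <- fit_glm(Y, dm)
  f2 <- fit_glm(Y[, perm], dm)
  expect_equal(f2$betas, f1$betas[, perm])
})

test_that("rank deficiency is reported with the collinear column names", {
  X <- cbind(a = rnorm(20), b = rnorm(20))
  X <- cbind(X, c = X[, "a"] + X[, "b"])
  expect_error(fit_glm(matrix(rnorm(20), 20, 1), X),
               "rank deficient.*c")
})
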