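# --- ROI one-sample tests --------------------------------------------------

test_that("all-zero values give t = 0 and adjusted p = 1", {
  res <- one_sample_tests(matrix(0, 10, 3))
  expect_true(all(res$t == 0))
  expect_true(all(res$p_adj == 1))
  expect_true(all(res$degenerate))
})

test_that("constant nonzero values are flagged as degenerate, not NaN", {
  res <- one_sample_tests(matrix(1, 10, 2))
  expect_true(all(res$degenerate))
  expect_true(all(is.na(res$t)))
  expect_false(any(is.nan(unlist(res[, c("t", "p", "d")]))))
})

test_that("statistics match t.test and Bonferroni is min(1, 6p)", {
  set.seed(31)
  m <- matrix(stats::rnorm(24 * 4, mean = 0.3), 24, 4)
  res <- one_sample_tests(m, n_corrections = 6)
  for (j in 1:4) {
    tt <- stats::t.test(m[, j])
    expect_equal(res$t[j], unname(tt$statistic))
    expect_equal(res$p[j], tt$p.value)
    expect_equal(res$p_adj[j], min(1, tt$p.value * 6))
    expect_equal(res$d[j], mean(m[, j]) / stats::sd(m[, j]))
  }
  res1 <- one_sample_tests(m, alternative = "greater")
  expect_true(all(res1$p <= res$p | res$t < 0))
  expect_error(one_sample_tests(m[1, , drop = FALSE]), "2 subjects")
})

test_that("rejection frequency matches the noncentral-t power oracle", {
  n <- 24; mu <- 0.5; n_rep <- 400
  crit <- stats::qt(0.975, n - 1)
  ncp <- mu * sqrt(n)
  power <- 1 - stats::pt(crit, n - 1, ncp) + stats::pt(-crit, n - 1, ncp)
  set.seed(17)
  rej <- replicate(n_rep, {
    res <- one_sample_tests(matrix(stats::rnorm(n, mean = mu)), n_corrections = 1)
    res$p < 0.05
  })
  se <- sqrt(power * (1 - power) / n_rep)
  expect_lt(abs(mean(rej) - power), 3 * se)
})

# --- permutation cluster test ----------------------------------------------

test_that("constant-zero profiles produce no clusters", {
  res <- permutation_cluster_1d(matrix(0, 12, 30), n_perm = 200, seed = 1)
  expect_equal(nrow(res), 0)
})

test_that("all-negative group means produce no one-sided clusters", {
  set.seed(5)
  prof <- matrix(stats::rnorm(16 * 25, mean = -1, sd = 0.3), 16, 25)
  res <- permutation_cluster_1d(prof, n_perm = 300, seed = 2)
  expect_equal(nrow(res), 0)
})

test_that("a planted cluster is detected over its positions", {
  set.seed(9)
  prof <- matrix(stats::rnorm(16 * 40, 0, 1), 16, 40)
  prof[, 10:20] <- prof[, 10:20] + 1.5
  res <- permutation_cluster_1d(prof, n_perm = 1000, seed = 3)
  sig <- res[res$significant, ]
  expect_gte(nrow(sig), 1)
  main <- sig[which.max(sig$stat), ]
  expect_lte(main$start, 12)
  expect_gte(main$end, 18)
  expect_lt(main$p, 0.01)
  expect_gt(main$d, 0.5)
})

test_that("doubling the signal never shrinks the detected extent (seeded)", {
  set.seed(23)
  noise <- matrix(stats::rnorm(16 * 40), 16, 40)
  extent <- function(amp) {
    prof <- noise
    prof[, 15:25] <- prof[, 15:25] + amp
    res <- permutation_cluster_1d(prof, n_perm = 500, seed = 4)
    if (!nrow(res)) 0 else sum(res$size[res$significant])
  }
  expect_gte(extent(2), extent(1))
})

test_that("cluster options and guards behave", {
  set.seed(2)
  prof <- matrix(stats::rnorm(12 * 20, 0.8), 12, 20)
  by_mass <- permutation_cluster_1d(prof, n_perm = 200, seed = 5)
  by_size <- permutation_cluster_1d(prof, n_perm = 200, seed = 5,
                                    cluster_stat = "size")
  expect_equal(by_mass[, c("start", "end")], by_size[, c("start", "end")])
  expect_equal(by_size$stat, as.numeric(by_size$size))
  d_pos <- permutation_cluster_1d(prof, n_perm = 200, seed = 5,
                                  effect_size = "positions")
  expect_false(identical(by_mass$d, d_pos$d))
  expect_error(permutation_cluster_1d(prof, n_perm = 50, seed = 1), ">= 100")
  expect_error(permutation_cluster_1d(prof, n_perm = 200), "seed")
  expect_error(permutation_cluster_1d(prof[1, , drop = FALSE],
                                      n_perm = 200, seed = 1), "2 subjects")
  expect_warning(permutation_cluster_1d(prof, n_perm = 100, alpha = 0.005,
                                        seed = 1), "resolve")
})

test_that("permutation p values are reproducible given the seed", {
  set.seed(6)
  prof <- matrix(stats::rnorm(14 * 30, 0.5), 14, 30)
  a <- permutation_cluster_1d(prof, n_perm = 300, seed = 77)
  b <- permutation_cluster_1d(prof, n_perm = 300, seed = 77)
  expect_identical(a, b)
})
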