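#' Remove additive feature patterns for integrated decoding
#'
#' Within each run, subtracts the run-mean pattern together with the
#' order-marginal mean patterns (each order collapsed across timings) and the
#' timing-marginal mean patterns (each timing collapsed across orders). What
#' remains is the interaction residual: activity not explained by any linear
#' combination of order and timing patterns. The output has exactly zero
#' marginal means over orders (at fixed timing) and over timings (at fixed
#' order) within every run, and the operation is idempotent.
#'
#' @param ds A [pattern_dataset()] with the full 2 x 2 design in every run.
#' @return A `pattern_dataset` of residual patterns with the same labels.
#' @export
residualize_integration <- function(ds) {
  if (!inherits(ds, "pattern_dataset")) stop("'ds' must be a pattern_dataset")
  betas <- ds$betas
  out <- betas
  for (r in unique(ds$run)) {
    idx <- which(ds$run == r)
    orders <- sort(unique(ds$order[idx])); timings <- sort(unique(ds$timing[idx]))
    if (length(idx) != length(orders) * length(timings))
      stop("run ", r, " is missing condition cells; the full factorial ",
           "design is required within every run")
    run_mean <- colMeans(betas[idx, , drop = FALSE])
    om <- lapply(orders, function(o)
      colMeans(betas[idx[ds$order[idx] == o], , drop = FALSE]))
    tm <- lapply(timings, function(t)
      colMeans(betas[idx[ds$timing[idx] == t], , drop = FALSE]))
    names(om) <- orders; names(tm) <- timings
    for (i in idx) {
      out[i, ] <- betas[i, ] -
        om[[as.character(ds$order[i])]] -
        tm[[as.character(ds$timing[i])]] + run_mean
    }
  }
  res <- pattern_dataset(out, ds$order, ds$timing, ds$run)
  res
}

#' Binomial z-transform of a classification accuracy
#'
#' Standardizes an observed accuracy against the binomial null at chance:
#' `z = (accuracy - chance) / sqrt(chance * (1 - chance) / n_tests)`. Makes
#' classifiers with different chance levels (pairwise vs 4-way) comparable.
#'
#' @param accuracy Observed proportion correct in `[0, 1]`.
#' @param n_tests Total number of test classifications (>= 1).
#' @param chance Chance probability, strictly inside (0, 1).
#' @return The z score (0 exactly at chance).
#' @examples
#' accuracy_to_z(0.75, 12, 0.5)  # ~1.732
#' @export
accuracy_to_z <- function(accuracy, n_tests, chance) {
  if (any(chance <= 0) || any(chance >= 1))
    stop("'chance' must lie strictly inside (0, 1)")
  if (any(n_tests < 1)) stop("'n_tests' must be >= 1")
  if (any(accuracy < 0) || any(accuracy > 1))
    stop("'accuracy' must lie in [0, 1]")
  (accuracy - chance) / sqrt(chance * (1 - chance) / n_tests)
}

match_rows <- function(ds, spec) {
  idx <- integer(nrow(spec))
  for (i in seq_len(nrow(spec))) {
    hit <- which(ds$order == spec$order[i] & ds$timing == spec$timing[i] &
                   ds$run == spec$run[i])
    if (length(hit) != 1L)
      stop("fold references condition cell (order ", spec$order[i],
           ", timing ", spec$timing[i], ", run ", spec$run[i],
           ") not present exactly once in the dataset")
    idx[i] <- hit
  }
  idx
}

#' Cross-validated decoding accuracy and z score
#'
#' Runs the pooled-covariance LDA classifier over a set of folds, pools the
#' correct/total counts across all folds, and z-transforms the pooled
#' accuracy against the binomial chance distribution.
#'
#' @param ds A [pattern_dataset()].
#' @param folds Folds from [build_folds()] (their runs and conditions must
#'   exist in `ds`).
#' @param shrinkage Covariance shrinkage passed to [lda_fit()].
#' @param chance Chance level; defaults to `1 / #classes` of the fold
#'   labels.
#' @return An object of class `"decoding_result"`: `accuracy`, `n_tests`,
#'   `chance`, `z`, `n_correct`, `scheme`.
#' @export
crossvalidate <- function(ds, folds, shrinkage = 0.1, chance = NULL) {
  if (!inherits(ds, "pattern_dataset")) stop("'ds' must be a pattern_dataset")
  if (!length(folds)) stop("'folds' must be a non-empty fold list")
  n_correct <- 0L; n_total <- 0L
  n_classes <- length(unique(folds[[1]]$train$label))
  for (f in folds) {
    if (!nrow(f$test)) stop("fold has an empty test set")
    tr_idx <- match_rows(ds, f$train)
    te_idx <- match_rows(ds, f$test)
    fit <- lda_fit(ds$betas[tr_idx, , drop = FALSE], f$train$label,
                   shrinkage = shrinkage)
    pred <- predict(fit, ds$betas[te_idx, , drop = FALSE])
    n_correct <- n_correct + sum(pred == f$test$label)
    n_total <- n_total + nrow(f$test)
  }
  if (is.null(chance)) chance <- 1 / n_classes
  acc <- n_correct / n_total
  structure(list(accuracy = acc, n_tests = n_total, chance = chance,
                 z = accuracy_to_z(acc, n_total, chance),
                 n_correct = n_correct,
                 scheme = folds[[1]]$scheme),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("decoding_result (%s): accuracy %.3f (chance %.3f, n = %d), z = %.3f\n",
              x$scheme %||% "?", x$accuracy, x$chance, x$n_tests, x$z))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-call factorized decoding of a pattern dataset
#'
#' Convenience wrapper: builds the folds for the requested scheme (using the
#' runs present in `ds`), residualizes the dataset first when
#' `scheme = "integrated"`, and cross-validates.
#'
#' @inheritParams crossvalidate
#' @param scheme `"order"`, `"timing"` or `"integrated"`.
#' @return A `"decoding_result"`.
#' @examples
#' ds <- simulate_patterns(sim_config(n_voxels = 40, order_amp = 2, seed = 3))
#' decode(ds, "order")$z
#' @export
decode <- function(ds, scheme = c("order", "timing", "integrated"),
                   shrinkage = 0.1) {
  scheme <- match.arg(scheme)
  n_runs <- length(unique(ds$run))
  folds <- build_folds(scheme, n_runs = n_runs)
  if (scheme == "integrated") ds <- residualize_integration(ds)
  crossvalidate(ds, folds, shrinkage = shrinkage)
}
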