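#' Construct cross-validation folds for factorized sequence decoding
#'
#' Three fold schemes over the 2 (order) x 2 (timing) x runs design:
#' \describe{
#'   \item{`"order"`}{Cross-classification of finger order across timing:
#'     train on the two orders paired with one timing over all-but-one runs,
#'     test on the two orders paired with the \emph{other} timing in the
#'     held-out run. Each held-out run contributes two train/test pairings,
#'     so 6 runs yield 12 folds. Only order information that generalizes
#'     across timing can support accuracy.}
#'   \item{`"timing"`}{The mirror image: decode timing, transfer across
#'     order; 12 folds with 6 runs.}
#'   \item{`"integrated"`}{4-way classification of all conditions,
#'     leave-one-run-out: 6 folds with 6 runs. Intended for use on
#'     [residualize_integration()] output so that only non-additive
#'     condition information remains.}
#' }
#'
#' @param scheme `"order"`, `"timing"` or `"integrated"`.
#' @param n_runs Number of runs (default 6, must be >= 2).
#' @param n_orders,n_timings Design size; only the 2 x 2 design is
#'   supported.
#' @return A list of folds; each fold is a list with `train` and `test`
#'   data frames (columns `order`, `timing`, `run`, `label`) and the
#'   `scheme`. Train and test runs are disjoint in every fold; for the
#'   feature schemes the non-decoded feature always differs between train
#'   and test.
#' @examples
#' length(build_folds("order"))       # 12
#' length(build_folds("integrated"))  # 6
#' @export
build_folds <- function(scheme = c("order", "timing", "integrated"),
                        n_runs = 6L, n_orders = 2L, n_timings = 2L) {
  scheme <- match.arg(scheme)
  if (n_orders != 2L || n_timings != 2L)
    stop("unsupported design: factorized folds require a 2 x 2 ",
         "order-by-timing design")
  n_runs <- as.integer(n_runs)
  if (n_runs < 2L) stop("'n_runs' must be >= 2")

  folds <- list()
  if (scheme == "integrated") {
    grid <- expand.grid(order = 1:2, timing = 1:2)
    grid$label <- seq_len(nrow(grid))
    for (test_run in seq_len(n_runs)) {
      train_runs <- setdiff(seq_len(n_runs), test_run)
      tr <- merge(grid, data.frame(run = train_runs))
      te <- grid; te$run <- test_run
      folds[[length(folds) + 1L]] <-
        list(train = tr[, c("order", "timing", "run", "label")],
             test = te[, c("order", "timing", "run", "label")],
             scheme = scheme)
    }
    return(folds)
  }

  # feature schemes: decode one factor, transfer across the other
  decoded <- scheme
  other <- if (scheme == "order") "timing" else "order"
  for (test_run in seq_len(n_runs)) {
    train_runs <- setdiff(seq_len(n_runs), test_run)
    for (train_level in 1:2) {
      test_level <- 3L - train_level
      tr <- expand.grid(label = 1:2, run = train_runs)
      tr[[decoded]] <- tr$label
      tr[[other]] <- train_level
      te <- data.frame(label = 1:2, run = test_run)
      te[[decoded]] <- te$label
      te[[other]] <- test_level
      cols <- c("order", "timing", "run", "label")
      folds[[length(folds) + 1L]] <-
        list(train = tr[, cols], test = te[, cols], scheme = scheme)
    }
  }
  folds
}
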