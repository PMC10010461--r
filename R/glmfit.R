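#' Fit a first-level GLM by ordinary least squares
#'
#' Estimates one beta per regressor per voxel by OLS. Rank deficiency is
#' detected before fitting and reported with the names of the offending
#' (collinear) columns rather than silently dropping them.
#'
#' @param Y Numeric matrix of BOLD time series, scans x voxels.
#' @param X A [build_design()] object or a plain scans x regressors matrix
#'   with unique column names.
#' @return An object of class `"glm_fit"`: `betas` (regressors x voxels,
#'   rownames = regressor names), `sigma2` (residual variance per voxel),
#'   `df_residual`, and the design dimensions.
#' @export
fit_glm <- function(Y, X) {
  if (inherits(X, "design_matrix")) X <- X$X
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(Y) != nrow(X))
    stop("'Y' and the design must have the same number of scans")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  betas <- qr.coef(qx, Y)
  res <- Y - X %*% betas
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / max(df, 1L)
  structure(list(betas = betas, sigma2 = sigma2, df_residual = df,
                 n_scans = nrow(X), n_regressors = ncol(X)),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("glm_fit:", x$n_regressors, "regressors x", ncol(x$betas),
      "voxels,", x$df_residual, "residual df\n")
  invisible(x)
}

#' Simulate BOLD data from a design and true betas
#'
#' Convenience generator for pipeline validation: `Y = X B + noise`, where
#' rows of `B` are matched to design columns by name (regressors absent from
#' `B` contribute nothing).
#'
#' @param design A [build_design()] object or design matrix.
#' @param true_betas Matrix of true effects, regressors x voxels, with
#'   rownames naming design columns.
#' @param noise_sd SD of i.i.d. Gaussian scanner noise.
#' @param seed RNG seed.
#' @return Numeric matrix, scans x voxels.
#' @export
simulate_bold <- function(design, true_betas, noise_sd = 1, seed = 1L) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  true_betas <- as.matrix(true_betas)
  if (is.null(rownames(true_betas)))
    stop("'true_betas' must have rownames naming design columns")
  B <- matrix(0, ncol(X), ncol(true_betas),
              dimnames = list(colnames(X), colnames(true_betas)))
  known <- intersect(rownames(true_betas), colnames(X))
  B[known, ] <- true_betas[known, ]
  with_seed(seed,
            X %*% B + matrix(stats::rnorm(nrow(X) * ncol(B), 0, noise_sd),
                             nrow(X)))
}

#' Assemble condition-by-run beta patterns from per-run GLM fits
#'
#' Collects the production (or preparation) regressor betas of every
#' condition across a list of run-wise [fit_glm()] results into a
#' [pattern_dataset()] ready for decoding.
#'
#' @param fits List of `"glm_fit"` objects, one per run (run index = list
#'   position).
#' @param phase `"prod"` (production, default) or `"prep"` (preparation):
#'   which regressor family to extract.
#' @return A [pattern_dataset()] with one row per condition per run.
#' @export
collect_run_betas <- function(fits, phase = c("prod", "prep")) {
  phase <- match.arg(phase)
  pat <- paste0("^", phase, "_o(\\d+)t(\\d+)$")
  rows <- list(); order <- integer(0); timing <- integer(0); run <- integer(0)
  for (r in seq_along(fits)) {
    b <- fits[[r]]$betas
    hit <- grep(pat, rownames(b), value = TRUE)
    if (!length(hit)) stop("run ", r, " has no '", phase, "' regressors")
    m <- regmatches(hit, regexec(pat, hit))
    for (k in seq_along(hit)) {
      rows[[length(rows) + 1L]] <- b[hit[k], ]
      order <- c(order, as.integer(m[[k]][2]))
      timing <- c(timing, as.integer(m[[k]][3]))
      run <- c(run, r)
    }
  }
  pattern_dataset(do.call(rbind, rows), order, timing, run)
}
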