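#' Gaussian linear discriminant classifier with pooled shrinkage covariance
#'
#' Fits the classifier used throughout the decoding pipeline: per-class mean
#' patterns plus a single pooled within-class covariance matrix, shrunk
#' toward a scaled identity, `(1 - lambda) * S + lambda * (tr(S)/p) * I`.
#' Shrinkage is essential in the typical regime where the number of voxels
#' (e.g. 160) far exceeds the number of training patterns (e.g. 10-20).
#' Classification assigns the class with the largest linear discriminant
#' `x' S^-1 mu_k - mu_k' S^-1 mu_k / 2` (equal priors); ties break
#' deterministically toward the lowest class index.
#'
#' @param x Training patterns, rows x voxels.
#' @param labels Class label per row (>= 2 classes, >= 1 row each).
#' @param shrinkage Shrinkage weight `lambda` in `[0, 1]` (default 0.1).
#' @return An object of class `"lda_pooled"` with elements `means` (class x
#'   voxel), `classes`, `cov` (regularized pooled covariance) and `w`, `b`
#'   (precomputed discriminant weights and offsets).
#' @export
lda_fit <- function(x, labels, shrinkage = 0.1) {
  x <- as.matrix(x)
  labels <- as.vector(labels)
  if (nrow(x) != length(labels)) stop("one label per training row required")
  if (shrinkage < 0 || shrinkage > 1) stop("'shrinkage' must be in [0, 1]")
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("at least 2 classes are required")
  p <- ncol(x)

  means <- t(vapply(classes, function(k)
    colMeans(x[labels == k, , drop = FALSE]), numeric(p)))
  centered <- x - means[match(labels, classes), , drop = FALSE]
  df <- nrow(x) - length(classes)
  S <- if (df > 0) crossprod(centered) / df else matrix(0, p, p)
  target <- sum(diag(S)) / p
  if (target == 0) target <- 1  # degenerate training set: fall back to identity
  S_reg <- (1 - shrinkage) * S + shrinkage * target * diag(p)

  ch <- tryCatch(chol(S_reg), error = function(e) NULL)
  if (is.null(ch))
    stop("pooled covariance is singular; increase 'shrinkage' ",
         "(it regularizes toward a scaled identity)")
  # w_k = S^-1 mu_k, b_k = -mu_k' S^-1 mu_k / 2
  w <- backsolve(ch, forwardsolve(t(ch), t(means)))
  b <- -0.5 * colSums(t(means) * w)
  structure(list(means = means, classes = classes, cov = S_reg,
                 shrinkage = shrinkage, w = w, b = b),
            class = "lda_pooled")
}

#' @rdname lda_fit
#' @param object A fitted `"lda_pooled"` classifier.
#' @param newdata Patterns to classify, rows x voxels.
#' @param ... Unused.
#' @return `predict()` returns the vector of predicted class labels.
#' @export
predict.lda_pooled <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  scores <- newdata %*% object$w +
    matrix(object$b, nrow(newdata), length(object$b), byrow = TRUE)
  # which.max returns the first (lowest-index) maximum: deterministic ties
  object$classes[apply(scores, 1, which.max)]
}

#' @export
print.lda_pooled <- function(x, ...) {
  cat("lda_pooled:", length(x$classes), "classes,", ncol(x$means),
      "voxels, shrinkage", x$shrinkage, "\n")
  invisible(x)
}
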