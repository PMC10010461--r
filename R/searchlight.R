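#' Searchlight decoding map
#'
#' Runs the factorized classifier inside every searchlight neighborhood and
#' assigns the resulting z-accuracy to the neighborhood's center node. For
#' the integrated scheme the dataset is residualized once up front
#' (residualization acts voxel-wise, so this equals residualizing within
#' every neighborhood). The result does not depend on the order in which
#' nodes are visited.
#'
#' @param ds A [pattern_dataset()] whose voxel columns correspond one-to-one
#'   to the nodes of `neighborhoods`.
#' @param neighborhoods A neighborhood list from [make_neighborhood_graph()]
#'   (node index -> member voxel indices).
#' @param scheme `"order"`, `"timing"` or `"integrated"`.
#' @param shrinkage Covariance shrinkage passed to [lda_fit()].
#' @param nodes Optional subset of node indices to evaluate (default: all).
#' @return Numeric vector of z scores, one per node (named by node index);
#'   `NA` for skipped nodes. Neighborhoods with fewer than 2 voxels are
#'   skipped with a warning.
#' @export
searchlight <- function(ds, neighborhoods,
                        scheme = c("order", "timing", "integrated"),
                        shrinkage = 0.1, nodes = NULL) {
  scheme <- match.arg(scheme)
  if (!inherits(ds, "pattern_dataset")) stop("'ds' must be a pattern_dataset")
  if (is.null(nodes)) nodes <- seq_along(neighborhoods)
  if (any(nodes < 1L | nodes > length(neighborhoods)))
    stop("'nodes' must index into 'neighborhoods'")
  max_vox <- max(unlist(neighborhoods[nodes]))
  if (max_vox > ncol(ds$betas))
    stop("neighborhoods reference voxel ", max_vox,
         " but the dataset has only ", ncol(ds$betas))

  n_runs <- length(unique(ds$run))
  folds <- build_folds(scheme, n_runs = n_runs)
  if (scheme == "integrated") ds <- residualize_integration(ds)

  z <- rep(NA_real_, length(neighborhoods))
  skipped <- 0L
  for (node in nodes) {
    vox <- neighborhoods[[node]]
    if (length(vox) < 2L) { skipped <- skipped + 1L; next }
    sub <- ds
    sub$betas <- ds$betas[, vox, drop = FALSE]
    z[node] <- crossvalidate(sub, folds, shrinkage = shrinkage)$z
  }
  if (skipped > 0L)
    warning(skipped, " node(s) skipped: neighborhood smaller than 2 voxels")
  names(z) <- seq_along(z)
  z
}

#' Average a z map within regions of interest
#'
#' @param z_map Numeric vector of node-wise z values (e.g. from
#'   [searchlight()]).
#' @param rois Named list of integer node-index vectors, one per ROI.
#' @param na_rm Drop `NA` nodes (skipped searchlights) before averaging.
#' @return Named numeric vector of per-ROI mean z.
#' @export
roi_mean <- function(z_map, rois, na_rm = FALSE) {
  if (!is.list(rois)) rois <- list(roi = rois)
  vapply(rois, function(idx) {
    idx <- as.integer(idx)
    if (!length(idx)) stop("ROIs must be non-empty")
    if (any(idx < 1L | idx > length(z_map)))
      stop("ROI indexes nodes outside the z map")
    mean(z_map[idx], na.rm = na_rm)
  }, numeric(1))
}
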