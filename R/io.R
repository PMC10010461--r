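#' Read and write pattern datasets as TSV or NIfTI
#'
#' A [pattern_dataset()] round-trips through two plain formats: a single TSV
#' with factor columns `order`, `timing`, `run` followed by one column per
#' voxel, or a directory of 3-D NIfTI volumes (one per condition-run row,
#' grid geometry) accompanied by a `labels.tsv` naming each volume's factors.
#'
#' @param ds A [pattern_dataset()].
#' @param path TSV file path.
#' @return `read_pattern_tsv()` and `read_patterns_nifti()` return a
#'   `pattern_dataset`; the writers return the path/dir invisibly.
#' @export
write_pattern_tsv <- function(ds, path) {
  if (!inherits(ds, "pattern_dataset")) stop("'ds' must be a pattern_dataset")
  df <- data.frame(order = ds$order, timing = ds$timing, run = ds$run,
                   ds$betas)
  colnames(df)[-(1:3)] <- paste0("v", seq_len(ncol(ds$betas)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pattern_tsv
#' @export
read_pattern_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  vox <- grep("^v\\d+$", names(df))
  if (!length(vox)) stop("no voxel columns (v1, v2, ...) found in ", path)
  pattern_dataset(as.matrix(df[, vox, drop = FALSE]),
                  df$order, df$timing, df$run)
}

#' @rdname write_pattern_tsv
#' @param dir Directory for the NIfTI volumes.
#' @param dims Integer length-3 volume dimensions with
#'   `prod(dims) == n_voxels`; voxels fill the volume in column-major order.
#' @param voxel_size Isotropic voxel size in mm (default 2).
#' @export
write_patterns_nifti <- function(ds, dir, dims, voxel_size = 2) {
  if (!inherits(ds, "pattern_dataset")) stop("'ds' must be a pattern_dataset")
  dims <- as.integer(dims)
  if (length(dims) != 3L || prod(dims) != ncol(ds$betas))
    stop("'dims' must be a length-3 vector with prod(dims) == n_voxels")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(nrow(ds$betas))
  for (i in seq_len(nrow(ds$betas))) {
    files[i] <- sprintf("beta_o%dt%d_run%d.nii.gz",
                        ds$order[i], ds$timing[i], ds$run[i])
    vol <- array(ds$betas[i, ], dim = dims)
    RNifti::writeNifti(RNifti::asNifti(vol, pixdim = rep(voxel_size, 3)),
                       file.path(dir, files[i]))
  }
  utils::write.table(
    data.frame(file = files, order = ds$order, timing = ds$timing,
               run = ds$run),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}

#' @rdname write_pattern_tsv
#' @export
read_patterns_nifti <- function(dir) {
  lab_path <- file.path(dir, "labels.tsv")
  if (!file.exists(lab_path)) stop("no labels.tsv found in ", dir)
  lab <- utils::read.table(lab_path, header = TRUE, sep = "\t")
  betas <- t(vapply(lab$file, function(f)
    as.vector(RNifti::readNifti(file.path(dir, f))),
    numeric(prod(dim(RNifti::readNifti(file.path(dir, lab$file[1])))))))
  rownames(betas) <- NULL
  pattern_dataset(betas, lab$order, lab$timing, lab$run)
}

#' Read and write behavioral trial tables
#'
#' Trial tables use one row per trial with press times in ms and one column
#' per press time and finger, the layout produced by [simulate_behavior()].
#'
#' @param trials A trial data frame.
#' @param path TSV file path.
#' @return `read_trials_tsv()` returns the data frame; the writer returns
#'   the path invisibly.
#' @export
write_trials_tsv <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_tsv
#' @export
read_trials_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
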