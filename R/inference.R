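#' One-sample t tests on ROI decoding values with Bonferroni correction
#'
#' Tests, per ROI, whether the across-subject mean of a decoding z value (or
#' any per-subject statistic) differs from chance level (zero), with a
#' Bonferroni adjustment for a stated family of comparisons (default 6,
#' e.g. 3 classifiers x 2 trial phases).
#'
#' @param roi_values Numeric matrix, subjects x ROIs (column names label the
#'   ROIs).
#' @param n_corrections Bonferroni family size; adjusted p =
#'   `min(1, p * n_corrections)`.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param mu Null value (default 0 = chance).
#' @return Data frame with one row per ROI: `mean`, `sd`, `t`, `df`, `p`,
#'   `p_adj`, Cohen's `d` (`mean / sd`) and a `degenerate` flag for
#'   zero-variance columns (statistics are `NA` there, never `NaN`).
#' @export
one_sample_tests <- function(roi_values, n_corrections = 6L,
                             alternative = c("two.sided", "greater", "less"),
                             mu = 0) {
  alternative <- match.arg(alternative)
  roi_values <- as.matrix(roi_values)
  if (nrow(roi_values) < 2L) stop("at least 2 subjects are required")
  if (is.null(colnames(roi_values)))
    colnames(roi_values) <- paste0("roi", seq_len(ncol(roi_values)))
  res <- lapply(seq_len(ncol(roi_values)), function(j) {
    x <- roi_values[, j]
    s <- stats::sd(x)
    if (s == 0) {
      # zero variance: exactly at the null value this is an uninformative
      # t = 0 / p = 1; off the null the statistic is undefined (NA, not NaN)
      at_null <- mean(x) == mu
      data.frame(roi = colnames(roi_values)[j], mean = mean(x), sd = s,
                 t = if (at_null) 0 else NA_real_,
                 df = length(x) - 1L,
                 p = if (at_null) 1 else NA_real_,
                 p_adj = if (at_null) 1 else NA_real_,
                 d = if (at_null) 0 else NA_real_, degenerate = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      tt <- stats::t.test(x, mu = mu, alternative = alternative)
      data.frame(roi = colnames(roi_values)[j], mean = mean(x), sd = s,
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value,
                 p_adj = min(1, tt$p.value * n_corrections),
                 d = (mean(x) - mu) / s, degenerate = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# t statistics of columns against zero; vectorized over permuted sign
# patterns using the invariance of per-subject squared values.
col_t <- function(m, ssq, n) {
  v <- (ssq - n * m^2) / (n - 1)
  v[v <= 0] <- NA  # zero-variance column: no defined t
  m / sqrt(v / n)
}

#' One-sided sign-flip permutation cluster test along a 1-D profile
#'
#' Family-wise corrected cluster inference for subjects x positions profiles
#' (z-accuracies or signal change along a cortical cross-section). Under the
#' null hypothesis that each subject's profile is symmetrically distributed
#' around zero, subject profiles are randomly sign-flipped; for each
#' permutation, positions where the group one-sample t exceeds the
#' cluster-forming threshold are grouped into contiguous clusters and the
#' maximal cluster statistic is recorded. Observed clusters are assigned the
#' corrected p value `(1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param profile Numeric matrix, subjects x positions (>= 2 subjects, no
#'   missing values).
#' @param n_perm Number of sign-flip permutations (default 10000, >= 100).
#' @param alpha Family-wise significance level (default 0.05).
#' @param cluster_stat `"mass"` (sum of t within the cluster, default) or
#'   `"size"` (number of positions).
#' @param p_threshold Uncorrected one-sided p of the per-position
#'   cluster-forming t threshold (default 0.05).
#' @param effect_size `"values"` (default: Cohen's d of the cluster-averaged
#'   per-subject values, mean/SD) or `"positions"` (mean of per-position d
#'   over the cluster).
#' @param seed Required RNG seed for the permutation draw.
#' @return A data frame of class `"cluster_result"`, one row per
#'   supra-threshold cluster (possibly zero rows): `start`, `end` (position
#'   indices), `size`, `stat`, `p`, `d`, `significant` (`p <= alpha`).
#'   `n_perm`, `alpha` and the threshold are attached as attributes.
#' @export
permutation_cluster_1d <- function(profile, n_perm = 10000L, alpha = 0.05,
                                   cluster_stat = c("mass", "size"),
                                   p_threshold = 0.05,
                                   effect_size = c("values", "positions"),
                                   seed) {
  cluster_stat <- match.arg(cluster_stat)
  effect_size <- match.arg(effect_size)
  if (missing(seed)) stop("'seed' is required for reproducible permutations")
  profile <- as.matrix(profile)
  n <- nrow(profile); pos <- ncol(profile)
  if (n < 2L) stop("at least 2 subjects are required")
  if (anyNA(profile)) stop("'profile' must not contain missing values")
  n_perm <- as.integer(n_perm)
  if (n_perm < 100L) stop("'n_perm' must be >= 100")
  if (1 / n_perm > alpha)
    warning("n_perm = ", n_perm, " cannot resolve p values below alpha = ",
            alpha)

  t_crit <- stats::qt(1 - p_threshold, df = n - 1)
  ssq <- colSums(profile^2)
  t_obs <- col_t(colMeans(profile), ssq, n)
  t_obs[is.na(t_obs)] <- 0

  find_clusters <- function(tvec) {
    above <- tvec > t_crit
    if (!any(above)) return(NULL)
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- r$values
    data.frame(start = starts[keep], end = ends[keep])
  }
  cl_stat <- function(tvec, cl) {
    if (cluster_stat == "size") cl$end - cl$start + 1
    else vapply(seq_len(nrow(cl)), function(i)
      sum(tvec[cl$start[i]:cl$end[i]]), numeric(1))
  }

  obs <- find_clusters(t_obs)
  # max-cluster null distribution from random sign flips; per-subject
  # squared values are flip-invariant, so the whole t matrix vectorizes
  null_max <- with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n_perm, n)
    M <- (signs %*% profile) / n
    V <- sweep(-n * M^2, 2, ssq, "+") / (n - 1)
    Tm <- M / sqrt(V / n)
    Tm[!is.finite(Tm)] <- 0
    vapply(seq_len(n_perm), function(b) {
      tv <- Tm[b, ]
      cl <- find_clusters(tv)
      if (is.null(cl)) 0 else max(cl_stat(tv, cl))
    }, numeric(1))
  })

  if (is.null(obs)) {
    out <- data.frame(start = integer(0), end = integer(0), size = integer(0),
                      stat = numeric(0), p = numeric(0), d = numeric(0),
                      significant = logical(0))
  } else {
    stat <- cl_stat(t_obs, obs)
    p <- vapply(stat, function(s) (1 + sum(null_max >= s)) / (n_perm + 1),
                numeric(1))
    d <- vapply(seq_len(nrow(obs)), function(i) {
      cols <- obs$start[i]:obs$end[i]
      if (effect_size == "values") {
        avg <- rowMeans(profile[, cols, drop = FALSE])
        mean(avg) / stats::sd(avg)
      } else {
        mean(colMeans(profile[, cols, drop = FALSE]) /
               apply(profile[, cols, drop = FALSE], 2, stats::sd))
      }
    }, numeric(1))
    out <- data.frame(start = obs$start, end = obs$end,
                      size = obs$end - obs$start + 1L,
                      stat = stat, p = p, d = d, significant = p <= alpha)
  }
  attr(out, "n_perm") <- n_perm
  attr(out, "alpha") <- alpha
  attr(out, "t_crit") <- t_crit
  class(out) <- c("cluster_result", "data.frame")
  out
}
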