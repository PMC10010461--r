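#' Detect finger presses from multi-channel force traces
#'
#' Reproduces the standard force-keyboard press-detection chain: each channel
#' is baseline-corrected by the mean of its pre-cue baseline window, smoothed
#' with a Gaussian window, and a press onset is recorded at the first sample
#' of every episode in which the corrected force exceeds a fixed threshold.
#' A new press on the same channel requires the force to fall back below the
#' threshold first.
#'
#' @param trace Numeric matrix of forces in Newton, one row per millisecond
#'   sample (1000 Hz), one column per channel (typically 10 fingers).
#'   Acquisition is assumed to start `baseline_ms` before the Sequence cue.
#' @param threshold Press threshold in Newton above baseline. The apparatus
#'   convention is 1 N (2.5 N for a minority of early participants).
#' @param baseline_ms Length of the pre-cue baseline window used for
#'   correction (default 500 ms).
#' @param smooth_ms Full width at half maximum of the Gaussian smoothing
#'   kernel in ms (default 100 ms). `0` disables smoothing.
#' @return A data frame with one row per detected press: `channel`, and
#'   `onset_ms` measured from acquisition start (subtract `baseline_ms` for
#'   cue-relative times), ordered by onset.
#' @export
detect_presses <- function(trace, threshold = 1, baseline_ms = 500,
                           smooth_ms = 100) {
  trace <- as.matrix(trace)
  if (!is.numeric(trace)) stop("'trace' must be numeric")
  if (threshold <= 0) stop("'threshold' must be > 0")
  if (smooth_ms < 0) stop("'smooth_ms' must be >= 0")
  if (nrow(trace) < baseline_ms)
    stop("trace shorter than the ", baseline_ms, " ms baseline window")

  base <- colMeans(trace[seq_len(baseline_ms), , drop = FALSE])
  corrected <- sweep(trace, 2, base)
  if (smooth_ms > 0) corrected <- apply(corrected, 2, gauss_smooth, fwhm = smooth_ms)
  corrected <- as.matrix(corrected)

  out <- list()
  for (ch in seq_len(ncol(corrected))) {
    above <- corrected[, ch] > threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    onsets <- starts[r$values]
    out[[length(out) + 1L]] <- data.frame(channel = ch, onset_ms = onsets)
  }
  if (!length(out))
    return(data.frame(channel = integer(0), onset_ms = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$onset_ms, res$channel), , drop = FALSE]
}

# Gaussian smoothing with kernel renormalized near the edges so that
# constant signals pass through unchanged.
gauss_smooth <- function(x, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  n <- length(x)
  num <- stats::convolve(c(rep(0, half), x, rep(0, half)), rev(k), type = "filter")
  den <- stats::convolve(c(rep(0, half), rep(1, n), rep(0, half)), rev(k), type = "filter")
  num / den
}

#' Interpress intervals of a five-press sequence
#'
#' @param press_times Strictly increasing numeric vector of exactly five
#'   press times in ms.
#' @return Numeric vector of the four consecutive interpress intervals (ms).
#' @examples
#' compute_ipis(c(0, 1200, 2010, 2360, 3010))  # Timing 1 targets
#' @export
compute_ipis <- function(press_times) {
  press_times <- as.numeric(press_times)
  if (length(press_times) != 5L)
    stop("exactly 5 press times are required, got ", length(press_times))
  if (anyNA(press_times) || any(diff(press_times) <= 0))
    stop("press times must be strictly increasing")
  diff(press_times)
}
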