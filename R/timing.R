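#' Target sequence specifications
#'
#' A sequence is defined by a finger order (five presses, all trained
#' sequences sharing the same first finger so that first-press identity
#' cannot drive decoding) and a target timing structure (four interpress
#' intervals). The two canonical timing structures are
#' Timing 1 = 1200, 810, 350, 650 ms and Timing 2 = 350, 1200, 650, 810 ms;
#' both sum to the same total duration (3010 ms).
#'
#' @param finger_order Integer vector of 5 finger identities.
#' @param target_ipis Numeric vector of 4 target interpress intervals (ms).
#' @return An object of class `"sequence_spec"`.
#' @export
sequence_spec <- function(finger_order, target_ipis) {
  finger_order <- as.integer(finger_order)
  target_ipis <- as.numeric(target_ipis)
  if (length(finger_order) != 5L) stop("'finger_order' must have length 5")
  if (length(target_ipis) != 4L) stop("'target_ipis' must have length 4")
  if (any(target_ipis <= 0)) stop("target IPIs must be positive")
  structure(list(finger_order = finger_order, target_ipis = target_ipis),
            class = "sequence_spec")
}

#' @rdname sequence_spec
#' @param orders A list of two length-5 finger orders (defaults to two fixed
#'   permutations sharing the first finger).
#' @details `default_sequences()` returns the canonical 2 x 2 set of four
#'   specs, indexed `[[order]][[timing]]`, all starting with the same finger.
#' @export
default_sequences <- function(orders = list(c(1L, 3L, 5L, 2L, 4L),
                                            c(1L, 4L, 2L, 5L, 3L))) {
  timings <- list(c(1200, 810, 350, 650), c(350, 1200, 650, 810))
  if (length(orders) != 2L) stop("'orders' must list two finger orders")
  orders <- lapply(orders, as.integer)
  firsts <- vapply(orders, `[`, integer(1), 1L)
  if (length(unique(firsts)) != 1L)
    stop("all sequences must begin with the same finger press")
  lapply(orders, function(o) lapply(timings, function(t) sequence_spec(o, t)))
}

#' Normalized sequence timing error
#'
#' Expresses produced and target interpress intervals as percentages of the
#' participant's average total sequence length, then accumulates the absolute
#' percent deviation from target across the four intervals. The
#' normalization removes global tempo differences: producing every interval
#' scaled by the same factor as the average total length yields zero error.
#'
#' @param produced_ipis,target_ipis Numeric vectors of 4 intervals (ms).
#' @param avg_total_len Average total sequence length (ms) of the session,
#'   used as the normalization denominator.
#' @return A list of class `"timing_error"` with `per_interval` (absolute
#'   percent deviation per interval) and `cumulative` (their sum, %).
#' @examples
#' timing_error(c(1300, 810, 350, 650), c(1200, 810, 350, 650), 3010)
#' @export
timing_error <- function(produced_ipis, target_ipis, avg_total_len) {
  produced_ipis <- as.numeric(produced_ipis)
  target_ipis <- as.numeric(target_ipis)
  if (length(produced_ipis) != 4L || length(target_ipis) != 4L)
    stop("both IPI vectors must have length 4")
  if (any(produced_ipis <= 0) || any(target_ipis <= 0))
    stop("IPIs must be positive")
  if (length(avg_total_len) != 1L || avg_total_len <= 0)
    stop("'avg_total_len' must be a single positive length in ms")
  prod_pct <- produced_ipis / avg_total_len * 100
  targ_pct <- target_ipis / avg_total_len * 100
  dev <- abs(prod_pct - targ_pct)
  structure(list(per_interval = dev, cumulative = sum(dev)),
            class = "timing_error")
}

#' @export
print.timing_error <- function(x, ...) {
  cat("timing error: per interval",
      paste(sprintf("%.2f%%", x$per_interval), collapse = ", "),
      "| cumulative", sprintf("%.2f%%\n", x$cumulative))
  invisible(x)
}

# Points bands; intervals are closed on the left, open on the right.
rt_points <- function(rt) {
  if (is.na(rt)) return(0L)
  bands <- c(200, 360, 480, 560, 600)
  5L - sum(rt >= bands)
}

ipi_points <- function(mean_dev_pct) {
  if (is.na(mean_dev_pct)) return(0L)
  bands <- c(10, 20, 30, 40, 50)
  5L - sum(mean_dev_pct >= bands)
}

#' Score one trial on the 0-10 points feedback scale
#'
#' Implements the trial-by-trial feedback scheme: up to 5 points for
#' initiation reaction time (5: < 200 ms, 4: 200-360, 3: 360-480, 2: 480-560,
#' 1: 560-600, 0: >= 600 ms) plus up to 5 points for timing accuracy based on
#' the mean absolute deviation of the produced IPIs from target, in percent
#' of the respective target interval (5: < 10%, 4: 10-20, 3: 20-30, 2: 30-40,
#' 1: 40-50, 0: >= 50%). A wrong press order voids the trial (0 points), as
#' does exceeding the force threshold during the preparation period. No-Go
#' trials earn 5 points when no press is made and 0 otherwise.
#'
#' @param trial A list or one-row data frame with fields `trial_type`
#'   (`"instructed"`, `"memory"` or `"nogo"`), `press_times` (ms, relative to
#'   the Go cue), `press_fingers`, `rt` (ms; first press minus Go cue) and a
#'   `target` [sequence_spec()]. No-Go trials may omit presses and `rt`.
#' @param prep_force_exceeded Logical; `TRUE` if force crossed threshold
#'   during the preparation period (voids the trial).
#' @return Integer points in 0..10.
#' @export
score_trial <- function(trial, prep_force_exceeded = FALSE) {
  type <- trial$trial_type
  presses <- trial$press_times
  if (is.null(presses)) presses <- numeric(0)
  presses <- presses[!is.na(presses)]
  if (identical(type, "nogo")) {
    if (length(presses) == 0L && !isTRUE(prep_force_exceeded)) return(5L)
    return(0L)
  }
  if (isTRUE(prep_force_exceeded)) return(0L)
  if (length(presses) == 0L) return(0L)
  if (is.null(trial$rt) || is.na(trial$rt))
    stop("Go trial with presses must have a reaction time")
  fingers <- trial$press_fingers[!is.na(trial$press_fingers)]
  target <- trial$target
  correct_order <- length(fingers) == 5L &&
    all(fingers == target$finger_order)
  if (!correct_order) return(0L)
  produced <- compute_ipis(presses)
  mean_dev <- mean(abs(produced - target$target_ipis) /
                     target$target_ipis * 100)
  as.integer(rt_points(trial$rt) + ipi_points(mean_dev))
}
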