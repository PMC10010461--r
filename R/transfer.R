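#' Synchronization-transfer statistics
#'
#' After training, synchronization accuracy to visually paced sequences is
#' compared between trained sequences, sequences sharing only the trained
#' finger order (order transfer), sequences sharing only the trained timing
#' (timing transfer), and entirely new sequences. Because transfer of a
#' trained timing to a new order only stabilizes after a few exposures,
#' deviations are averaged from the `min_repetition`-th exposure of each
#' sequence onward (default: fourth). Each non-new condition is then compared
#' against the new-sequence condition with a paired t test, one-sided by
#' default in the direction of a transfer benefit (smaller deviation).
#'
#' @param trials Data frame with columns `subject`, `condition` (one of
#'   `"trained"`, `"order_transfer"`, `"timing_transfer"`, `"new"`),
#'   `sequence` (sequence identity within condition), `repetition` (1-based
#'   exposure count of that sequence) and `deviation` (absolute deviation
#'   from target timing, ms).
#' @param min_repetition First exposure included in the average (default 4).
#' @param alternative Direction of the paired t test of condition minus new;
#'   `"less"` (default) tests for a transfer benefit.
#' @return A data frame with one row per non-new condition: per-condition
#'   mean absolute deviation, mean for new sequences, `t`, `df`, `p`,
#'   Cohen's `d` (mean of paired differences over their SD) and a
#'   `degenerate` flag set when the paired differences have zero variance
#'   (in which case `t`, `p` and `d` are `NA`, never `NaN`).
#' @export
transfer_stats <- function(trials, min_repetition = 4L,
                           alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  needed <- c("subject", "condition", "sequence", "repetition", "deviation")
  if (!all(needed %in% names(trials)))
    stop("'trials' must have columns: ", paste(needed, collapse = ", "))
  max_rep <- tapply(trials$repetition,
                    interaction(trials$condition, trials$sequence, drop = TRUE),
                    max)
  if (any(max_rep < min_repetition))
    stop("every sequence needs at least ", min_repetition,
         " exposures; synchronization is only assessed from the ",
         min_repetition, "th exposure onward")

  kept <- trials[trials$repetition >= min_repetition, , drop = FALSE]
  subj_means <- tapply(abs(kept$deviation),
                       list(kept$subject, kept$condition), mean)
  if (!"new" %in% colnames(subj_means))
    stop("'trials' must contain a 'new' condition to compare against")
  conds <- setdiff(colnames(subj_means), "new")
  new_vals <- subj_means[, "new"]

  res <- lapply(conds, function(cond) {
    x <- subj_means[, cond]
    ok <- stats::complete.cases(x, new_vals)
    diffs <- x[ok] - new_vals[ok]
    degen <- stats::sd(diffs) == 0
    if (degen) {
      tt <- list(statistic = NA_real_, parameter = length(diffs) - 1L,
                 p.value = NA_real_)
      d <- NA_real_
    } else {
      tt <- stats::t.test(x[ok], new_vals[ok], paired = TRUE,
                          alternative = alternative)
      d <- mean(diffs) / stats::sd(diffs)
    }
    data.frame(condition = cond,
               mean_deviation = mean(x[ok]),
               mean_deviation_new = mean(new_vals[ok]),
               n = sum(ok),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, d = d, degenerate = degen,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
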