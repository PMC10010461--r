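#' Build a first-level design matrix for one run
#'
#' Implements the regressor scheme that separates sequence planning from
#' production despite the hemodynamic lag: per condition, a
#' \emph{preparation} regressor built only from No-Go trials (a boxcar
#' starting at the Sequence cue and lasting the maximum possible preparation
#' phase, 2500 ms) and a \emph{production} regressor built only from Go
#' trials (a constant impulse at the onset of the first press, capturing
#' sequence initiation). Nuisance regressors: error trials (boxcar from
#' Sequence cue to the end of the intertrial interval), the preparation
#' period of Go trials (1000-2500 ms after the Sequence cue), and the
#' temporal derivative of every task and nuisance regressor. Everything is
#' convolved with the canonical HRF at microtime resolution (`TR/16`) and
#' sampled at the scan times; an intercept column is appended.
#'
#' @param events Data frame with one row per trial: `onset` (Sequence cue,
#'   s), `order` and `timing` (condition factors), `go` (logical),
#'   `first_press` (s, absolute run time; `NA` on No-Go trials), `error`
#'   (logical) and optionally `trial_end` (s, end of the ITI; required when
#'   error trials are present).
#' @param n_scans Number of volumes in the run.
#' @param TR Repetition time in seconds (default 2).
#' @param prep_duration Preparation boxcar length in seconds (default 2.5).
#' @param go_prep_window Start/end of the Go-trial preparation nuisance
#'   window relative to the Sequence cue (default `c(1, 2.5)` s).
#' @param derivatives Include temporal derivatives (default `TRUE`).
#' @param hrf Optional HRF kernel sampled at `TR/16`; defaults to
#'   [canonical_hrf()].
#' @return An object of class `"design_matrix"`: a list with `X` (scans x
#'   regressors, uniquely named columns `prep_o<o>t<t>`, `prod_o<o>t<t>`,
#'   `err`, `go_prep`, `d_<name>` for derivatives, `intercept`), `TR` and
#'   `names`.
#' @export
build_design <- function(events, n_scans, TR = 2, prep_duration = 2.5,
                         go_prep_window = c(1, 2.5), derivatives = TRUE,
                         hrf = NULL) {
  needed <- c("onset", "order", "timing", "go", "first_press", "error")
  if (!all(needed %in% names(events)))
    stop("'events' must have columns: ", paste(needed, collapse = ", "))
  run_len <- n_scans * TR
  if (any(events$onset < 0) || any(events$onset >= run_len))
    stop("event onsets must lie within the run (0 to ", run_len, " s)")
  if (any(events$error) && !"trial_end" %in% names(events))
    stop("'trial_end' is required when error trials are present")

  dt <- TR / 16
  if (is.null(hrf)) hrf <- canonical_hrf(dt)
  n_fine <- ceiling(run_len / dt) + length(hrf)
  t_fine <- (seq_len(n_fine) - 1) * dt
  scan_idx <- round((seq_len(n_scans) - 1) * TR / dt) + 1L

  boxcar <- function(starts, ends) {
    x <- numeric(n_fine)
    for (k in seq_along(starts)) {
      i0 <- floor(starts[k] / dt) + 1L
      i1 <- max(i0, ceiling(ends[k] / dt))
      x[i0:min(i1, n_fine)] <- 1
    }
    x
  }
  impulse <- function(times) {
    x <- numeric(n_fine)
    x[pmin(round(times / dt) + 1L, n_fine)] <- 1
    x
  }
  convolve_sample <- function(x) {
    y <- stats::convolve(x, rev(hrf), type = "open")[seq_len(n_fine)]
    y[scan_idx]
  }

  ok <- !events$error
  cols <- list(); fine <- list()
  for (o in sort(unique(events$order))) {
    for (tg in sort(unique(events$timing))) {
      sel_prep <- ok & !events$go & events$order == o & events$timing == tg
      sel_prod <- ok & events$go & events$order == o & events$timing == tg
      nm_prep <- sprintf("prep_o%dt%d", o, tg)
      nm_prod <- sprintf("prod_o%dt%d", o, tg)
      if (any(sel_prep)) {
        fine[[nm_prep]] <- boxcar(events$onset[sel_prep],
                                  events$onset[sel_prep] + prep_duration)
      } else {
        warning("no usable No-Go trials for condition o", o, "t", tg,
                "; preparation regressor omitted")
      }
      if (any(sel_prod)) {
        fp <- events$first_press[sel_prod]
        if (anyNA(fp)) stop("Go trials must have a 'first_press' time")
        fine[[nm_prod]] <- impulse(fp)
      } else {
        warning("no usable Go trials for condition o", o, "t", tg,
                "; production regressor omitted")
      }
    }
  }
  if (any(events$error)) {
    fine[["err"]] <- boxcar(events$onset[events$error],
                            events$trial_end[events$error])
  }
  sel_go <- ok & events$go
  if (any(sel_go)) {
    fine[["go_prep"]] <- boxcar(events$onset[sel_go] + go_prep_window[1],
                                events$onset[sel_go] + go_prep_window[2])
  }

  X <- vapply(fine, convolve_sample, numeric(n_scans))
  if (derivatives) {
    D <- apply(X, 2, function(col) c(0, diff(col)) / TR)
    colnames(D) <- paste0("d_", colnames(X))
    X <- cbind(X, D)
  }
  X <- cbind(X, intercept = 1)
  if (anyDuplicated(colnames(X))) stop("regressor names must be unique")
  structure(list(X = X, TR = TR, names = colnames(X)),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("design_matrix:", nrow(x$X), "scans x", ncol(x$X),
      "regressors (TR =", x$TR, "s)\n")
  invisible(x)
}
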