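#' Canonical double-gamma hemodynamic response function
#'
#' The conventional two-gamma HRF: a positive response gamma (delay 6 s,
#' dispersion 1 s) minus an undershoot gamma (delay 16 s, dispersion 1 s)
#' scaled by 1/6, evaluated over 32 s and normalized to unit peak. The peak
#' falls at about 5 s and the undershoot around 15 s.
#'
#' @param dt Sampling interval in seconds (> 0).
#' @param delay,u_delay Delay (gamma shape, with rate `1/dispersion`) of the
#'   response and undershoot components, in seconds.
#' @param dispersion,u_dispersion Dispersions of the two components (s).
#' @param ratio Response-to-undershoot amplitude ratio (default 6).
#' @param length_s Kernel support in seconds (default 32).
#' @return Numeric vector of the kernel sampled at `0, dt, 2*dt, ...` up to
#'   `length_s`, with `max(h) == 1` and `h[1] == 0`.
#' @examples
#' h <- canonical_hrf(0.1)
#' (which.max(h) - 1) * 0.1  # ~5 s
#' @export
canonical_hrf <- function(dt, delay = 6, u_delay = 16,
                          dispersion = 1, u_dispersion = 1,
                          ratio = 6, length_s = 32) {
  if (dt <= 0) stop("'dt' must be > 0")
  t <- seq(0, length_s, by = dt)
  h <- stats::dgamma(t, shape = delay / dispersion, scale = dispersion) -
    stats::dgamma(t, shape = u_delay / u_dispersion, scale = u_dispersion) / ratio
  h / max(h)
}
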