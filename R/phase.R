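#' Predict the mu phase at pulse time from pre-pulse data
#'
#' Implements an autoregressive forward-prediction phase estimator: the
#' last 500 ms of pre-pulse source signal are band-passed in the
#' individual mu band (`f_mu` +- 1 Hz, linear-phase FIR of order 64
#' applied forward-backward), trimmed by 64 ms at both ends to discard
#' filter edges, an AR(30) model (Burg recursion, which is unbiased on
#' short near-deterministic segments where Yule-Walker is not) is fitted and used to predict
#' the signal forward across the pulse, and the Hilbert phase of the
#' predicted segment spanning -64..+64 ms is read out at t = 0. Cosine
#' convention: phase 0 at a signal peak, +-pi at a trough.
#'
#' If the fitted AR model is unstable (poles on or outside the unit
#' circle), the estimator falls back to the Hilbert phase at the end of
#' the trimmed window advanced to t = 0 at `f_mu`, and flags the estimate.
#'
#' @param x Numeric vector, >= 500 samples of source signal ending at
#'   `t_end_ms` (ms before the pulse; default -4).
#' @param f_mu Individual mu frequency (Hz).
#' @param fs Sampling rate (Hz; 1 kHz assumed by the default windows).
#' @param t_end_ms Time of the last sample relative to the pulse (ms).
#' @param filter_order FIR band-pass order (default 64).
#' @param ar_order AR model order (default 30).
#'
#' @return List of class `phase_estimate`: `phase` (rad, in `(-pi, pi]`),
#'   `f_mu`, `flagged`, `method` metadata.
#' @export
estimate_phase_at_pulse <- function(x, f_mu, fs, t_end_ms = -4,
                                    filter_order = 64, ar_order = 30) {
  n <- length(x)
  if (n < 500 * fs / 1000) stop("need at least 500 ms of pre-pulse signal")
  fir <- signal::fir1(filter_order, c(f_mu - 1, f_mu + 1) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(fir, x)
  trim <- round(64 * fs / 1000)
  xt <- xf[(trim + 1):(n - trim)]
  t_last <- t_end_ms - trim * 1000 / fs # time of last trimmed sample (ms)

  fit <- stats::ar.burg(xt, aic = FALSE, order.max = ar_order, demean = TRUE)
  roots <- polyroot(c(1, -fit$ar))
  # near-unit-circle poles are the oscillation itself; flag only clearly
  # explosive fits (or predictions that blow up in amplitude)
  flagged <- any(Mod(roots) < 0.97)
  n_fwd <- round((64 - t_last) * fs / 1000)
  if (!flagged) {
    pred <- ar_extrapolate(xt, fit$ar, n_fwd, mean_x = fit$x.mean)
    if (max(abs(pred)) > 10 * max(abs(xt))) flagged <- TRUE
  }
  if (!flagged) {
    ext <- c(xt, pred)
    # predicted segment covering -64..+64 ms around the pulse
    n_seg <- round(128 * fs / 1000) + 1
    seg <- tail(ext, n_seg)
    a <- analytic_signal(seg)
    i0 <- n_seg - round(64 * fs / 1000) # index of t = 0
    phase <- Arg(a[i0])
  } else {
    # fallback: Hilbert phase read away from the window edge, advanced
    # deterministically at f_mu to t = 0
    a <- analytic_signal(xt)
    i0 <- length(xt) - round(64 * fs / 1000)
    t_read <- t_last - 64
    phase <- wrap_pi(Arg(a[i0]) + 2 * pi * f_mu * (-t_read) / 1000)
  }
  structure(
    list(
      phase = wrap_pi(phase), f_mu = f_mu, flagged = flagged,
      method = list(filter_order = filter_order, ar_order = ar_order)
    ),
    class = "phase_estimate"
  )
}
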