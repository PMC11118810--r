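#' Canonical motor-network source positions (MNI mm)
#'
#' Left primary motor cortex seed, left supplementary motor area and right
#' primary motor cortex centroids used throughout the package.
#'
#' @return Named list of length-3 numeric vectors.
#' @export
motor_positions <- function() {
  list(
    lM1  = c(-45.9, -9.9, 54.6),
    lSMA = c(-12, -11, 74),
    rM1  = c(40, -25, 52)
  )
}

#' Default analysis source grid
#'
#' A deterministic quasi-uniform grid of intracranial positions (MNI mm)
#' that always contains the three canonical motor nodes as its first three
#' entries. The grid stands in for a template source model at desk scale.
#'
#' @param n_sources Total number of sources (>= 3, default 50).
#' @return `n_sources x 3` matrix of positions.
#' @export
default_source_grid <- function(n_sources = 50) {
  stopifnot(n_sources >= 3)
  mp <- motor_positions()
  fixed <- rbind(mp$lM1, mp$lSMA, mp$rM1)
  # deterministic low-discrepancy fill of a brain-shaped ellipsoid
  n_extra <- n_sources - 3L
  pts <- matrix(NA_real_, n_extra, 3)
  if (n_extra > 0) {
    g <- 1.22074408460575947536 # 3D plastic-number sequence
    a <- 1 / c(g, g^2, g^3)
    k <- 0L
    i <- 0L
    centre <- c(0, -18, 28)
    semi <- c(62, 80, 58)
    while (k < n_extra) {
      i <- i + 1L
      u <- (0.5 + a * i) %% 1
      p <- centre + semi * (2 * u - 1)
      if (sum(((p - centre) / semi)^2) > 1) next
      if (min(sqrt(colSums((t(rbind(fixed, pts[seq_len(k), , drop = FALSE])) - p)^2))) < 14) next
      k <- k + 1L
      pts[k, ] <- p
    }
  }
  out <- rbind(fixed, pts)
  rownames(out) <- NULL
  out
}

#' Simulation configuration
#'
#' Defines one synthetic EEG-TMS session: mu-band oscillatory sources at the
#' motor nodes with trial-varying phase coupling to the lM1 seed, 1/f
#' background and sensor noise, instantaneous lead-field mixing, and MEP
#' amplitudes whose log depends on the per-trial coupling strengths and on
#' the mu phase at the pulse.
#'
#' @param n_trials Number of TMS pulses/trials (default 1000).
#' @param isi_jitter Inter-stimulus interval, seconds `c(mean, sd)`
#'   (bookkeeping only; epochs are generated directly).
#' @param fs_raw Acquisition rate in Hz (must be a multiple of `fs_out`).
#' @param fs_out Analysis rate in Hz.
#' @param n_sensors Number of EEG sensors (>= 8).
#' @param source_positions MNI positions; first row is the lM1 seed.
#' @param f_mu Individual mu frequency in Hz, within 9-13.
#' @param coupling_targets Data frame with one row per coupled node:
#'   `source` (index into the grid), `offset` (phase lag of the target
#'   relative to the seed, rad; non-zero offsets give non-zero iPLV),
#'   `kappa_mean` and `kappa_spread` (mean and SD of the per-trial Beta
#'   coupling weight in `[0,1]`), `lag_ms` (temporal lag; negative means the
#'   target *leads* the seed, creating directed coupling).
#' @param amp_source Oscillation amplitude at the coupled sources (a.u.,
#'   scaled to microvolts by the lead field).
#' @param phase_diffusion Phase-diffusion rate (rad / sqrt(s)) of the
#'   Wiener phase noise; sets the oscillators' spectral width.
#' @param noise List: `background` (1/f source noise amplitude relative to
#'   `amp_source`) and `sensor` (additive sensor noise SD, microvolts).
#' @param mep_model List of log-MEP model parameters: `beta0` (log mV),
#'   `beta_sma`, `beta_m1` (coupling effects on log amplitude), `beta_phase`
#'   (phase effect), `phi_star` (preferred phase, rad), `sigma` (trial noise
#'   SD of the shared log amplitude), `muscle_sigma` (independent per-muscle
#'   log jitter).
#' @param artifact List: `amplitude` (mV) and `tau` (ms) of the exponential
#'   stimulus artifact added to the EMG.
#' @param mep_latency,mep_width MEP waveform latency and Gaussian width (ms).
#' @param seed Integer RNG seed; identical configs give identical sessions.
#'
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_trials = 1000,
                       isi_jitter = c(2, 0.25),
                       fs_raw = 5000,
                       fs_out = 1000,
                       n_sensors = 32,
                       source_positions = default_source_grid(50),
                       f_mu = 11,
                       coupling_targets = data.frame(
                         name = c("lSMA", "rM1"),
                         source = c(2L, 3L),
                         # effective seed-target phase difference ~ pi/2:
                         # the -10 ms lag contributes 2*pi*f_mu*0.01 rad
                         offset = c(pi / 2 + 2 * pi * 11 * 0.01, pi / 2),
                         kappa_mean = c(0.6, 0.45),
                         kappa_spread = c(0.28, 0.28),
                         lag_ms = c(-10, 0),
                         detune_hz = c(0.7, -0.7)
                       ),
                       amp_source = 1,
                       phase_diffusion = 2.5,
                       noise = list(background = 1, sensor = 0.5),
                       mep_model = list(
                         beta0 = log(0.6), beta_sma = 0.4, beta_m1 = 0.25,
                         beta_phase = 0.15, phi_star = 0, sigma = 0.45,
                         muscle_sigma = 0.05
                       ),
                       artifact = list(amplitude = 3, tau = 5),
                       mep_latency = 25,
                       mep_width = 5,
                       seed = 1L) {
  if (f_mu < 9 || f_mu > 13) stop("f_mu must lie within 9-13 Hz")
  if (fs_raw %% fs_out != 0) stop("fs_raw must be an integer multiple of fs_out")
  source_positions <- as.matrix(source_positions)
  if (!all(is.finite(source_positions))) stop("source positions must be finite")
  ct <- as.data.frame(coupling_targets)
  stopifnot(all(c("source", "offset", "kappa_mean", "kappa_spread") %in% names(ct)))
  if (is.null(ct$lag_ms)) ct$lag_ms <- 0
  if (is.null(ct$detune_hz)) ct$detune_hz <- 0
  if (any(ct$kappa_mean < 0 | ct$kappa_mean > 1)) stop("kappa_mean must be in [0,1]")
  if (any(ct$kappa_spread < 0)) stop("kappa_spread must be >= 0")
  if (any(ct$source < 1 | ct$source > nrow(source_positions)) || any(ct$source == 1)) {
    stop("coupling target sources must index the grid and differ from the seed (source 1)")
  }
  structure(
    list(
      n_trials = as.integer(n_trials), isi_jitter = isi_jitter,
      fs_raw = fs_raw, fs_out = fs_out, n_sensors = as.integer(n_sensors),
      source_positions = source_positions, f_mu = f_mu,
      coupling_targets = ct, amp_source = amp_source,
      phase_diffusion = phase_diffusion, noise = noise,
      mep_model = mep_model, artifact = artifact,
      mep_latency = mep_latency, mep_width = mep_width,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d trials, %d sensors, %d sources, f_mu = %g Hz, seed %d\n",
    x$n_trials, x$n_sensors, nrow(x$source_positions), x$f_mu, x$seed
  ))
  invisible(x)
}

# per-trial Beta-distributed coupling weights with given mean and SD
draw_kappa <- function(n, mean, spread) {
  if (spread == 0) return(rep(mean, n))
  if (mean %in% c(0, 1)) return(rep(mean, n))
  v <- spread^2
  vmax <- mean * (1 - mean)
  if (v >= vmax) v <- 0.99 * vmax
  nu <- mean * (1 - mean) / v - 1
  rbeta(n, mean * nu, (1 - mean) * nu)
}
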