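#' Inject a biphasic MEP and stimulus artifact into an EMG trace
#'
#' Adds a biphasic motor-evoked-potential waveform (difference of two
#' Gaussians, scaled to the requested peak-to-peak amplitude on the trace's
#' own sample grid) at the given post-pulse latency, plus an exponential
#' stimulus artifact `A * exp(-t / tau)` from the pulse onward.
#'
#' @param trace Numeric EMG sample vector (mV).
#' @param time_ms Sample times (ms relative to the pulse), same length.
#' @param amplitude Peak-to-peak MEP amplitude in mV (>= 0).
#' @param latency_ms MEP latency (ms); must lie in the post-pulse half of
#'   the epoch.
#' @param width_ms Gaussian width of each MEP lobe (ms).
#' @param artifact List with `amplitude` (mV) and `tau` (ms) of the
#'   exponential stimulus artifact.
#'
#' @return The trace with MEP and artifact added.
#' @export
inject_mep <- function(trace, time_ms, amplitude, latency_ms = 25,
                       width_ms = 5,
                       artifact = list(amplitude = 0, tau = 5)) {
  if (amplitude < 0) stop("MEP amplitude must be >= 0")
  if (latency_ms <= 0 || latency_ms > max(time_ms)) {
    stop("latency must lie inside the post-pulse half of the epoch")
  }
  out <- trace + amplitude * mep_waveform(time_ms, latency_ms, width_ms)
  post <- time_ms >= 0
  out[post] <- out[post] + artifact$amplitude * exp(-time_ms[post] / artifact$tau)
  out
}

# biphasic waveform normalized to unit peak-to-peak on the given grid
mep_waveform <- function(time_ms, latency_ms, width_ms) {
  g <- exp(-(time_ms - latency_ms)^2 / (2 * width_ms^2)) -
    exp(-(time_ms - latency_ms - 1.2 * width_ms)^2 / (2 * width_ms^2))
  rng <- max(g) - min(g)
  if (rng == 0) return(g)
  g / rng
}

# Wiener phase trajectories: phi0 + 2*pi*f*t + diffusion, one column per trial
phase_walk <- function(times, n_trials, f, diffusion) {
  nt <- length(times)
  dt <- diff(times)
  incr <- matrix(rnorm((nt - 1) * n_trials), nt - 1, n_trials) *
    (diffusion * sqrt(dt))
  # column-wise cumulative sum without apply(): cumsum the column-major
  # vector, then remove the carried-over offset of the preceding columns
  cs <- matrix(cumsum(incr), nt - 1, n_trials)
  offs <- c(0, cs[nt - 1, -n_trials]) # running grand total before each column
  theta <- rbind(0, sweep(cs, 2, offs))
  phi0 <- matrix(runif(n_trials, -pi, pi), nt, n_trials, byrow = TRUE)
  phi0 + 2 * pi * f * times + theta
}

# 1/f (pink) noise, independent columns, unit SD
pink_noise <- function(n, k) {
  white <- matrix(rnorm(n * k), n, k)
  W <- mvfft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1) # symmetric frequency index
  W <- W / sqrt(f)
  x <- Re(mvfft(W, inverse = TRUE)) / n
  sweep(x, 2, apply(x, 2, sd), `/`)
}

# per-trial coupled phase trajectories for seed and targets
simulate_phase_set <- function(cfg, times) {
  fs <- cfg$fs_out
  K <- cfg$n_trials
  ct <- cfg$coupling_targets
  lag_samp <- round(ct$lag_ms * fs / 1000)
  pad <- max(abs(c(lag_samp, 0L)))
  dt <- 1 / fs
  t_ext <- seq(times[1] - pad * dt, by = dt, length.out = length(times) + 2 * pad)
  phi_seed_ext <- phase_walk(t_ext, K, cfg$f_mu, cfg$phase_diffusion)
  core <- pad + seq_along(times)
  phi_seed <- phi_seed_ext[core, , drop = FALSE]

  kappa <- matrix(NA_real_, K, nrow(ct))
  phi_targets <- vector("list", nrow(ct))
  for (i in seq_len(nrow(ct))) {
    kappa[, i] <- draw_kappa(K, ct$kappa_mean[i], ct$kappa_spread[i])
    psi <- phase_walk(times, K, cfg$f_mu + ct$detune_hz[i], cfg$phase_diffusion)
    # target tracks the (lagged) seed phase plus the configured offset;
    # entrainment strength is the per-trial convex weight kappa
    phi_drive <- phi_seed_ext[core - lag_samp[i], , drop = FALSE] - ct$offset[i]
    pull <- wrap_fast(phi_drive - psi)
    phi_targets[[i]] <- psi + sweep(pull, 2, kappa[, i], `*`)
  }
  list(phi_seed = phi_seed, phi_targets = phi_targets, kappa = kappa)
}

# shared log-MEP model: returns per-trial list of log amplitudes
mep_log_amplitudes <- function(cfg, kappa, phase_at_pulse) {
  mm <- cfg$mep_model
  ct <- cfg$coupling_targets
  betas <- numeric(nrow(ct))
  # convention: first coupling target carries the SMA effect, second the rM1
  if (nrow(ct) >= 1) betas[1] <- mm$beta_sma
  if (nrow(ct) >= 2) betas[2] <- mm$beta_m1
  lin <- mm$beta0 + as.vector(kappa %*% betas) +
    mm$beta_phase * cos(phase_at_pulse - mm$phi_star)
  K <- length(phase_at_pulse)
  log_shared <- lin + rnorm(K, sd = mm$sigma)
  ms <- mm$muscle_sigma %||% 0.05
  out <- list(
    true = lin,
    fdi = log_shared + rnorm(K, sd = ms),
    apb = log_shared + rnorm(K, sd = ms)
  )
  if (!all(is.finite(exp(out$fdi))) || !all(is.finite(exp(out$apb)))) {
    stop("mep_model produced non-finite amplitudes")
  }
  out
}

#' Simulate a full synthetic EEG-TMS session
#'
#' Generates epoched pre-pulse EEG (lead-field-mixed coupled mu oscillators
#' plus 1/f background sources and sensor noise), epoched EMG with stimulus
#' artifact and MEPs, the lead field used for mixing, and a ground-truth
#' table of per-trial coupling weights, seed phase at the pulse and
#' noiseless log-MEP.
#'
#' EEG epochs span -1004..-4 ms at `fs_out` (1000 samples at 1 kHz); the
#' seed phase is propagated to t = 0 for the ground-truth pulse phase. EMG
#' is synthesized at `fs_raw` over -500..+500 ms and decimated to `fs_out`.
#'
#' @param cfg A [sim_config()].
#' @return Object of class `synthetic_session`: list with elements `eeg`,
#'   `emg` ([epoched_recording]s), `leadfield` ([lead_field], free
#'   orientation), `truth` (tibble) and `config`.
#' @export
simulate_session <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  fs <- cfg$fs_out
  K <- cfg$n_trials
  ct <- cfg$coupling_targets
  n_src <- nrow(cfg$source_positions)

  lf <- make_lead_field(cfg$n_sensors, cfg$source_positions, seed = cfg$seed)
  lfr <- reduce_orientation(lf)

  # phases on -1004 ms .. 0 (pulse); EEG epoch keeps the first 1000 samples
  n_epoch <- round(1000 * fs / 1000)
  times_full <- seq(-1.004, by = 1 / fs, length.out = n_epoch + round(0.004 * fs) + 1)
  ph <- simulate_phase_set(cfg, times_full)
  idx_epoch <- seq_len(n_epoch)
  i_pulse <- length(times_full)
  phase_at_pulse <- wrap_pi(ph$phi_seed[i_pulse, ])

  # source signals -> sensors; the oscillation is band-limited around f_mu
  # (coupling lives in the mu band; out-of-band tails of the phase-diffusion
  # process would otherwise stay quadrature-coherent at all frequencies)
  # and each coupled source carries its own broadband noise floor
  coupled_idx <- c(1L, ct$source)
  eeg <- array(0, dim = c(cfg$n_sensors, n_epoch, K))
  bw_gen <- cfg$gen_bandwidth %||% 4
  bf_gen <- signal::butter(4, c(cfg$f_mu - bw_gen / 2, cfg$f_mu + bw_gen / 2) / (fs / 2),
                           type = "pass")
  src_noise <- cfg$noise$source %||% 0.3
  sigs <- vector("list", length(coupled_idx))
  sigs[[1]] <- cos(ph$phi_seed[idx_epoch, , drop = FALSE])
  for (i in seq_len(nrow(ct))) {
    sigs[[i + 1]] <- cos(ph$phi_targets[[i]][idx_epoch, , drop = FALSE])
  }
  for (i in seq_along(coupled_idx)) {
    s_bl <- apply(sigs[[i]], 2, function(col) zero_phase_bandpass(bf_gen, col, fs))
    s_bl <- cfg$amp_source * (s_bl + src_noise * pink_noise(n_epoch, K))
    col <- lfr$gain[, coupled_idx[i]]
    eeg <- eeg + outer(col, s_bl) # sensors x time x trials
  }
  bg_amp <- cfg$noise$background * cfg$amp_source
  if (bg_amp > 0) {
    bg_src <- setdiff(seq_len(n_src), coupled_idx)
    for (j in bg_src) {
      s <- bg_amp * pink_noise(n_epoch, K)
      eeg <- eeg + outer(lfr$gain[, j], s)
    }
  }
  if (cfg$noise$sensor > 0) {
    eeg <- eeg + array(rnorm(length(eeg), sd = cfg$noise$sensor), dim = dim(eeg))
  }
  dim(eeg) <- c(cfg$n_sensors, n_epoch, K)
  eeg_rec <- epoched_recording(
    eeg, fs, seq(-1004, by = 1000 / fs, length.out = n_epoch),
    role = "eeg"
  )

  # EMG at fs_raw over -500..+500 ms, then decimated
  logs <- mep_log_amplitudes(cfg, ph$kappa, phase_at_pulse)
  n_raw <- cfg$fs_raw # 1 s of samples
  t_raw <- seq(-500, by = 1000 / cfg$fs_raw, length.out = n_raw)
  wf <- mep_waveform(t_raw, cfg$mep_latency, cfg$mep_width)
  art <- numeric(n_raw)
  post <- t_raw >= 0
  art[post] <- cfg$artifact$amplitude * exp(-t_raw[post] / cfg$artifact$tau)
  emg_sd <- cfg$noise$emg_sd %||% 0.01 # mV
  q <- cfg$fs_raw / fs
  n_dec <- n_raw / q
  emg <- array(NA_real_, dim = c(2, n_dec, K))
  for (m in 1:2) {
    amps <- exp(if (m == 1) logs$fdi else logs$apb)
    raw <- outer(wf, amps) + art +
      matrix(rnorm(n_raw * K, sd = emg_sd), n_raw, K)
    emg[m, , ] <- decimate_matrix(raw, q)
  }
  emg_rec <- epoched_recording(
    emg, fs, seq(-500, by = 1000 / fs, length.out = n_dec),
    labels = c("FDI", "APB"), role = "emg"
  )

  truth <- tibble::tibble(trial = seq_len(K))
  nm <- ct$name %||% paste0("src", ct$source)
  for (i in seq_len(nrow(ct))) truth[[paste0("kappa_", nm[i])]] <- ph$kappa[, i]
  truth$phase <- phase_at_pulse
  truth$log_mep_true <- logs$true

  structure(
    list(eeg = eeg_rec, emg = emg_rec, leadfield = lf, truth = truth,
         config = cfg),
    class = "synthetic_session"
  )
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf(
    "<synthetic_session> %d trials, %d sensors, %d sources, f_mu = %g Hz\n",
    n_trials(x$eeg), dim(x$eeg)[1], nrow(x$leadfield$positions), x$config$f_mu
  ))
  invisible(x)
}

#' Fast source-level simulation of per-trial quantities
#'
#' Generates the same per-trial ground truth as [simulate_session()] —
#' coupling weights, seed/target phase trajectories, pulse phase and MEP
#' amplitudes — but computes per-trial iPLV directly from the source phase
#' trajectories instead of synthesizing, mixing and inverting sensor-level
#' data. Intended for large calibration and power studies where thousands
#' of sessions are needed; the full sensor-level path is validated
#' separately by the round-trip tests.
#'
#' @param cfg A [sim_config()].
#' @return Tibble with one row per trial: `kappa_*` and `iplv_*` per
#'   coupling target, `phase` (seed phase at the pulse, rad), `log_mep_true`,
#'   per-muscle log amplitudes and `mep_linear` (geometric mean, mV).
#' @export
simulate_trial_table <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  fs <- cfg$fs_out
  n_epoch <- round(1000 * fs / 1000)
  n_core <- n_epoch + round(0.004 * fs) + 1 # epoch samples + gap + pulse
  ct <- cfg$coupling_targets
  nm <- ct$name %||% paste0("src", ct$source)
  K <- cfg$n_trials
  kappa <- matrix(NA_real_, K, nrow(ct))
  for (i in seq_len(nrow(ct))) {
    kappa[, i] <- draw_kappa(K, ct$kappa_mean[i], ct$kappa_spread[i])
  }
  lag_samp <- as.integer(round(ct$lag_ms * fs / 1000))
  pad <- max(abs(c(lag_samp, 0L)))
  sim <- cpp_phase_iplv(
    K, n_core, n_epoch, pad, 1 / fs, cfg$f_mu, cfg$phase_diffusion,
    as.numeric(ct$offset), as.numeric(ct$detune_hz), lag_samp, kappa
  )
  phase_at_pulse <- sim$phase_at_pulse

  out <- tibble::tibble(trial = seq_len(K))
  for (i in seq_len(nrow(ct))) {
    out[[paste0("kappa_", nm[i])]] <- kappa[, i]
    out[[paste0("iplv_", nm[i])]] <- sim$iplv[, i]
  }
  logs <- mep_log_amplitudes(cfg, kappa, phase_at_pulse)
  out$phase <- phase_at_pulse
  out$log_mep_true <- logs$true
  out$log_fdi <- logs$fdi
  out$log_apb <- logs$apb
  out$mep_linear <- exp((logs$fdi + logs$apb) / 2)
  out
}

#' Simulate a cohort of synthetic subjects
#'
#' One synthetic subject is one session; a cohort jitters the individual mu
#' frequency and the MEP effect sizes across subjects.
#'
#' @param n_subjects Number of subjects (default 8).
#' @param cfg Base [sim_config()]; per-subject configs jitter `f_mu`
#'   (SD 1 Hz, clipped to 9-13) and the `beta` effects (20% relative SD).
#' @param seed Cohort seed.
#' @param mode `"table"` for the fast source-level path (default) or
#'   `"session"` for full sensor-level sessions.
#' @return List with `subjects` (list of tables or sessions) and `params`
#'   (tibble of per-subject generator parameters).
#' @export
simulate_cohort <- function(n_subjects = 8, cfg = sim_config(), seed = 1L,
                            mode = c("table", "session")) {
  mode <- match.arg(mode)
  set.seed(seed)
  f_mus <- pmin(13, pmax(9, cfg$f_mu + rnorm(n_subjects)))
  jit <- function(x) x * (1 + 0.2 * rnorm(n_subjects))
  b_sma <- jit(rep(cfg$mep_model$beta_sma, n_subjects))
  b_m1 <- jit(rep(cfg$mep_model$beta_m1, n_subjects))
  b_ph <- jit(rep(cfg$mep_model$beta_phase, n_subjects))
  seeds <- sample.int(.Machine$integer.max %/% 2, n_subjects)
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    cfg_s <- cfg
    cfg_s$f_mu <- f_mus[s]
    cfg_s$mep_model$beta_sma <- b_sma[s]
    cfg_s$mep_model$beta_m1 <- b_m1[s]
    cfg_s$mep_model$beta_phase <- b_ph[s]
    cfg_s$seed <- seeds[s]
    subjects[[s]] <- if (mode == "table") simulate_trial_table(cfg_s) else simulate_session(cfg_s)
  }
  list(
    subjects = subjects,
    params = tibble::tibble(
      subject = seq_len(n_subjects), f_mu = f_mus,
      beta_sma = b_sma, beta_m1 = b_m1, beta_phase = b_ph, seed = seeds
    )
  )
}
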