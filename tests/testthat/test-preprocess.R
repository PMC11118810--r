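test_that("epoching and decimation preserve in-band signals and reject aliases", {
  fs_raw <- 5000
  t_raw <- seq(0, 30, by = 1 / fs_raw)
  x10 <- sin(2 * pi * 10 * t_raw)
  x800 <- sin(2 * pi * 800 * t_raw)
  raw <- rbind(x10, x800)
  pulses <- round(seq(6, 29, by = 2.2) * fs_raw)

  ep <- epoch_and_downsample(raw, fs_raw, pulses)
  expect_equal(dim(ep$data)[2:3], c(1000L, length(pulses)))
  expect_equal(ep$fs, 1000)
  expect_equal(ep$time_ms[1], -1004)

  amp10 <- max(ep$data[1, , 1]) # in-band amplitude preserved
  expect_lt(abs(amp10 - 1), 0.01)
  amp800 <- max(abs(ep$data[2, , ])) # above-Nyquist content attenuated
  expect_lt(20 * log10(amp800 / 1), -20)

  expect_error(
    epoch_and_downsample(raw, fs_raw, c(1000L)),
    "pulse 1"
  )
})

test_that("robust variance flags pick out bad channels and trials", {
  set.seed(2)
  mk <- function(data) epoched_recording(data, 1000, seq_len(dim(data)[2]), role = "eeg")

  clean_ok <- vapply(1:20, function(r) {
    d <- array(rnorm(16 * 200 * 30), c(16, 200, 30))
    b <- detect_bad(mk(d), z_thresh = 5)
    length(b$bad_channels) == 0 && length(b$bad_trials) == 0
  }, logical(1))
  expect_gte(mean(clean_ok), 0.95)

  d <- array(rnorm(8 * 200 * 15), c(8, 200, 15))
  d[3, , ] <- d[3, , ] * 100
  expect_equal(detect_bad(mk(d))$bad_channels, 3L)

  d <- array(rnorm(8 * 200 * 15, sd = 1e-3), c(8, 200, 15))
  d[, 100:200, 7] <- d[, 100:200, 7] + 1 # 1 mV step (data in mV-scale units)
  expect_equal(detect_bad(mk(d))$bad_trials, 7L)

  # idempotence on clean data: removing nothing, a second pass flags nothing
  b2 <- detect_bad(mk(array(rnorm(8 * 200 * 15), c(8, 200, 15))))
  expect_length(b2$bad_channels, 0)

  expect_error(detect_bad(mk(array(rnorm(3 * 50 * 12), c(3, 50, 12)))), "channels")
})

test_that("mu-component selection applies the three criteria", {
  # controlled ICs: an 11 Hz motor component, a 21 Hz component, white noise
  ses <- small_session()
  lfr <- reduce_orientation(ses$leadfield)
  filt <- eloreta_filter(lfr)
  fs <- 1000
  tt <- seq(0, by = 1 / fs, length.out = 1000 * 6)
  set.seed(4)
  tc <- rbind(
    sin(2 * pi * 11 * tt) + 0.05 * rnorm(length(tt)),
    sin(2 * pi * 21 * tt) + 0.05 * rnorm(length(tt)),
    rnorm(length(tt))
  )
  ica <- list(
    timecourses = array(tc, c(3, 1000, 6)),
    topographies = cbind(lfr$gain[, 1], lfr$gain[, 10], rnorm(32)),
    dims = c(32, 1000, 6)
  )
  sel <- select_mu_components(ica, filt, motor_mask(lfr$positions), fs)
  expect_true(sel$selection$kept[1])
  expect_false(sel$selection$kept[2]) # beta-dominant: mu/beta ratio < 5
  expect_false(sel$selection$kept[3]) # no 9-13 Hz peak
  expect_equal(sel$profile$f_mu, 11)

  # no passing IC -> subject excluded
  ica_bad <- ica
  ica_bad$timecourses <- ica$timecourses[2:3, , , drop = FALSE]
  ica_bad$topographies <- ica$topographies[, 2:3]
  expect_error(
    select_mu_components(ica_bad, filt, motor_mask(lfr$positions), fs),
    "no μ component"
  )
})

test_that("ICA decomposition separates sources and reconstruction is exact", {
  ses <- small_session()
  ica <- run_ica(ses$eeg, n_comp = 10, seed = 1)

  # keeping every component reproduces the rank-10 projection of the
  # centered data
  rec <- reconstruct_clean(ica, 1:10, 1000, ses$eeg$time_ms)
  d <- dim(ses$eeg$data)
  X <- matrix(ses$eeg$data, d[1], d[2] * d[3])
  Xc <- X - rowMeans(X)
  sv <- svd(Xc, nu = 10, nv = 0)
  proj <- sv$u %*% crossprod(sv$u, Xc)
  expect_lt(
    max(abs(matrix(rec$data, d[1], d[2] * d[3]) - proj)),
    1e-6 * max(abs(Xc))
  )

  # a single kept component gives rank-1 trials
  rec1 <- reconstruct_clean(ica, 3, 1000, ses$eeg$time_ms)
  expect_equal(qr(rec1$data[, , 1])$rank, 1L)

  # order invariance
  recA <- reconstruct_clean(ica, c(1, 2), 1000, ses$eeg$time_ms)
  recB <- reconstruct_clean(ica, c(2, 1), 1000, ses$eeg$time_ms)
  expect_identical(recA$data, recB$data)

  expect_error(reconstruct_clean(ica, integer(0), 1000, ses$eeg$time_ms), "empty")
})

test_that("MEP extraction round-trips injected amplitudes", {
  t_ms <- emg_time_ms()
  z <- numeric(length(t_ms))
  mk <- function(traces) {
    K <- length(traces)
    arr <- array(NA_real_, c(2, length(t_ms), K))
    for (k in seq_len(K)) arr[1, , k] <- arr[2, , k] <- traces[[k]]
    epoched_recording(arr, 1000, t_ms, labels = c("FDI", "APB"), role = "emg")
  }

  m <- extract_mep(mk(list(inject_mep(z, t_ms, 1.0))))
  expect_lt(abs(m$p2p_fdi[1] - 1.0), 0.01)

  m2 <- extract_mep(mk(list(
    inject_mep(z, t_ms, 0.5, artifact = list(amplitude = 5, tau = 5))
  )))
  expect_lt(abs(m2$p2p_fdi[1] - 0.5) / 0.5, 0.10)

  tonic <- inject_mep(z + c(rnorm(500, sd = 0.2), numeric(500)), t_ms, 1)
  m3 <- extract_mep(mk(list(tonic)))
  expect_true(m3$rejected[1])
  expect_equal(m3$reason[1], "pre-stimulus activity")

  # non-convergent artifact fit falls back to no subtraction, flagged
  m4 <- extract_mep(mk(list(inject_mep(z, t_ms, 0.5, artifact = list(amplitude = 0, tau = 5)))))
  expect_true(m4$artifact_fit_failed[1]) # all-zero artifact window
  expect_lt(abs(m4$p2p_fdi[1] - 0.5), 0.01)
})

test_that("amplitude grid is recovered within noise-floor limits", {
  set.seed(2)
  t_ms <- emg_time_ms()
  amps <- exp(seq(log(0.05), log(5), length.out = 10))
  arr <- array(NA_real_, c(2, length(t_ms), length(amps)))
  for (k in seq_along(amps)) {
    for (mm in 1:2) {
      arr[mm, , k] <- inject_mep(rnorm(length(t_ms), sd = 0.01), t_ms, amps[k],
        artifact = list(amplitude = 3, tau = 5)
      )
    }
  }
  m <- extract_mep(epoched_recording(arr, 1000, t_ms, role = "emg"))
  err <- abs(m$p2p_fdi - amps)
  big <- amps >= 0.5
  expect_true(all(err[big] / amps[big] <= 0.05))
  expect_true(all(err[!big] <= 0.040)) # absolute noise floor (mV)
})

test_that("PC1 of the log-MEP table behaves like a principal component should", {
  set.seed(8)
  x <- rnorm(200)
  pc <- mep_pc1(x, x)
  expect_equal(pc$variance_explained, 1.0)
  expect_gt(cor(pc$score, x), 0.999)

  a <- rnorm(10000)
  b <- rnorm(10000)
  expect_lt(abs(mep_pc1(a, b)$variance_explained - 0.5), 0.02)

  base <- rnorm(5000)
  a2 <- base + 0.1 * rnorm(5000) # r ~ 0.995
  b2 <- base + 0.1 * rnorm(5000)
  expect_gte(mep_pc1(a2, b2)$variance_explained, 0.99)

  expect_error(mep_pc1(rep(1, 20), rep(2, 20)), "zero variance")
  expect_error(mep_pc1(rnorm(5), rnorm(5)), "at least 10")
})
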