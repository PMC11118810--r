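test_that("voxel patches are exact Euclidean neighbourhoods", {
  pos <- default_source_grid(50)
  p <- select_voxel_patch(pos, motor_positions()$lM1, radius_mm = 4)
  expect_equal(p$members, 1L) # grid spacing exceeds the radius

  expect_equal(select_voxel_patch(pos, pos[7, ], radius_mm = 0)$members, 7L)
  expect_error(select_voxel_patch(pos, c(500, 0, 0), 4), "radius")

  set.seed(2)
  cloud <- matrix(rnorm(900, sd = 10), 300, 3)
  centre <- c(1, -2, 3)
  p2 <- select_voxel_patch(cloud, centre, radius_mm = 8)
  brute <- which(sqrt(rowSums(sweep(cloud, 2, centre)^2)) <= 8)
  expect_equal(p2$members, brute)
})

test_that("cross-spectra are Hermitian with unit self-coherence", {
  set.seed(7)
  x <- rnorm(20 * 1000)
  X <- rbind(x, x)
  cs <- cross_spectra(X[1, , drop = FALSE], X[2, , drop = FALSE], 9:13, 1000)
  for (fi in seq_along(cs$freqs)) {
    S <- cs$mean[, , fi]
    expect_equal(S, Conj(t(S)), tolerance = 1e-12) # Hermitian
    coh <- Mod(S[1, 2]) / sqrt(Re(S[1, 1]) * Re(S[2, 2]))
    expect_equal(coh, 1, tolerance = 1e-10)
  }

  # independent white noise: off-diagonal coherence vanishes (the
  # magnitude bias of the coherency estimate is ~sqrt(pi / (4 N_seg)))
  cs2 <- cross_spectra(
    matrix(rnorm(3000 * 1000), 1), matrix(rnorm(3000 * 1000), 1), 9:13, 1000
  )
  coh <- vapply(seq_len(5), function(fi) {
    S <- cs2$mean[, , fi]
    Mod(S[1, 2]) / sqrt(Re(S[1, 1]) * Re(S[2, 2]))
  }, numeric(1))
  expect_lt(mean(coh), 0.02)

  expect_error(cross_spectra(X[1, 1:5000, drop = FALSE], X[2, 1:5000, drop = FALSE], 9:13, 1000), "8 segments")
})

test_that("bivariate MPSI agrees with the direct PSI oracle and is antisymmetric", {
  set.seed(8)
  fs <- 1000
  nt <- 30 * fs
  bf <- signal::butter(4, c(9, 13) / (fs / 2), type = "pass")
  s <- signal::filtfilt(bf, rnorm(nt + 100))
  x <- s[101:(nt + 100)] + 0.2 * rnorm(nt)
  y <- s[(101 - 10):(nt + 100 - 10)] + 0.2 * rnorm(nt)

  cs <- cross_spectra(rbind(x), rbind(y), 9:13, fs)
  psi_pkg <- mpsi(cs, reg = 0)
  psi_ref <- oracle_psi(x, y, 9:13, fs)
  expect_lt(abs(psi_pkg - psi_ref), 1e-10)
  expect_gt(psi_pkg, 0) # x leads y

  cs_rev <- cross_spectra(rbind(y), rbind(x), 9:13, fs)
  expect_equal(mpsi(cs_rev), -mpsi(cs), tolerance = 1e-12)

  expect_error(mpsi(cs, band = c(9, 9)), "2 analysis frequencies")
})

test_that("MPSI is invariant to voxel order within a patch", {
  set.seed(9)
  fs <- 1000
  nt <- 15 * fs
  bf <- signal::butter(4, c(9, 13) / (fs / 2), type = "pass")
  s <- signal::filtfilt(bf, rnorm(nt + 100))[101:(nt + 100)]
  X <- rbind(s, 0.8 * s, 1.2 * s) + matrix(rnorm(3 * nt, sd = 0.3), 3)
  Y <- rbind(
    c(s[-(1:8)], numeric(8)),
    0.7 * c(s[-(1:8)], numeric(8))
  ) + matrix(rnorm(2 * nt, sd = 0.3), 2)
  psi1 <- mpsi(cross_spectra(X, Y, 9:13, fs))
  psi2 <- mpsi(cross_spectra(X[c(3, 1, 2), ], Y, 9:13, fs))
  expect_equal(psi1, psi2, tolerance = 1e-10)
})

test_that("jackknife pseudo-Z matches a brute-force leave-one-out oracle", {
  set.seed(10)
  fs <- 1000
  nt <- 20 * fs
  bf <- signal::butter(4, c(9, 13) / (fs / 2), type = "pass")
  s <- signal::filtfilt(bf, rnorm(nt + 100))[101:(nt + 100)]
  x <- s + 0.3 * rnorm(nt)
  y <- c(s[-(1:10)], numeric(10)) + 0.3 * rnorm(nt)
  cs <- cross_spectra(rbind(x), rbind(y), 9:13, fs)
  dr <- jackknife_pseudo_z(cs)

  N <- cs$n_segments
  loo <- vapply(seq_len(N), function(i) {
    keep <- setdiff(seq_len(N), i)
    S <- apply(cs$per_segment[, , , keep, drop = FALSE], c(1, 2, 3), mean)
    mnstate:::mpsi_from_S(S, 1, 1, seq_along(cs$freqs), 1e-8)
  }, numeric(1))
  sd_ref <- sqrt((N - 1) / N * sum((loo - mean(loo))^2))
  expect_equal(dr$jackknife_sd, sd_ref, tolerance = 1e-10)
  expect_equal(dr$pseudo_z, dr$psi / sd_ref)

  # identical segments: zero jackknife SD is flagged, never divided
  seg <- sin(2 * pi * 11 * seq_len(fs) / fs)
  xs <- rep(seg, 10)
  cs0 <- cross_spectra(rbind(xs), rbind(xs), 9:13, fs)
  dr0 <- jackknife_pseudo_z(cs0)
  expect_true(dr0$flagged)
  expect_true(is.na(dr0$pseudo_z))
})

test_that("undirected zero-lag coupling stays below the significance threshold", {
  set.seed(11)
  fs <- 1000
  nt <- 30 * fs
  bf <- signal::butter(4, c(9, 13) / (fs / 2), type = "pass")
  hits <- vapply(1:60, function(r) {
    s <- signal::filtfilt(bf, rnorm(nt + 100))[101:(nt + 100)]
    x <- s + 0.5 * rnorm(nt)
    y <- 0.8 * s + 0.5 * rnorm(nt) # zero-lag mixture, no direction
    dr <- jackknife_pseudo_z(cross_spectra(rbind(x), rbind(y), 9:13, fs))
    abs(dr$pseudo_z) < 1.96
  }, logical(1))
  expect_gte(mean(hits), 0.85) # ~95% nominal coverage
})

test_that("group Z aggregates subject pseudo-Z scores", {
  expect_equal(group_z(c(-1, -1, -1, -1))$z, -2)
  expect_equal(group_z(2.5)$z, 2.5)
  expect_equal(group_z(c(0, 0))$p, 1)

  set.seed(12)
  zs <- matrix(rnorm(8 * 1e5), 8)
  Z <- sqrt(8) * colMeans(zs)
  expect_lt(abs(mean(Z)), 0.02)
  expect_lt(abs(var(Z) - 1), 0.02)
  # agrees with the package on a handful of draws
  expect_equal(group_z(zs[, 1])$z, Z[1])
})

test_that("the generator's directed chain shows the expected lead-lag pattern", {
  ses <- memo("dir_session", simulate_session(sim_config(n_trials = 100, seed = 11)))
  src <- memo("dir_sources", {
    project_sources(eloreta_filter(reduce_orientation(ses$leadfield)), ses$eeg)
  })
  f_mu <- ses$config$f_mu
  # lSMA leads lM1 by construction (negative generator lag)
  cs_sma <- cross_spectra(
    matrix(src[2, , ], 1), matrix(src[1, , ], 1),
    (f_mu - 2):(f_mu + 2), 1000
  )
  dr_sma <- jackknife_pseudo_z(cs_sma, pair = c("lSMA", "lM1"))
  expect_gt(dr_sma$psi, 0)
  expect_gt(dr_sma$pseudo_z, 1.5)

  # lM1 and rM1 are mutually undriven: no significant direction
  cs_ctl <- cross_spectra(
    matrix(src[1, , ], 1), matrix(src[3, , ], 1),
    (f_mu - 2):(f_mu + 2), 1000
  )
  dr_ctl <- jackknife_pseudo_z(cs_ctl, pair = c("lM1", "rM1"))
  expect_lt(abs(dr_ctl$pseudo_z), 2.5)
})
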