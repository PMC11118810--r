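test_that("narrowband analytic signal behaves as a band-pass eigenfunction", {
  fs <- 1000
  tt <- seq(0, 0.999, by = 1 / fs)
  x <- sin(2 * pi * 11 * tt)
  ae <- narrowband_analytic(x, f_c = 11, fs = fs)

  # envelope near-constant: within 2% away from the pad-adjacent samples,
  # bounded Gibbs wobble (< 5%) at the outermost samples
  ev <- ae$envelope
  expect_lt(diff(range(ev[100:900])) / mean(ev), 0.02)
  expect_lt(diff(range(ev)) / mean(ev), 0.05)
  expect_lt(sd(ev) / mean(ev), 0.01)

  # phase advances by 2*pi*f_c per second
  dphi <- diff(ae$phase)
  dphi <- atan2(sin(dphi), cos(dphi))
  expect_equal(mean(dphi) * fs, 2 * pi * 11, tolerance = 0.01)

  # out-of-band tone attenuated below 10% of the in-band response
  y <- sin(2 * pi * 16 * tt)
  ay <- narrowband_analytic(y, f_c = 11, fs = fs)
  expect_lt(median(ay$envelope) / median(ae$envelope), 0.10)

  expect_error(narrowband_analytic(x[1:100], 11, fs), "too short")
})

test_that("AR padding beats zero padding at the window edges", {
  fs <- 1000
  tt <- seq(0, 0.999, by = 1 / fs)
  set.seed(6)
  pink1 <- function(n) {
    W <- fft(rnorm(n))
    f <- pmin(c(1, 1:(n - 1)), n - c(1, 1:(n - 1)) + 1)
    x <- Re(fft(W / sqrt(f), inverse = TRUE)) / n
    x / sd(x)
  }
  edge <- c(1:64, (1000 - 63):1000)
  wins <- vapply(1:60, function(r) {
    x <- sin(2 * pi * 11 * tt + runif(1, -pi, pi)) + 0.3 * pink1(1000)
    # reference envelope from a long surround (no edge effects)
    xl <- c(x, x, x)
    ref <- narrowband_analytic(xl, 11, fs, pad_ms = 0)$envelope[1001:2000]
    ar <- narrowband_analytic(x, 11, fs)$envelope
    zp <- {
      bf <- signal::butter(4, c(10, 12) / (fs / 2), type = "pass")
      xf <- signal::filtfilt(bf, x)
      a <- mnstate:::analytic_signal(c(numeric(64), xf, numeric(64)))
      Mod(a)[65:1064]
    }
    mean(abs(ar[edge] - ref[edge])) < mean(abs(zp[edge] - ref[edge]))
  }, logical(1))
  expect_gt(mean(wins), 0.5) # AR padding smaller edge error in the median run
})

test_that("iPLV identities hold exactly", {
  phi <- runif(1000, -pi, pi)
  expect_equal(iplv_trial(phi + pi / 2, phi), 1.0)
  expect_equal(iplv_trial(phi, phi), 0.0)

  # invariance to a common phase offset and to argument swap
  a <- cumsum(rnorm(500, sd = 0.1)) + 2 * pi * 11 * seq_len(500) / 1000
  b <- cumsum(rnorm(500, sd = 0.1)) + 2 * pi * 11 * seq_len(500) / 1000
  expect_equal(iplv_trial(a, b), iplv_trial(a + 1.3, b + 1.3))
  expect_equal(iplv_trial(a, b), iplv_trial(b, a))

  expect_error(iplv_trial(c(a, NA), c(b, 1)), "NaN")
  expect_error(iplv_trial(1, 1), "length")
})

test_that("uniform-phase null matches the closed-form expectation", {
  set.seed(10)
  T_len <- 1000
  vals <- vapply(seq_len(3000), function(r) {
    iplv_trial(runif(T_len, -pi, pi), runif(T_len, -pi, pi))
  }, numeric(1))
  expect_lt(abs(mean(vals) - 1 / sqrt(pi * T_len)) / (1 / sqrt(pi * T_len)), 0.05)
})

test_that("seed maps recover coupled targets and ignore zero-lag copies", {
  fs <- 1000
  K <- 30
  tt <- seq(0, 0.999, by = 1 / fs)
  set.seed(12)
  # 4 synthetic sources: seed, quarter-cycle coupled target, zero-lag
  # scaled copy of the seed, independent target
  src <- array(NA_real_, c(4, 1000, K))
  for (k in seq_len(K)) {
    ph <- cumsum(c(runif(1, -pi, pi), rnorm(999, sd = 2.5 / sqrt(fs)))) + 2 * pi * 11 * tt
    ph_i <- cumsum(c(runif(1, -pi, pi), rnorm(999, sd = 2.5 / sqrt(fs)))) + 2 * pi * 11.7 * tt
    src[1, , k] <- cos(ph)
    src[2, , k] <- cos(ph - pi / 2)
    src[3, , k] <- 0.5 * cos(ph)
    src[4, , k] <- cos(ph_i)
  }
  sm <- seed_map(src, 1, 11, fs)
  v <- sm$map$values
  expect_equal(v[1], 0) # seed excluded
  expect_gt(v[2], 0.9) # coupled target
  expect_lt(v[3], 0.05) # volume-conduction immunity

  # independent target sits at the Monte-Carlo null level for these dynamics
  null_vals <- sm$trial_iplv$iplv[sm$trial_iplv$target == 4]
  expect_lt(abs(v[4] - mean(null_vals)), 3 * sd(null_vals) / sqrt(K) + 1e-9)
  expect_lt(v[4], 0.5)

  expect_error(seed_map(src[, , 1:5], 1, 11, fs), "20 trials")
  expect_error(seed_map(src, 9, 11, fs), "seed")
})

test_that("theta and beta control frequencies show no coupling for mu-locked data", {
  # mu-coupled generator session: voxels 1-3 carry the coupled oscillators,
  # the rest only background activity
  ses <- small_session()
  src <- small_sources()[c(1:3, 10, 20, 30, 40), , ]
  f_mu <- ses$config$f_mu

  mu_v <- seed_map(src, 1, f_mu, 1000)$map$values
  expect_gt(mu_v[2], max(mu_v[4:7]) + 0.1) # coupling visible at mu

  for (f_ctrl in c(5, 21)) {
    v <- seed_map(src, 1, f_ctrl, 1000)$map$values
    null_lvl <- mean(v[4:7])
    null_spread <- diff(range(v[4:7]))
    # coupled voxels indistinguishable from empty ones
    expect_lt(abs(v[2] - null_lvl), null_spread + 0.1)
    expect_lt(abs(v[3] - null_lvl), null_spread + 0.1)
  }
})

test_that("group maps average element-wise and are order-invariant", {
  mk <- function(v) structure(
    list(values = v, seed_index = 1, freq = 11, level = "subject", positions = NULL),
    class = "connectivity_map"
  )
  m1 <- mk(c(0, 0.2, 0.8))
  expect_equal(group_map(list(m1))$values, m1$values)

  m2 <- mk(c(0, 0.6, -0.8 + 2 * 0.5))
  g <- group_map(list(m1, m2))
  expect_equal(g$values[3], 0.5)
  expect_equal(g$level, "group")
  expect_equal(group_map(list(m2, m1))$values, g$values)

  expect_error(group_map(list(m1, mk(c(0, 1)))), "mismatch")
})

test_that("cROI extraction finds coupled patches and respects the exclusion zone", {
  # constructed group map: two high-iPLV patches away from the seed plus a
  # high-value cluster hugging the seed (leakage halo)
  set.seed(15)
  mp <- motor_positions()
  patch <- function(centre, n, r = 8) {
    sweep(matrix(rnorm(3 * n, sd = r / 2), n, 3), 2, centre, `+`)
  }
  pos <- rbind(
    mp$lM1,
    patch(mp$lSMA, 6), patch(mp$rM1, 6),
    patch(mp$lM1 + c(5, 5, 0), 6), # inside the exclusion radius
    default_source_grid(40)[4:40, ] + matrix(rnorm(37 * 3), 37, 3)
  )
  v <- c(0, rep(0.8, 6), rep(0.7, 6), rep(0.9, 6), runif(37, 0, 0.3))
  map <- structure(
    list(values = v, seed_index = 1, freq = 11, level = "group", positions = pos),
    class = "connectivity_map"
  )
  crois <- extract_crois(map, quantile = 0.75, link_mm = 15, min_size = 4)
  expect_equal(nrow(crois), 2)
  cents <- do.call(rbind, crois$centroid)
  d_sma <- min(sqrt(colSums((t(cents) - mp$lSMA)^2)))
  d_rm1 <- min(sqrt(colSums((t(cents) - mp$rM1)^2)))
  expect_lt(d_sma, 10)
  expect_lt(d_rm1, 10)

  # a uniform random map yields no cROI at the default settings
  fails <- vapply(1:20, function(r) {
    m <- map
    m$values <- c(0, runif(length(v) - 1))
    inherits(tryCatch(extract_crois(m), error = function(e) e), "error")
  }, logical(1))
  expect_gte(mean(fails), 0.9)
})

test_that("cROI trial connectivity matches the member-voxel average", {
  src <- small_sources()
  ses <- small_session()
  iplv <- croi_trial_iplv(src, 1, members = 2L, ses$config$f_mu, 1000)
  expect_length(iplv, mnstate:::n_trials(ses$eeg))
  expect_true(all(iplv >= 0 & iplv <= 1))
  # single-member cROI equals the plain per-trial seed-target iPLV
  sm <- seed_map(src[1:3, , ], 1, ses$config$f_mu, 1000)
  expect_equal(iplv, sm$trial_iplv$iplv[sm$trial_iplv$target == 2], tolerance = 1e-10)
})
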