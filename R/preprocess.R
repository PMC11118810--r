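# anti-alias filter + integer decimation, column-wise on a matrix
decimate_matrix <- function(x, q) {
  if (q == 1) return(x)
  bf <- signal::butter(8, 0.8 / q)
  y <- apply(x, 2, function(col) signal::filtfilt(bf, col))
  y[seq(1, nrow(x), by = q), , drop = FALSE]
}

#' Epoch and downsample a continuous recording
#'
#' Anti-alias filters and decimates a continuous multichannel recording to
#' `fs_out`, then cuts stimulus-locked epochs. With the default window
#' `c(-1004, -4)` ms and `fs_out = 1000` each epoch holds exactly 1000
#' pre-pulse samples.
#'
#' @param raw Numeric matrix `channels x samples` (continuous recording).
#' @param fs_raw Acquisition sampling rate (Hz); must be an integer
#'   multiple of `fs_out`.
#' @param pulse_samples Integer sample indices (at `fs_raw`) of the pulses.
#' @param window_ms Epoch window `c(start, end)` in ms relative to each
#'   pulse; samples cover `[start, end)`.
#' @param fs_out Output sampling rate (Hz).
#' @param role Passed to [epoched_recording()].
#'
#' @return An [epoched_recording].
#' @export
epoch_and_downsample <- function(raw, fs_raw, pulse_samples,
                                 window_ms = c(-1004, -4), fs_out = 1000,
                                 role = "eeg") {
  raw <- as.matrix(raw)
  if (fs_raw %% fs_out != 0) stop("fs_raw must be an integer multiple of fs_out")
  q <- fs_raw / fs_out
  dec <- t(decimate_matrix(t(raw), q)) # channels x decimated samples
  n_samp <- round((window_ms[2] - window_ms[1]) * fs_out / 1000)
  n_epoch <- length(pulse_samples)
  out <- array(NA_real_, dim = c(nrow(raw), n_samp, n_epoch))
  for (k in seq_len(n_epoch)) {
    p_dec <- floor((pulse_samples[k] - 1) / q) + 1
    i0 <- p_dec + round(window_ms[1] * fs_out / 1000)
    i1 <- i0 + n_samp - 1
    if (i0 < 1 || i1 > ncol(dec)) {
      stop(sprintf("epoch window for pulse %d extends past the recording", k))
    }
    out[, , k] <- dec[, i0:i1]
  }
  epoched_recording(
    out, fs_out,
    window_ms[1] + (seq_len(n_samp) - 1) * 1000 / fs_out,
    role = role
  )
}

#' Flag bad channels and trials by robust variance z-score
#'
#' A channel (trial) is flagged when the z-score of its variance relative
#' to the median and MAD of all channel (trial) variances exceeds
#' `z_thresh`. The input is never mutated.
#'
#' @param epochs An [epoched_recording] with >= 4 channels and >= 10 trials.
#' @param z_thresh Robust z threshold (default 5).
#' @return List with integer vectors `bad_channels` and `bad_trials`.
#' @export
detect_bad <- function(epochs, z_thresh = 5) {
  d <- dim(epochs$data)
  if (d[1] < 4) stop("need at least 4 channels")
  if (d[3] < 10) stop("need at least 10 trials")
  v_ch <- apply(epochs$data, 1, function(x) var(as.vector(x))) # pooled over time x trials
  v_tr <- apply(epochs$data, 3, function(x) var(as.vector(x)))
  robust_flag <- function(v) {
    m <- median(v)
    s <- mad(v)
    if (s == 0) s <- .Machine$double.eps
    which(abs(v - m) / s > z_thresh)
  }
  bad_channels <- robust_flag(v_ch)
  bad_trials <- robust_flag(v_tr)
  if (length(bad_channels) == d[1]) stop("all channels flagged: data unusable")
  list(bad_channels = bad_channels, bad_trials = bad_trials)
}

#' Independent component analysis in a PCA subspace
#'
#' Symmetric fixed-point ICA (tanh contrast) run on the trial-concatenated
#' epochs inside the subspace of the `n_comp` largest principal vectors.
#' Deterministic for a given `seed`.
#'
#' @param epochs An [epoched_recording].
#' @param n_comp Subspace dimension (default 35, capped at the channel
#'   count).
#' @param seed RNG seed for the orthogonal initialisation.
#' @param max_iter,tol Fixed-point iteration controls.
#' @return List with `timecourses` (`comp x time x trials`),
#'   `topographies` (`channels x comp` mixing columns), `unmixing`,
#'   `center`, `n_comp`, `dims`.
#' @export
run_ica <- function(epochs, n_comp = 35, seed = 1L, max_iter = 200, tol = 1e-6) {
  d <- dim(epochs$data)
  n_comp <- min(n_comp, d[1])
  X <- matrix(epochs$data, d[1], d[2] * d[3]) # channels x (time*trials)
  mu <- rowMeans(X)
  Xc <- X - mu
  sv <- svd(Xc, nu = n_comp, nv = 0)
  keep <- seq_len(n_comp)
  Kw <- t(sv$u[, keep]) / (sv$d[keep] / sqrt(ncol(Xc))) # whitening (comp x ch)
  Z <- Kw %*% Xc
  set.seed(seed)
  W <- qr.Q(qr(matrix(rnorm(n_comp^2), n_comp)))
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors) %*% W
  }
  n <- ncol(Z)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    W1 <- (G %*% t(Z)) / n - diag(rowMeans(1 - G^2)) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  S <- W %*% Z # components x samples
  unmix <- W %*% Kw # comp x channels
  mix <- MASS::ginv(unmix) # channels x comp (topographies)
  list(
    timecourses = array(S, dim = c(n_comp, d[2], d[3])),
    topographies = mix,
    unmixing = unmix,
    center = mu,
    n_comp = n_comp,
    dims = d
  )
}

# Welch PSD with Hann windows; returns freq + power
welch_psd <- function(x, fs, seg_len = NULL) {
  n <- length(x)
  seg_len <- seg_len %||% min(n, fs) # 1-s segments by default
  n_seg <- floor(n / seg_len)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  acc <- 0
  for (s in seq_len(n_seg)) {
    seg <- x[((s - 1) * seg_len + 1):(s * seg_len)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(fft(seg))^2
  }
  nf <- floor(seg_len / 2)
  list(freq = (seq_len(nf) - 1) * fs / seg_len, power = (acc / n_seg)[seq_len(nf)])
}

#' Select mu-rhythm independent components
#'
#' Applies three automatic criteria to each IC: (a) its Welch spectrum has
#' a local maximum in the 9-13 Hz range, (b) the mu-band power (peak +- 2
#' Hz) to beta-band power (15-30 Hz) ratio is at least `ratio_min`, and (c)
#' the source projection of its sensor topography attains its maximum
#' absolute value inside `motor_mask`. The individual mu frequency `f_mu`
#' is the spectral peak of the strongest kept IC.
#'
#' @param ica Result of an ICA decomposition (list with `timecourses`
#'   `comp x time x trials` and `topographies` `channels x comp`).
#' @param filter A [eloreta_filter()] spatial filter for topography
#'   localization.
#' @param motor_mask Integer source indices considered motor cortex.
#' @param fs Sampling rate (Hz).
#' @param mu_range Search range for the mu peak (default `c(9, 13)`).
#' @param beta_band Beta band for the power ratio (default `c(15, 30)`).
#' @param ratio_min Minimum mu/beta power ratio (default 5).
#'
#' @return List with `selection` (tibble, one row per IC: peak frequency,
#'   mu/beta ratio, source argmax, kept flag) and `profile` (list with
#'   `f_mu`, `mu_band`, `beta_band`, `theta_f = 5`, `beta_f = 21`).
#' @export
select_mu_components <- function(ica, filter, motor_mask, fs,
                                 mu_range = c(9, 13), beta_band = c(15, 30),
                                 ratio_min = 5) {
  n_comp <- dim(ica$timecourses)[1]
  rows <- vector("list", n_comp)
  for (i in seq_len(n_comp)) {
    x <- as.vector(ica$timecourses[i, , ])
    psd <- welch_psd(x, fs)
    in_mu <- psd$freq >= mu_range[1] & psd$freq <= mu_range[2]
    p <- psd$power
    # local maximum within the mu range
    is_peak <- c(FALSE, diff(sign(diff(p))) < 0, FALSE)
    peak_idx <- which(is_peak & in_mu)
    has_peak <- length(peak_idx) > 0
    f_peak <- if (has_peak) psd$freq[peak_idx[which.max(p[peak_idx])]] else NA_real_
    mu_power <- if (has_peak) {
      mean(p[psd$freq >= f_peak - 2 & psd$freq <= f_peak + 2])
    } else {
      mean(p[in_mu])
    }
    beta_power <- mean(p[psd$freq >= beta_band[1] & psd$freq <= beta_band[2]])
    ratio <- mu_power / beta_power
    src <- as.vector(filter$weights %*% (ica$topographies[, i]))
    argmax <- which.max(abs(src))
    rows[[i]] <- tibble::tibble(
      ic = i, peak_freq = f_peak, mu_beta_ratio = ratio,
      source_argmax = argmax,
      kept = has_peak && is.finite(ratio) && ratio >= ratio_min &&
        argmax %in% motor_mask,
      mu_power = mu_power
    )
  }
  sel <- dplyr::bind_rows(rows)
  kept <- dplyr::filter(sel, .data$kept)
  if (nrow(kept) == 0) stop("no μ component: subject excluded")
  f_mu <- kept$peak_freq[which.max(kept$mu_power)]
  list(
    selection = sel,
    profile = list(
      f_mu = f_mu, mu_band = c(f_mu - 2, f_mu + 2),
      beta_band = beta_band, theta_f = 5, beta_f = 21
    )
  )
}

#' Reconstruct cleaned channel-level epochs from kept ICs
#'
#' @param ica ICA decomposition as in [select_mu_components()].
#' @param kept Integer indices of the ICs to keep (order-invariant).
#' @param fs Sampling rate (Hz) of the reconstructed recording.
#' @param time_ms Time axis for the output epochs.
#' @return An [epoched_recording] equal to the sum over kept ICs of
#'   topography x timecourse.
#' @export
reconstruct_clean <- function(ica, kept, fs, time_ms) {
  if (length(kept) == 0) stop("kept IC set is empty")
  kept <- sort(unique(kept))
  d <- ica$dims
  S <- matrix(ica$timecourses[kept, , , drop = FALSE], length(kept), d[2] * d[3])
  X <- ica$topographies[, kept, drop = FALSE] %*% S
  epoched_recording(array(X, dim = d), fs, time_ms, role = "eeg")
}
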