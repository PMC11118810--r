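#' Select a voxel patch around a centre position
#'
#' @param positions `n x 3` MNI positions (mm).
#' @param centre Length-3 centre position (mm).
#' @param radius_mm Patch radius (default 4).
#' @return List of class `voxel_patch`: `members`, `centre`, `radius_mm`.
#' @export
select_voxel_patch <- function(positions, centre, radius_mm = 4) {
  positions <- as.matrix(positions)
  if (nrow(positions) == 0) stop("positions must be non-empty")
  d <- sqrt(colSums((t(positions) - centre)^2))
  members <- which(d <= radius_mm)
  if (length(members) == 0) {
    stop(sprintf(
      "no voxel within %g mm of the centre (nearest at %.1f mm); increase the radius",
      radius_mm, min(d)
    ))
  }
  structure(
    list(members = members, centre = centre, radius_mm = radius_mm),
    class = "voxel_patch"
  )
}

#' Segment-wise cross-spectra of two multivariate time series
#'
#' Splits the concatenated series into non-overlapping segments of
#' `seg_len` samples, applies a Hann window, and computes the discrete
#' Fourier coefficients at the requested analysis frequencies; the
#' cross-spectral matrix `S(f)` is the across-segment mean of the outer
#' products `a(f) a(f)^H` of the stacked `[X; Y]` coefficient vectors
#' (per-segment matrices retained for the jackknife).
#'
#' @param X,Y Numeric matrices `n x time` and `m x time` (equal time
#'   length), e.g. concatenated 1-s pre-stimulus epochs.
#' @param freqs Analysis frequencies (Hz); must be multiples of the
#'   segment frequency resolution `fs / seg_len`.
#' @param fs Sampling rate (Hz).
#' @param seg_len Segment length in samples (default `fs`, i.e. 1 s and a
#'   1 Hz resolution).
#'
#' @return Object of class `cross_spectra`: `per_segment` (complex array
#'   `(n+m) x (n+m) x nfreq x nseg`), `mean` (across-segment mean),
#'   `freqs`, `n`, `m`, `n_segments`.
#' @export
cross_spectra <- function(X, Y, freqs, fs, seg_len = fs) {
  X <- rbind(X)
  Y <- rbind(Y)
  stopifnot(ncol(X) == ncol(Y))
  n <- nrow(X)
  m <- nrow(Y)
  n_seg <- floor(ncol(X) / seg_len)
  if (n_seg < 8) stop("fewer than 8 segments: jackknife unstable")
  df <- fs / seg_len
  bins <- freqs / df
  if (any(abs(bins - round(bins)) > 1e-8)) {
    stop("freqs must be multiples of the frequency resolution fs/seg_len")
  }
  bins <- round(bins) + 1L # DFT bin index (1-based, bin 1 = DC)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  p <- n + m
  per_seg <- array(complex(real = 0), dim = c(p, p, length(freqs), n_seg))
  for (s in seq_len(n_seg)) {
    idx <- ((s - 1) * seg_len + 1):(s * seg_len)
    seg <- rbind(X[, idx, drop = FALSE], Y[, idx, drop = FALSE])
    seg <- seg - rowMeans(seg)
    A <- t(mvfft(t(seg * rep(w, each = p)))) # p x seg_len spectra
    for (fi in seq_along(bins)) {
      a <- A[, bins[fi]]
      per_seg[, , fi, s] <- a %*% Conj(t(a))
    }
  }
  structure(
    list(
      per_segment = per_seg,
      mean = apply(per_seg, c(1, 2, 3), mean),
      freqs = freqs, n = n, m = m, n_segments = n_seg, seg_len = seg_len
    ),
    class = "cross_spectra"
  )
}

# Hermitian inverse square root with trace regularization
inv_sqrt_h <- function(S, reg = 1e-8) {
  k <- nrow(S)
  S <- (S + Conj(t(S))) / 2 + diag(reg * Re(sum(diag(S))) / k, k)
  e <- eigen(S, symmetric = TRUE)
  if (any(e$values <= 0)) stop("cross-spectral block singular beyond regularization")
  e$vectors %*% (t(Conj(e$vectors)) / sqrt(e$values))
}

# MPSI from a stack of cross-spectral matrices S[p, p, nfreq]
mpsi_from_S <- function(S, n, m, band_idx, reg = 1e-8) {
  ix <- seq_len(n)
  iy <- n + seq_len(m)
  Cs <- lapply(band_idx, function(fi) {
    Sf <- S[, , fi]
    inv_sqrt_h(Sf[ix, ix, drop = FALSE], reg) %*%
      Sf[ix, iy, drop = FALSE] %*%
      inv_sqrt_h(Sf[iy, iy, drop = FALSE], reg)
  })
  psi <- 0
  for (i in seq_len(length(Cs) - 1)) {
    psi <- psi + Im(sum(diag(Conj(t(Cs[[i]])) %*% Cs[[i + 1]])))
  }
  psi
}

#' Multivariate phase slope index
#'
#' With the whitened cross-spectral matrix
#' `C(f) = S_XX(f)^(-1/2) S_XY(f) S_YY(f)^(-1/2)` (regularized inverse
#' square roots), `psi = sum_f Im tr( C(f)^H C(f + df) )` over adjacent
#' analysis frequencies in the band. Positive `psi` means X temporally
#' leads Y; swapping the arguments flips the sign exactly.
#'
#' @param cs A [cross_spectra()] object.
#' @param band Frequency band `c(lo, hi)` (Hz); default spans all analysis
#'   frequencies. Must cover at least 2 adjacent frequencies.
#' @param reg Relative diagonal regularization for the whitening
#'   (default 1e-8).
#' @return The scalar MPSI value.
#' @export
mpsi <- function(cs, band = NULL, reg = 1e-8) {
  stopifnot(inherits(cs, "cross_spectra"))
  band <- band %||% range(cs$freqs)
  idx <- which(cs$freqs >= band[1] & cs$freqs <= band[2])
  if (length(idx) < 2) stop("band must cover at least 2 analysis frequencies")
  mpsi_from_S(cs$mean, cs$n, cs$m, idx, reg)
}

#' Jackknife pseudo-Z for the MPSI
#'
#' Computes leave-one-segment-out MPSI estimates, the jackknife standard
#' deviation `sqrt((N-1)/N * sum (psi_i - mean)^2)`, and the pseudo-Z
#' `psi / SD` (flagged, not divided, when SD = 0).
#'
#' @inheritParams mpsi
#' @param pair Optional character pair of names for bookkeeping.
#' @return Object of class `directionality_result`: `psi`, `jackknife_sd`,
#'   `pseudo_z`, `flagged`, `n_segments`, `band`, `pair`. Sign convention:
#'   positive means the first series leads.
#' @export
jackknife_pseudo_z <- function(cs, band = NULL, reg = 1e-8, pair = c("X", "Y")) {
  stopifnot(inherits(cs, "cross_spectra"))
  band <- band %||% range(cs$freqs)
  idx <- which(cs$freqs >= band[1] & cs$freqs <= band[2])
  if (length(idx) < 2) stop("band must cover at least 2 analysis frequencies")
  N <- cs$n_segments
  if (N < 8) stop("need at least 8 segments")
  tot <- cs$mean * N
  psi_full <- mpsi_from_S(cs$mean, cs$n, cs$m, idx, reg)
  psi_loo <- vapply(seq_len(N), function(i) {
    mpsi_from_S((tot - cs$per_segment[, , , i]) / (N - 1), cs$n, cs$m, idx, reg)
  }, numeric(1))
  jsd <- sqrt((N - 1) / N * sum((psi_loo - mean(psi_loo))^2))
  flagged <- jsd == 0
  structure(
    list(
      psi = psi_full, jackknife_sd = jsd,
      pseudo_z = if (flagged) NA_real_ else psi_full / jsd,
      flagged = flagged, n_segments = N,
      band = band, pair = pair
    ),
    class = "directionality_result"
  )
}

#' @export
print.directionality_result <- function(x, ...) {
  cat(sprintf(
    "<directionality_result> %s -> %s: psi = %.4g, jackknife SD = %.4g, pseudo-Z = %.2f%s\n",
    x$pair[1], x$pair[2], x$psi, x$jackknife_sd,
    if (is.na(x$pseudo_z)) NA else x$pseudo_z,
    if (x$flagged) " [flagged: SD = 0]" else ""
  ))
  invisible(x)
}

#' Group-level Z from per-subject pseudo-Z scores
#'
#' `Z = sqrt(N) * mean(pseudo_z)`, interpreted against the standard
#' normal; two-sided p-value.
#'
#' @param pseudo_zs Numeric vector of per-subject pseudo-Z scores.
#' @return List with `z` and `p` (two-sided).
#' @export
group_z <- function(pseudo_zs) {
  stopifnot(length(pseudo_zs) >= 1)
  z <- sqrt(length(pseudo_zs)) * mean(pseudo_zs)
  list(z = z, p = 2 * pnorm(-abs(z)))
}
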