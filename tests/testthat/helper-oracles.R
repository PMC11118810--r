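# independent bivariate phase-slope-index oracle: plain Welch coherency and
# a direct sum over neighbouring frequencies, written without the package's
# whitening machinery
oracle_psi <- function(x, y, freqs, fs, seg_len = fs) {
  n_seg <- floor(length(x) / seg_len)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  bins <- round(freqs / (fs / seg_len)) + 1
  sxx <- syy <- numeric(length(freqs))
  sxy <- complex(length(freqs))
  for (s in seq_len(n_seg)) {
    idx <- ((s - 1) * seg_len + 1):(s * seg_len)
    a <- fft((x[idx] - mean(x[idx])) * w)[bins]
    b <- fft((y[idx] - mean(y[idx])) * w)[bins]
    sxx <- sxx + Mod(a)^2
    syy <- syy + Mod(b)^2
    sxy <- sxy + a * Conj(b)
  }
  coh <- (sxy / n_seg) / sqrt(sxx / n_seg * syy / n_seg)
  sum(Im(Conj(coh[-length(coh)]) * coh[-1]))
}

# unit-variance 1/f noise, independent implementation
oracle_pink <- function(n) {
  W <- fft(rnorm(n))
  f <- pmin(c(1, 1:(n - 1)), n - c(1, 1:(n - 1)) + 1)
  x <- Re(fft(W / sqrt(f), inverse = TRUE)) / n
  x / sd(x)
}
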