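#' Extract per-trial MEP amplitudes from epoched EMG
#'
#' Per trial and muscle: removes a linear pre-pulse trend, removes 50 Hz
#' line noise (and its first harmonic) by sinusoidal regression -- which,
#' unlike an IIR notch, does not ring off the large stimulus-artifact
#' transient -- fits `A * exp(-t / tau) + B` to the stimulus-artifact
#' window and subtracts its extrapolation over the post-pulse samples, then
#' measures the peak-to-peak amplitude inside the MEP window. Trials whose
#' pre-pulse RMS exceeds `pre_emg_thresh` (muscle tonus) are rejected.
#'
#' @param emg An [epoched_recording] with `role = "emg"` (mV), 2 channels
#'   (FDI, APB).
#' @param mep_window MEP search window, ms post-pulse (default `c(20, 45)`);
#'   must not overlap `artifact_window`.
#' @param artifact_window Window for the exponential artifact fit
#'   (default `c(2, 15)` ms).
#' @param pre_emg_thresh Pre-pulse RMS rejection threshold in microvolts
#'   (default 50).
#' @param notch_50 Remove 50/100 Hz line components (default TRUE).
#'
#' @return A tibble (class `mep_table`) with one row per trial: `p2p_fdi`,
#'   `p2p_apb` (mV), `log_fdi`, `log_apb`, `linear_amp` (geometric mean,
#'   mV), `pc1_score`, `rejected`, `reason`, `artifact_fit_failed`; the
#'   attribute `pc1_variance_explained` holds the PC1 variance fraction.
#' @export
extract_mep <- function(emg, mep_window = c(20, 45), artifact_window = c(2, 15),
                        pre_emg_thresh = 50, notch_50 = TRUE) {
  stopifnot(inherits(emg, "epoched_recording"))
  if (mep_window[1] <= artifact_window[2]) {
    stop("mep_window must start after artifact_window ends")
  }
  t_ms <- emg$time_ms
  fs <- emg$fs
  d <- dim(emg$data)
  K <- d[3]
  pre <- t_ms < -10
  art_idx <- which(t_ms >= artifact_window[1] & t_ms <= artifact_window[2])
  mep_idx <- which(t_ms >= mep_window[1] & t_ms <= mep_window[2])
  post_idx <- which(t_ms >= artifact_window[1])
  line_basis <- if (notch_50) {
    tt <- t_ms / 1000
    cbind(sin(2 * pi * 50 * tt), cos(2 * pi * 50 * tt),
          sin(2 * pi * 100 * tt), cos(2 * pi * 100 * tt))
  } else {
    NULL
  }

  p2p <- matrix(NA_real_, K, 2)
  fit_failed <- matrix(FALSE, K, 2)
  pre_rms <- matrix(NA_real_, K, 2)
  for (m in 1:2) {
    for (k in seq_len(K)) {
      x <- emg$data[m, , k]
      # linear detrend on the pre-pulse segment
      cf <- coef(lm.fit(cbind(1, t_ms[pre]), x[pre]))
      x <- x - (cf[1] + cf[2] * t_ms)
      if (!is.null(line_basis)) {
        lc <- coef(lm.fit(line_basis[pre, , drop = FALSE], x[pre]))
        x <- x - as.vector(line_basis %*% lc)
      }
      pre_rms[k, m] <- sqrt(mean(x[pre]^2))
      xf <- fit_subtract_artifact(x, t_ms, art_idx, post_idx)
      fit_failed[k, m] <- attr(xf, "failed")
      p2p[k, m] <- max(xf[mep_idx]) - min(xf[mep_idx])
    }
  }
  tonic <- pmax(pre_rms[, 1], pre_rms[, 2]) * 1000 > pre_emg_thresh # mV -> uV
  out <- tibble::tibble(
    trial = seq_len(K),
    p2p_fdi = p2p[, 1], p2p_apb = p2p[, 2],
    log_fdi = log(p2p[, 1]), log_apb = log(p2p[, 2]),
    linear_amp = exp((log(p2p[, 1]) + log(p2p[, 2])) / 2),
    rejected = tonic,
    reason = ifelse(tonic, "pre-stimulus activity", NA_character_),
    artifact_fit_failed = fit_failed[, 1] | fit_failed[, 2]
  )
  valid <- !out$rejected
  out$pc1_score <- NA_real_
  ve <- NA_real_
  if (sum(valid) >= 10) {
    pc <- mep_pc1(out$log_fdi[valid], out$log_apb[valid])
    out$pc1_score[valid] <- pc$score
    ve <- pc$variance_explained
  }
  attr(out, "pc1_variance_explained") <- ve
  class(out) <- c("mep_table", class(out))
  out
}

# exponential artifact fit and subtraction; returns trace with attr "failed"
fit_subtract_artifact <- function(x, t_ms, art_idx, post_idx) {
  ta <- t_ms[art_idx]
  ya <- x[art_idx]
  fit <- tryCatch(
    nls(y ~ A * exp(-t / tau) + B,
      data = list(y = ya, t = ta),
      start = list(A = ya[1] * exp(ta[1] / 5), tau = 5, B = mean(tail(ya, 5))),
      control = list(maxiter = 100, warnOnly = FALSE)
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || coef(fit)[["tau"]] <= 0) {
    attr(x, "failed") <- TRUE
    return(x)
  }
  cf <- coef(fit)
  x[post_idx] <- x[post_idx] - (cf[["A"]] * exp(-t_ms[post_idx] / cf[["tau"]]) + cf[["B"]])
  attr(x, "failed") <- FALSE
  x
}

#' First principal component of the two-muscle log-MEP table
#'
#' Centred PCA of the `(log FDI, log APB)` trial table; the PC1 score sign
#' is fixed so that it correlates positively with the mean log amplitude.
#'
#' @param log_fdi,log_apb Per-trial log amplitudes (>= 10 trials).
#' @return List with `score` (per-trial PC1), `variance_explained`
#'   (fraction in `[0, 1]`) and `loadings`.
#' @export
mep_pc1 <- function(log_fdi, log_apb) {
  stopifnot(length(log_fdi) == length(log_apb))
  if (length(log_fdi) < 10) stop("need at least 10 valid trials")
  M <- cbind(log_fdi, log_apb)
  if (all(apply(M, 2, sd) == 0)) stop("zero variance in both muscles")
  pc <- prcomp(M, center = TRUE, scale. = FALSE)
  score <- pc$x[, 1]
  mean_log <- rowMeans(M)
  if (sd(score) > 0 && stats::cor(score, mean_log) < 0) {
    score <- -score
    pc$rotation[, 1] <- -pc$rotation[, 1]
  }
  list(
    score = as.vector(score),
    variance_explained = pc$sdev[1]^2 / sum(pc$sdev^2),
    loadings = pc$rotation[, 1]
  )
}
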