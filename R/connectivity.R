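#' Narrowband analytic signal with AR edge padding
#'
#' Band-passes an epoch around a centre frequency (two-pass fourth-order
#' Butterworth, i.e. zero phase), pads both ends by `pad_ms` using a
#' Yule-Walker autoregressive model fitted on the filtered epoch (which
#' suppresses Hilbert edge effects better than zero padding), applies the
#' Hilbert transform, and trims the padding.
#'
#' @param x Numeric vector (one epoch) or `time x trials` matrix.
#' @param f_c Centre frequency (Hz); `f_c - bw/2` must be positive.
#' @param fs Sampling rate (Hz).
#' @param bw Bandwidth (Hz, default 2).
#' @param pad_ms Padding duration per end (ms, default 64).
#' @param ar_order AR model order (default 30); epochs must hold at least
#'   `4 * ar_order` samples.
#' @param pad `"ar"` (default) or `"reflect"`; AR fitting falls back to
#'   reflection on constant signals (flagged).
#'
#' @return List of class `analytic_epoch`: `analytic` (complex, same shape
#'   as `x`), `phase`, `envelope`, `f_c`, `bw`, `flagged` (per column).
#' @export
narrowband_analytic <- function(x, f_c, fs, bw = 2, pad_ms = 64,
                                ar_order = 30, pad = c("ar", "reflect")) {
  pad <- match.arg(pad)
  xm <- as.matrix(x)
  nt <- nrow(xm)
  if (nt < 4 * ar_order) stop("epoch too short for the AR padding order")
  if (f_c - bw / 2 <= 0) stop("f_c - bw/2 must be positive")
  bf <- signal::butter(4, c(f_c - bw / 2, f_c + bw / 2) / (fs / 2), type = "pass")
  n_pad <- round(pad_ms * fs / 1000)
  out <- matrix(complex(real = NA), nt, ncol(xm))
  flagged <- logical(ncol(xm))
  for (j in seq_len(ncol(xm))) {
    xf <- zero_phase_bandpass(bf, xm[, j], fs)
    padded <- tryCatch(
      {
        if (pad == "reflect") stop("reflect requested")
        fit <- ar.yw(xf, aic = FALSE, order.max = ar_order, demean = TRUE)
        if (any(!is.finite(fit$ar))) stop("AR fit failed")
        fwd <- ar_extrapolate(xf, fit$ar, n_pad, mean_x = fit$x.mean)
        bwd <- rev(ar_extrapolate(rev(xf), fit$ar, n_pad, mean_x = fit$x.mean))
        c(bwd, xf, fwd)
      },
      error = function(e) {
        flagged[j] <<- TRUE
        c(rev(xf[seq_len(n_pad) + 1]), xf, rev(xf[nt - seq_len(n_pad)]))
      }
    )
    a <- analytic_signal(padded)
    out[, j] <- a[n_pad + seq_len(nt)]
  }
  if (is.null(dim(x))) {
    out <- out[, 1]
  }
  structure(
    list(
      analytic = out, phase = Arg(out), envelope = Mod(out),
      f_c = f_c, bw = bw, flagged = flagged
    ),
    class = "analytic_epoch"
  )
}

#' Per-trial imaginary phase-locking value
#'
#' `iPLV = | Im( mean_t exp(i (phi_S(t) - phi_T(t))) ) |`. Insensitive to
#' zero-lag (volume-conduction) coupling: identical or zero-lag-mixed
#' signals give exactly 0.
#'
#' @param phase_seed,phase_target Phase series (rad), equal length >= 2.
#' @return iPLV in `[0, 1]`.
#' @export
iplv_trial <- function(phase_seed, phase_target) {
  if (length(phase_seed) != length(phase_target) || length(phase_seed) < 2) {
    stop("phase series must have equal length >= 2")
  }
  if (anyNA(phase_seed) || anyNA(phase_target)) stop("NaN phases")
  abs(Im(mean(exp(1i * (phase_seed - phase_target)))))
}

#' Seed-based iPLV connectivity map
#'
#' Band-passes every source time-course at the individual mu frequency,
#' computes the per-trial iPLV between the seed and each target over the
#' pre-pulse window, and averages across trials to form the subject map
#' (the seed's own map value is defined as 0).
#'
#' @param sources `sources x time x trials` array (from
#'   [project_sources()]).
#' @param seed_index Seed source index.
#' @param f_mu Analysis frequency (Hz).
#' @param fs Sampling rate (Hz).
#' @param bw Bandwidth (Hz, default 2).
#' @param positions Optional `n x 3` MNI positions carried into the map.
#' @param average `"trials"` (default; per-trial iPLV averaged across
#'   trials) or `"coherent"` (single iPLV over all pooled time-trial
#'   samples).
#' @param ... Passed to [narrowband_analytic()].
#'
#' @return List with `map` (class `connectivity_map`) and `trial_iplv`
#'   (tibble: trial, target, iplv).
#' @export
seed_map <- function(sources, seed_index, f_mu, fs, bw = 2, positions = NULL,
                     average = c("trials", "coherent"), ...) {
  average <- match.arg(average)
  d <- dim(sources)
  if (seed_index < 1 || seed_index > d[1]) stop("invalid seed index")
  if (d[3] < 20) stop("need at least 20 trials for a stable map")
  ph <- array(NA_real_, dim = d)
  for (j in seq_len(d[1])) {
    ph[j, , ] <- narrowband_analytic(
      matrix(sources[j, , ], d[2], d[3]), f_mu, fs, bw = bw, ...
    )$phase
  }
  targets <- setdiff(seq_len(d[1]), seed_index)
  tri <- matrix(0, d[3], d[1])
  vals <- numeric(d[1])
  for (j in targets) {
    dphi <- ph[seed_index, , ] - ph[j, , ]
    z <- exp(1i * dphi)
    tri[, j] <- abs(Im(colMeans(z)))
    vals[j] <- if (average == "trials") mean(tri[, j]) else abs(Im(mean(z)))
  }
  map <- structure(
    list(
      values = vals, seed_index = seed_index, freq = f_mu,
      level = "subject", positions = positions
    ),
    class = "connectivity_map"
  )
  trial_iplv <- tibble::tibble(
    trial = rep(seq_len(d[3]), length(targets)),
    target = rep(targets, each = d[3]),
    iplv = as.vector(tri[, targets])
  )
  list(map = map, trial_iplv = trial_iplv)
}

#' Group-average connectivity map
#'
#' @param maps List of subject `connectivity_map`s on identical grids.
#' @return A `connectivity_map` with `level = "group"`.
#' @export
group_map <- function(maps) {
  stopifnot(length(maps) >= 1)
  n <- length(maps[[1]]$values)
  for (m in maps) {
    if (length(m$values) != n || m$seed_index != maps[[1]]$seed_index) {
      stop("grid mismatch between subject maps")
    }
  }
  out <- maps[[1]]
  out$values <- Reduce(`+`, lapply(maps, `[[`, "values")) / length(maps)
  out$freq <- mean(vapply(maps, `[[`, numeric(1), "freq"))
  out$level <- "group"
  out
}

#' Extract connectivity regions of interest (cROIs) from a group map
#'
#' Thresholds the map at a quantile of its values, excludes sources within
#' `seed_exclusion_mm` of the seed (leakage halo), single-linkage clusters
#' the survivors with linkage distance `link_mm`, keeps clusters of at
#' least `min_size` sources, and returns them sorted by mean iPLV
#' (descending) with iPLV-weighted centroids.
#'
#' @param map A group `connectivity_map` with `positions`.
#' @param quantile Threshold quantile (default 0.95).
#' @param link_mm Single-linkage distance (default 15).
#' @param seed_exclusion_mm Seed exclusion radius (default 20).
#' @param min_size Minimum cluster size (default 5).
#'
#' @return Tibble (class `croi_set`): `name`, `members` (list column),
#'   `centroid` (list column, MNI mm), `mean_iplv`, `size`.
#' @export
extract_crois <- function(map, quantile = 0.95, link_mm = 15,
                          seed_exclusion_mm = 20, min_size = 5) {
  stopifnot(inherits(map, "connectivity_map"))
  if (is.null(map$positions)) stop("map carries no source positions")
  v <- map$values
  if (!all(is.finite(v))) stop("map values must be finite")
  pos <- as.matrix(map$positions)
  thr <- stats::quantile(v[-map$seed_index], quantile)
  seed_pos <- pos[map$seed_index, ]
  d_seed <- sqrt(colSums((t(pos) - seed_pos)^2))
  cand <- which(v >= thr & d_seed > seed_exclusion_mm)
  cand <- setdiff(cand, map$seed_index)
  if (length(cand) == 0) stop("no cROI: no sources survive thresholding")
  if (length(cand) == 1) {
    cl <- 1L
  } else {
    hc <- hclust(dist(pos[cand, , drop = FALSE]), method = "single")
    cl <- cutree(hc, h = link_mm)
  }
  rois <- list()
  for (g in unique(cl)) {
    idx <- cand[cl == g]
    if (length(idx) < min_size) next
    w <- v[idx]
    rois[[length(rois) + 1]] <- tibble::tibble(
      members = list(idx),
      centroid = list(colSums(pos[idx, , drop = FALSE] * w) / sum(w)),
      mean_iplv = mean(w),
      size = length(idx)
    )
  }
  if (length(rois) == 0) stop("no cROI: no cluster reaches min_size")
  out <- dplyr::arrange(dplyr::bind_rows(rois), dplyr::desc(.data$mean_iplv))
  out$name <- paste0("cROI", seq_len(nrow(out)))
  out <- out[, c("name", "members", "centroid", "mean_iplv", "size")]
  class(out) <- c("croi_set", class(out))
  out
}

#' Per-trial iPLV between the seed and a cROI
#'
#' The cROI time-course is the average of its member-voxel time-courses,
#' sign-aligned by correlation with the first member before averaging;
#' per-trial iPLV to the seed is then computed at `f_mu` as in
#' [seed_map()].
#'
#' @param sources `sources x time x trials` array.
#' @param seed_index Seed source index.
#' @param members Integer indices of the cROI member voxels.
#' @param f_mu,fs,bw As in [seed_map()].
#' @return Numeric vector of per-trial iPLV values.
#' @export
croi_trial_iplv <- function(sources, seed_index, members, f_mu, fs, bw = 2) {
  d <- dim(sources)
  ref <- as.vector(sources[members[1], , ])
  acc <- matrix(0, d[2], d[3])
  for (j in members) {
    x <- matrix(sources[j, , ], d[2], d[3])
    s <- sign(stats::cor(as.vector(x), ref))
    if (is.na(s) || s == 0) s <- 1
    acc <- acc + s * x
  }
  acc <- acc / length(members)
  ph_roi <- narrowband_analytic(acc, f_mu, fs, bw = bw)$phase
  ph_seed <- narrowband_analytic(
    matrix(sources[seed_index, , ], d[2], d[3]), f_mu, fs, bw = bw
  )$phase
  abs(Im(colMeans(exp(1i * (ph_seed - ph_roi)))))
}


# two-pass (zero-phase) filtering with the narrowband transient
# (~1/bandwidth, i.e. hundreds of ms at 2 Hz) kept inside end padding;
# the epoch is extended by an AR model of the raw signal (phase-true for
# oscillatory content), falling back to odd reflection
zero_phase_bandpass <- function(bf, x, fs) {
  n <- length(x)
  # pole decay of the 2-Hz-wide filter is ~0.4 s per pass; 2.5 s of
  # padding leaves < 0.2% residual transient inside the epoch
  np <- round(2.5 * fs)
  ext <- tryCatch(
    {
      fit <- stats::ar.burg(x, aic = FALSE, order.max = min(30, n %/% 4))
      if (any(!is.finite(fit$ar))) stop("AR fit failed")
      fwd <- ar_extrapolate(x, fit$ar, np, mean_x = fit$x.mean)
      bwd <- rev(ar_extrapolate(rev(x), fit$ar, np, mean_x = fit$x.mean))
      ok <- max(abs(c(fwd, bwd))) < 20 * max(abs(x - mean(x)) + 1e-300)
      if (!ok) stop("explosive extrapolation")
      c(bwd, x, fwd)
    },
    error = function(e) {
      npr <- min(n - 1, np)
      refl <- c(2 * x[1] - x[(npr + 1):2], x, 2 * x[n] - x[(n - 1):(n - npr)])
      pad0 <- np - npr
      c(numeric(pad0), refl, numeric(pad0))
    }
  )
  y <- signal::filtfilt(bf, ext)
  y[np + seq_len(n)]
}
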