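#' Epoched multichannel recording
#'
#' Container for stimulus-locked epochs of EEG or EMG data, stored as a
#' `channels x time x trials` array with its sampling rate and a time axis
#' in milliseconds relative to the TMS pulse.
#'
#' @param data Numeric array `channels x time x trials`. EEG data are in
#'   microvolts, EMG data in millivolts.
#' @param fs Sampling rate in Hz.
#' @param time_ms Numeric vector of sample times (ms relative to the pulse),
#'   strictly increasing, length `dim(data)[2]`.
#' @param labels Channel names (defaults to `ch1 ...`).
#' @param role `"eeg"` or `"emg"`.
#'
#' @return An object of class `epoched_recording`.
#' @export
epoched_recording <- function(data, fs, time_ms, labels = NULL, role = c("eeg", "emg")) {
  role <- match.arg(role)
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (length(time_ms) != dim(data)[2]) {
    stop("time_ms length must match the time dimension of `data`")
  }
  if (any(diff(time_ms) <= 0)) stop("time_ms must be strictly increasing")
  labels <- labels %||% paste0("ch", seq_len(dim(data)[1]))
  structure(
    list(data = data, fs = fs, time_ms = time_ms, labels = labels, role = role),
    class = "epoched_recording"
  )
}

#' @export
print.epoched_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoched_recording [%s]> %d channels x %d samples x %d trials @ %g Hz, t = %g..%g ms\n",
    x$role, d[1], d[2], d[3], x$fs, min(x$time_ms), max(x$time_ms)
  ))
  invisible(x)
}

#' @export
dim.epoched_recording <- function(x) dim(x$data)

n_trials <- function(x) dim(x$data)[3]

#' Lead field (forward model)
#'
#' Sensor-to-source gain matrix with source positions in MNI millimetres.
#' Before orientation reduction the gain is `sensors x (3 * n_sources)`
#' (free dipole orientations, xyz blocks per source); after reduction it is
#' `sensors x n_sources` and each source carries a unit orientation vector.
#'
#' @param gain Numeric gain matrix.
#' @param positions `n_sources x 3` matrix of MNI positions (mm).
#' @param orientations Optional `n_sources x 3` matrix of unit orientation
#'   vectors (present after [reduce_orientation()]).
#'
#' @return An object of class `lead_field`.
#' @export
lead_field <- function(gain, positions, orientations = NULL) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3)
  if (!all(is.finite(gain))) stop("lead field gain must be finite")
  if (!all(is.finite(positions))) stop("source positions must be finite")
  ns <- nrow(positions)
  if (!(ncol(gain) %in% c(ns, 3L * ns))) {
    stop("gain must have n_sources or 3*n_sources columns")
  }
  structure(
    list(
      gain = gain, positions = positions, orientations = orientations,
      reduced = ncol(gain) == ns
    ),
    class = "lead_field"
  )
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf(
    "<lead_field> %d sensors, %d sources (%s orientation)\n",
    nrow(x$gain), nrow(x$positions), if (x$reduced) "reduced" else "free"
  ))
  invisible(x)
}

n_sources <- function(lf) nrow(lf$positions)

#' @export
print.spatial_filter <- function(x, ...) {
  cat(sprintf(
    "<spatial_filter [eLORETA]> %d sources x %d sensors, alpha = %.3g, %d iterations (%s)\n",
    nrow(x$weights), ncol(x$weights), x$alpha, x$iterations_used,
    if (x$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}

#' @export
print.connectivity_map <- function(x, ...) {
  cat(sprintf(
    "<connectivity_map [%s]> %d sources, seed #%d, %g Hz; iPLV range %.3f..%.3f\n",
    x$level, length(x$values), x$seed_index, x$freq,
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> (robust IRLS fits, AIC ranking)\n")
  print(x$table[, c("model", "k", "aic", "delta_aic", "class")])
  invisible(x)
}
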