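#' Generate a synthetic lead field
#'
#' Builds a smooth, physically plausible forward model: sensors are placed
#' on the upper part of a sphere of radius 95 mm (slightly jittered by the
#' seed) and each source contributes the quasi-static potential of a current
#' dipole in an unbounded homogeneous conductor,
#' `V = (q . d) / (4 pi sigma |d|^3)` with `d` the sensor-source vector.
#' The gain is linear in the dipole moment, decays with distance and has
#' full column rank for well-separated sources. This synthetic forward map
#' stands in for a boundary-element solution, which is out of scope here.
#'
#' @param n_sensors Number of sensors (>= 8).
#' @param source_positions `n x 3` matrix of MNI positions (mm), `n >= 2`,
#'   all distinct.
#' @param seed Integer seed controlling the small sensor-position jitter.
#'
#' @return A [lead_field] with free orientations
#'   (`n_sensors x (3 * n_sources)`; per-source xyz column blocks).
#' @export
make_lead_field <- function(n_sensors, source_positions, seed = 1L) {
  if (n_sensors < 8) stop("n_sensors must be >= 8")
  pos <- as.matrix(source_positions)
  if (nrow(pos) < 2) stop("need at least 2 source positions")
  if (anyDuplicated(round(pos, 6)) > 0) stop("duplicate source positions")
  if (!all(is.finite(pos))) stop("source positions must be finite")

  set.seed(seed)
  sens <- fibonacci_cap(n_sensors, radius = 95, centre = c(0, -18, 20))
  sens <- sens + matrix(rnorm(3 * n_sensors, sd = 1), n_sensors, 3)

  ns <- nrow(pos)
  gain <- matrix(0, n_sensors, 3L * ns)
  sigma_c <- 0.33 # S/m
  for (j in seq_len(ns)) {
    d <- sweep(sens, 2, pos[j, ]) # sensors x 3
    r3 <- rowSums(d^2)^1.5
    blk <- d / (4 * pi * sigma_c * r3) # potential per unit moment component
    gain[, (3 * j - 2):(3 * j)] <- blk
  }
  # scale so a unit-amplitude source produces on the order of microvolts
  gain <- gain / max(abs(gain)) * 5
  lead_field(gain, pos)
}

# n points on the upper cap of a sphere (Fibonacci spiral)
fibonacci_cap <- function(n, radius, centre) {
  i <- seq_len(n) - 0.5
  # z from 0.15 to 1 -> upper cap only
  z <- 0.15 + (1 - 0.15) * i / n
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  xyz <- cbind(r * cos(phi), r * sin(phi), z) * radius
  sweep(xyz, 2, centre, `+`)
}

# gain block (sensors x 3) of one source from a free-orientation lead field
gain_block <- function(lf, j) {
  lf$gain[, (3 * j - 2):(3 * j), drop = FALSE]
}
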