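#' Write a session to a plain-text directory layout
#'
#' Stores a session as a directory of CSV and JSON files mirroring the
#' logical layout `eeg/ emg/ leadfield/ truth`: per-trial sample matrices
#' are flattened to `channel, time_ms, trial, value` long CSVs would be
#' enormous, so the arrays are stored as one wide CSV per channel block
#' with a JSON sidecar holding dimensions, sampling rates and labels.
#'
#' @param session A `synthetic_session`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr_rec <- function(rec, name) {
    d <- dim(rec$data)
    write.csv(matrix(rec$data, d[1] * d[2], d[3]),
      file.path(dir, paste0(name, "_data.csv")),
      row.names = FALSE
    )
    jsonlite::write_json(
      list(dim = d, fs = rec$fs, time_ms = rec$time_ms, labels = rec$labels,
           role = rec$role),
      file.path(dir, paste0(name, "_meta.json")),
      auto_unbox = TRUE, digits = NA
    )
  }
  wr_rec(session$eeg, "eeg")
  wr_rec(session$emg, "emg")
  write.csv(session$leadfield$gain, file.path(dir, "leadfield_gain.csv"),
    row.names = FALSE
  )
  write.csv(session$leadfield$positions, file.path(dir, "leadfield_positions.csv"),
    row.names = FALSE
  )
  write.csv(session$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir Session directory.
#' @return A `synthetic_session`-shaped list (without the generator
#'   config).
#' @export
read_session <- function(dir) {
  rd_rec <- function(name) {
    meta <- jsonlite::read_json(file.path(dir, paste0(name, "_meta.json")),
      simplifyVector = TRUE
    )
    m <- as.matrix(read.csv(file.path(dir, paste0(name, "_data.csv"))))
    epoched_recording(array(as.numeric(m), dim = meta$dim), meta$fs,
      meta$time_ms,
      labels = meta$labels, role = meta$role
    )
  }
  gain <- as.matrix(read.csv(file.path(dir, "leadfield_gain.csv")))
  pos <- as.matrix(read.csv(file.path(dir, "leadfield_positions.csv")))
  dimnames(gain) <- NULL
  dimnames(pos) <- NULL
  structure(
    list(
      eeg = rd_rec("eeg"), emg = rd_rec("emg"),
      leadfield = lead_field(gain, pos),
      truth = tibble::as_tibble(read.csv(file.path(dir, "truth.csv")))
    ),
    class = "synthetic_session"
  )
}

#' Export a connectivity map as CSV
#'
#' Columns: source index, MNI x/y/z (if positions are attached), iPLV.
#'
#' @param map A `connectivity_map`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
export_map_csv <- function(map, file) {
  df <- data.frame(source = seq_along(map$values), iplv = map$values)
  if (!is.null(map$positions)) {
    df$x <- map$positions[, 1]
    df$y <- map$positions[, 2]
    df$z <- map$positions[, 3]
    df <- df[, c("source", "x", "y", "z", "iplv")]
  }
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Export a cROI set as JSON
#'
#' @param crois A `croi_set` from [extract_crois()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
export_crois_json <- function(crois, file) {
  jsonlite::write_json(
    lapply(seq_len(nrow(crois)), function(i) {
      list(
        name = crois$name[i],
        centroid = crois$centroid[[i]],
        members = crois$members[[i]],
        mean_iplv = crois$mean_iplv[i]
      )
    }),
    file,
    auto_unbox = TRUE, digits = NA
  )
  invisible(file)
}

#' Published per-subject AIC values for the five MEP models
#'
#' AIC values reported for eight subjects in a published EEG-TMS study of
#' motor-network state-dependent stimulation, for the constant, phase,
#' motor-network and network-plus-phase MEP-prediction models. Useful as a
#' worked example for [classify_models()].
#'
#' @return Tibble with columns `subject`, `constant`, `phase`, `network`,
#'   `network_plus_phase`.
#' @export
published_aic_table <- function() {
  tibble::tribble(
    ~subject, ~constant, ~phase, ~network, ~network_plus_phase,
    1, 2106.5, 2004.8, 2071.6, 1971.0,
    2, 1416.8, 1414.6, 1299.5, 1298.6,
    3, 1724.4, 1716.9, 1726.9, 1719.1,
    4, 1867.0, 1863.6, 1858.4, 1855.5,
    5, 1931.0, 1933.8, 1932.9, 1935.7,
    6, 1823.4, 1830.1, 1822.4, 1824.8,
    7, 2178.2, 2180.3, 2173.6, 2176.2,
    8, 1626.0, 1622.9, 1602.1, 1597.7
  )
}
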