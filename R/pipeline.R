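#' End-to-end analysis of one session
#'
#' Runs the full single-subject pipeline on an epoched EEG/EMG session:
#' bad-trial detection, ICA in the 35-PC subspace with automatic
#' mu-component selection, channel-level reconstruction from the kept
#' components, eLORETA source projection, seed-based iPLV mapping at the
#' individual mu frequency, cROI extraction, per-trial cROI connectivity,
#' MEP extraction with PC1 scoring, pre-pulse phase estimation at the
#' seed, and the five-model robust-regression comparison.
#'
#' @param session A `synthetic_session` (or any list with `eeg`, `emg`,
#'   `leadfield` of the same layout).
#' @param seed_index Seed source index (default 1, the lM1 node).
#' @param use_ica Run ICA cleaning before source projection (default
#'   FALSE). On grids of a few dozen sources, reconstructing the data from
#'   the handful of mu components reduces the sensor data to rank 2-3 and
#'   the whole-grid seed map degenerates; component selection is still
#'   reported when enabled. Enable it for artifact-laden inputs.
#' @param f_mu Analysis frequency; default NULL estimates it from the kept
#'   mu components (or falls back to the session config).
#' @param crois Optional precomputed [extract_crois()] table (e.g. from a
#'   group map); default extracts cROIs from this subject's own map.
#' @param motor_mask_mm Radius (mm) around the canonical motor nodes
#'   defining the motor mask for IC selection (default 30).
#' @param alpha eLORETA regularization (default 0.05).
#' @param n_comp ICA subspace dimension (default 35).
#' @param croi_quantile,link_mm,seed_exclusion_mm,min_size Passed to
#'   [extract_crois()].
#'
#' @return List of class `session_analysis`: `trials` (tibble with
#'   per-trial `pc1`, `iplv_*`, `phase`, `mep_linear`), `map`, `crois`,
#'   `models` ([fit_mep_models()] result), `f_mu`, `filter`, `ic_selection`,
#'   `mep_table`, `sources` (array).
#' @export
analyze_session <- function(session, seed_index = 1, use_ica = FALSE,
                            f_mu = NULL, crois = NULL, motor_mask_mm = 30,
                            alpha = 0.05, n_comp = 35,
                            croi_quantile = 0.95, link_mm = 15,
                            seed_exclusion_mm = 20, min_size = 5) {
  eeg <- session$eeg
  lfr <- reduce_orientation(session$leadfield)
  filt <- eloreta_filter(lfr, alpha = alpha)
  pos <- lfr$positions

  bad <- detect_bad(eeg)
  keep_tr <- setdiff(seq_len(n_trials(eeg)), bad$bad_trials)
  if (length(keep_tr) < n_trials(eeg)) {
    eeg$data <- eeg$data[, , keep_tr, drop = FALSE]
  }

  ic_selection <- NULL
  if (use_ica) {
    ica <- run_ica(eeg, n_comp = n_comp)
    mask <- motor_mask(pos, radius_mm = motor_mask_mm)
    sel <- select_mu_components(ica, filt, mask, eeg$fs)
    ic_selection <- sel$selection
    if (is.null(f_mu)) f_mu <- sel$profile$f_mu
    eeg <- reconstruct_clean(ica, which(sel$selection$kept), eeg$fs, eeg$time_ms)
  }
  if (is.null(f_mu)) f_mu <- session$config$f_mu

  src <- project_sources(filt, eeg)
  sm <- seed_map(src, seed_index, f_mu, eeg$fs, positions = pos)
  if (is.null(crois)) {
    crois <- extract_crois(sm$map,
      quantile = croi_quantile, link_mm = link_mm,
      seed_exclusion_mm = seed_exclusion_mm, min_size = min_size
    )
  }

  trials <- tibble::tibble(trial = keep_tr)
  for (i in seq_len(nrow(crois))) {
    trials[[paste0("iplv_", crois$name[i])]] <-
      croi_trial_iplv(src, seed_index, crois$members[[i]], f_mu, eeg$fs)
  }
  n_pre <- round(500 * eeg$fs / 1000)
  t_end <- max(eeg$time_ms)
  trials$phase <- vapply(seq_along(keep_tr), function(k) {
    x <- src[seed_index, , k]
    estimate_phase_at_pulse(tail(x, n_pre), f_mu, eeg$fs, t_end_ms = t_end)$phase
  }, numeric(1))

  mep <- extract_mep(session$emg)
  mep_k <- mep[keep_tr, ]
  trials$pc1 <- mep_k$pc1_score
  trials$mep_linear <- mep_k$linear_amp
  trials$mep_rejected <- mep_k$rejected

  ok <- !trials$mep_rejected & complete.cases(trials)
  models <- fit_mep_models(trials[ok, ],
    response = "pc1",
    iplv_cols = paste0("iplv_", crois$name)
  )

  structure(
    list(
      trials = trials, map = sm$map, crois = crois, models = models,
      f_mu = f_mu, filter = filt, ic_selection = ic_selection,
      mep_table = mep, sources = src
    ),
    class = "session_analysis"
  )
}

#' Motor-cortex source mask
#'
#' Indices of grid sources within `radius_mm` of any canonical motor node
#' ([motor_positions()]).
#'
#' @param positions `n x 3` MNI positions (mm).
#' @param radius_mm Mask radius (default 30).
#' @return Integer vector of source indices.
#' @export
motor_mask <- function(positions, radius_mm = 30) {
  positions <- as.matrix(positions)
  mp <- motor_positions()
  hit <- rep(FALSE, nrow(positions))
  for (p in mp) {
    hit <- hit | sqrt(colSums((t(positions) - p)^2)) <= radius_mm
  }
  which(hit)
}

#' Cohort-level HC/LC modulation analysis on trial tables
#'
#' For each subject's per-trial table (with `iplv_*` and `mep_linear`
#' columns), median-splits every connectivity column, intersects the
#' splits into network-level HC/LC trial sets, and tests the HC - LC MEP
#' modulation across subjects (one-tailed, HC > LC).
#'
#' @param tables List of per-subject tibbles (e.g. from
#'   [simulate_trial_table()] or [analyze_session()]`$trials`).
#' @param iplv_cols Connectivity columns (default all `iplv_*`).
#' @param mep_col MEP amplitude column (default `mep_linear`).
#' @return List: `network` ([mep_modulation()] result for
#'   HC_network vs LC_network), `per_croi` (named list of modulation
#'   results per connectivity column), `overlap_percent` (per subject).
#' @export
cohort_modulation <- function(tables,
                              iplv_cols = grep("^iplv", names(tables[[1]]), value = TRUE),
                              mep_col = "mep_linear") {
  n_sub <- length(tables)
  mep <- lapply(tables, `[[`, mep_col)
  hc_net <- lc_net <- vector("list", n_sub)
  per_croi_sets <- lapply(iplv_cols, function(cc) list(hc = vector("list", n_sub), lc = vector("list", n_sub)))
  names(per_croi_sets) <- iplv_cols
  overlap <- numeric(n_sub)
  for (s in seq_len(n_sub)) {
    splits <- lapply(iplv_cols, function(cc) median_split(tables[[s]][[cc]]))
    for (i in seq_along(iplv_cols)) {
      per_croi_sets[[i]]$hc[[s]] <- splits[[i]]$hc
      per_croi_sets[[i]]$lc[[s]] <- splits[[i]]$lc
    }
    net <- network_trials(splits)
    hc_net[[s]] <- net$hc_network
    lc_net[[s]] <- net$lc_network
    overlap[s] <- net$overlap_percent
  }
  per_croi <- lapply(per_croi_sets, function(ss) mep_modulation(mep, ss$hc, ss$lc))
  list(
    network = mep_modulation(mep, hc_net, lc_net),
    per_croi = per_croi,
    overlap_percent = overlap
  )
}
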