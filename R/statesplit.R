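#' Median split of trials by connectivity
#'
#' High-connectivity (HC) trials are those strictly above the median and
#' low-connectivity (LC) strictly below; trials exactly at the median are
#' assigned deterministically in index order to whichever set is currently
#' smaller (HC first on a tie of sizes), so `|#HC - #LC| <= 1`.
#'
#' @param values Per-trial connectivity values (>= 10 finite values).
#' @return List with integer vectors `hc` and `lc`.
#' @export
median_split <- function(values) {
  if (sum(is.finite(values)) < 10) stop("need at least 10 finite values")
  if (length(unique(values[is.finite(values)])) == 1) {
    stop("degenerate connectivity: all values identical")
  }
  med <- median(values, na.rm = TRUE)
  hc <- which(values > med)
  lc <- which(values < med)
  for (i in which(values == med)) {
    if (length(hc) <= length(lc)) hc <- c(hc, i) else lc <- c(lc, i)
  }
  list(hc = sort(hc), lc = sort(lc))
}

#' Network-level trial sets from per-cROI splits
#'
#' HC_network trials are those in which *all* cROIs are simultaneously in
#' their high-connectivity state (intersection of the per-cROI HC sets);
#' LC_network likewise. The overlap percentage is
#' `100 * |HC1 n HC2| / |HC1|` for the two-cROI case (mean over ordered
#' pairs otherwise).
#'
#' @param splits List of per-cROI splits from [median_split()].
#' @return List with `hc_network`, `lc_network`, `overlap_percent`.
#' @export
network_trials <- function(splits) {
  stopifnot(length(splits) >= 1)
  hc <- Reduce(intersect, lapply(splits, `[[`, "hc"))
  lc <- Reduce(intersect, lapply(splits, `[[`, "lc"))
  overlap <- NA_real_
  if (length(splits) >= 2) {
    pairs <- utils::combn(length(splits), 2)
    ov <- apply(pairs, 2, function(p) {
      100 * length(intersect(splits[[p[1]]]$hc, splits[[p[2]]]$hc)) /
        length(splits[[p[1]]]$hc)
    })
    overlap <- mean(ov)
  }
  if (length(hc) == 0 || length(lc) == 0) {
    warning("empty network-level trial set")
  }
  list(hc_network = hc, lc_network = lc, overlap_percent = overlap)
}

#' MEP modulation between two trial subsets
#'
#' Per subject, the modulation of a subset S is the percent change in mean
#' MEP amplitude relative to that subject's own across-trial mean:
#' `mod(S) = 100 * (mean(MEP_S) - mean(MEP_all)) / mean(MEP_all)`. The
#' group test is a one-tailed paired t-test across subjects on
#' `mod(A) - mod(B)` (alternative: A > B).
#'
#' @param mep List (one element per subject) of per-trial linear MEP
#'   amplitudes (mV), or a single numeric vector for one subject.
#' @param subset_a,subset_b Lists (or vectors) of trial indices per
#'   subject; both non-empty.
#' @return Object of class `modulation_result`: `per_subject` tibble
#'   (`mod_a`, `mod_b`, `diff`), `mean_diff`, `sem_diff`, `t`, `p`
#'   (one-tailed), `n_subjects`.
#' @export
mep_modulation <- function(mep, subset_a, subset_b) {
  if (is.numeric(mep)) {
    mep <- list(mep)
    subset_a <- list(subset_a)
    subset_b <- list(subset_b)
  }
  n_sub <- length(mep)
  stopifnot(length(subset_a) == n_sub, length(subset_b) == n_sub)
  rows <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    if (length(subset_a[[s]]) == 0 || length(subset_b[[s]]) == 0) {
      stop("both subsets must be non-empty for every subject")
    }
    m_all <- mean(mep[[s]])
    mod <- function(idx) 100 * (mean(mep[[s]][idx]) - m_all) / m_all
    rows[[s]] <- tibble::tibble(
      subject = s, mod_a = mod(subset_a[[s]]), mod_b = mod(subset_b[[s]])
    )
  }
  per_subject <- dplyr::mutate(dplyr::bind_rows(rows), diff = .data$mod_a - .data$mod_b)
  diffs <- per_subject$diff
  tt <- NULL
  if (n_sub >= 3) {
    if (sd(diffs) == 0) {
      # degenerate case (e.g. identical subsets): t = 0 at zero difference
      tt <- list(statistic = c(t = 0), p.value = if (mean(diffs) > 0) 0 else 0.5)
      if (mean(diffs) == 0) tt$p.value <- 0.5
    } else {
      tt <- t.test(diffs, alternative = "greater")
    }
  } else {
    message("fewer than 3 subjects: group test skipped")
  }
  structure(
    list(
      per_subject = per_subject,
      mean_diff = mean(diffs),
      sem_diff = if (n_sub > 1) sd(diffs) / sqrt(n_sub) else NA_real_,
      t = if (!is.null(tt)) unname(tt$statistic) else NA_real_,
      p = if (!is.null(tt)) tt$p.value else NA_real_,
      n_subjects = n_sub
    ),
    class = "modulation_result"
  )
}

#' @export
print.modulation_result <- function(x, ...) {
  cat(sprintf(
    "<modulation_result> %d subjects: diff = %.1f +- %.1f %% (t = %.2f, one-tailed p = %.3g)\n",
    x$n_subjects, x$mean_diff, x$sem_diff, x$t, x$p
  ))
  invisible(x)
}

#' Connectivity-agnostic control trial splits
#'
#' Splits the chronological trial sequence (i) into first and second half
#' and (ii) into even- and odd-numbered trials.
#'
#' @param n_trials Number of trials (>= 2).
#' @return List of index-vector pairs `halves = list(first, second)` and
#'   `parity = list(odd, even)`.
#' @export
control_splits <- function(n_trials) {
  stopifnot(n_trials >= 2)
  half <- floor(n_trials / 2)
  list(
    halves = list(first = seq_len(half), second = (half + 1):n_trials),
    parity = list(
      odd = seq(1, n_trials, by = 2),
      even = seq(2, n_trials, by = 2)
    )
  )
}

#' Control-split tests on median MEP amplitudes
#'
#' For each control split, computes per-subject median MEP amplitudes in
#' the two subsets and runs a two-tailed paired t-test across subjects.
#'
#' @param mep List of per-subject per-trial MEP amplitude vectors.
#' @return Tibble with one row per control (`halves`, `parity`): mean
#'   medians, `t`, `p` (two-tailed).
#' @export
control_split_test <- function(mep) {
  n_sub <- length(mep)
  run <- function(pick) {
    m1 <- vapply(mep, function(x) median(x[pick(length(x))[[1]]]), numeric(1))
    m2 <- vapply(mep, function(x) median(x[pick(length(x))[[2]]]), numeric(1))
    tt <- t.test(m1, m2, paired = TRUE)
    tibble::tibble(
      mean_first = mean(m1), mean_second = mean(m2),
      t = unname(tt$statistic), p = tt$p.value
    )
  }
  dplyr::bind_rows(
    dplyr::mutate(run(function(n) control_splits(n)$halves), control = "halves"),
    dplyr::mutate(run(function(n) control_splits(n)$parity), control = "parity")
  )[, c("control", "mean_first", "mean_second", "t", "p")]
}
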