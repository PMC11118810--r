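#' AIC from a residual sum of squares
#'
#' Gaussian-likelihood AIC with the residual variance counted as a
#' parameter: `AIC = n * ln(rss / n) + 2 * (k + 1)`.
#'
#' @param rss Residual sum of squares (> 0).
#' @param n Number of observations (> k + 2).
#' @param k Number of regression coefficients.
#' @return The AIC value.
#' @export
aic_rss <- function(rss, n, k) {
  if (rss <= 0) stop("rss must be positive (degenerate fit)")
  if (n <= k + 2) stop("need n > k + 2 observations")
  n * log(rss / n) + 2 * (k + 1)
}

#' Classify candidate models by AIC differences
#'
#' The preferred model minimizes the AIC (ties broken toward fewer
#' coefficients); a model with `0 < delta <= delta_plausible` is
#' `plausible`, larger deltas are `not_plausible`. When the winning margin
#' over the runner-up is below 2 the preferred model is annotated as
#' mildly preferred.
#'
#' @param aics Named numeric vector of per-model AICs (>= 2 models).
#' @param k Coefficient counts, same order (used only for tie-breaking;
#'   defaults to the input order).
#' @param delta_plausible Plausibility threshold (default 7).
#' @return Tibble: `model`, `aic`, `delta_aic`, `class`,
#'   `mildly_preferred`.
#' @export
classify_models <- function(aics, k = seq_along(aics), delta_plausible = 7) {
  stopifnot(length(aics) >= 2)
  nm <- names(aics) %||% paste0("model", seq_along(aics))
  best <- which(aics == min(aics))
  if (length(best) > 1) best <- best[which.min(k[best])]
  delta <- aics - aics[best]
  cls <- ifelse(delta == 0, "preferred",
    ifelse(delta <= delta_plausible, "plausible", "not_plausible")
  )
  cls[best] <- "preferred"
  cls[-best][delta[-best] == 0] <- "plausible" # exact ties with the winner
  margin <- min(delta[-best])
  tibble::tibble(
    model = unname(nm), aic = unname(aics), delta_aic = unname(delta),
    class = unname(cls),
    mildly_preferred = unname(cls == "preferred" & margin < 2)
  )
}

# robust IRLS fit (bisquare, tuning 4.685); returns coefficients + RSS
irls_fit <- function(X, y, tol = 1e-8, max_iter = 50) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("rank-deficient design: collinear columns (%s)",
                 paste(bad, collapse = ", ")))
  }
  # bisquare psi with its standard tuning constant 4.685 (the default)
  # rlm.default fits exactly the supplied design (intercept column included)
  fit <- MASS::rlm(X, y, psi = MASS::psi.bisquare, maxit = max_iter, acc = tol)
  r <- residuals(fit)
  # AIC uses the plain residual sum of squares of the robust fit: the
  # bisquare-weighted RSS shrinks with model size faster than a Gaussian
  # likelihood and mis-ranks nested models under the null
  list(coef = coef(fit), rss = sum(r^2), weights = fit$w, fit = fit)
}

#' Fit and compare the five MEP-prediction models
#'
#' Fits, by robust IRLS regression (bisquare weights, tuning constant
#' 4.685), five linear models of the per-trial MEP response: a constant
#' model; a single-cROI connectivity model `a + b1 * iPLV_1`; the network
#' model `a + sum_j b_j * iPLV_j`; the phase model
#' `a + c cos(phi) + d sin(phi)`; and the full network + phase model. The
#' models are then ranked by AIC ([aic_rss()]) and classified by
#' [classify_models()].
#'
#' @param data Data frame with one row per trial.
#' @param response Name of the response column (e.g. the PC1 log-MEP
#'   score); default `"pc1"`.
#' @param iplv_cols Names of the per-cROI connectivity columns (first one
#'   is the single-cROI model's predictor).
#' @param phase_col Name of the phase column (rad).
#' @param delta_plausible Plausibility threshold (default 7).
#'
#' @return Object of class `model_comparison`: `table` (per-model tibble
#'   with `k`, `rss`, `aic`, `delta_aic`, `class`), `fits` (per-model
#'   coefficient lists), `n_obs`, `response`.
#' @export
fit_mep_models <- function(data, response = "pc1",
                           iplv_cols = grep("^iplv", names(data), value = TRUE),
                           phase_col = "phase", delta_plausible = 7) {
  data <- as.data.frame(data)
  stopifnot(response %in% names(data), phase_col %in% names(data),
            length(iplv_cols) >= 1)
  keep <- complete.cases(data[, c(response, iplv_cols, phase_col)])
  data <- data[keep, ]
  n <- nrow(data)
  if (n < 50) stop("need at least 50 trials")
  y <- data[[response]]
  ivl <- as.matrix(data[, iplv_cols, drop = FALSE])
  cph <- cos(data[[phase_col]])
  sph <- sin(data[[phase_col]])
  one <- rep(1, n)
  designs <- list(
    constant = cbind(intercept = one),
    single_cROI = cbind(intercept = one, ivl[, 1, drop = FALSE]),
    network = cbind(intercept = one, ivl),
    phase = cbind(intercept = one, cos_phase = cph, sin_phase = sph),
    network_plus_phase = cbind(intercept = one, ivl, cos_phase = cph, sin_phase = sph)
  )
  fits <- lapply(designs, irls_fit, y = y)
  ks <- vapply(designs, ncol, integer(1))
  aics <- vapply(seq_along(fits), function(i) aic_rss(fits[[i]]$rss, n, ks[i]),
                 numeric(1))
  names(aics) <- names(designs)
  cls <- classify_models(aics, k = ks, delta_plausible = delta_plausible)
  tab <- dplyr::mutate(cls,
    k = unname(ks), rss = vapply(fits, `[[`, numeric(1), "rss"),
    .after = "model"
  )
  structure(
    list(
      table = tab,
      fits = lapply(fits, function(f) f$coef),
      n_obs = n, response = response,
      delta_plausible = delta_plausible
    ),
    class = "model_comparison"
  )
}

#' Preferred model of a comparison
#' @param x A `model_comparison`.
#' @return The preferred model's name.
#' @export
preferred_model <- function(x) {
  stopifnot(inherits(x, "model_comparison"))
  x$table$model[x$table$class == "preferred"][1]
}

#' Tidy a model comparison
#'
#' One row per model: coefficient count, RSS, AIC, delta AIC and
#' plausibility class.
#'
#' @param x A `model_comparison`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.model_comparison <- function(x, ...) {
  x$table
}

#' One-line summary of a model comparison
#'
#' @param x A `model_comparison`.
#' @param ... Unused.
#' @return A one-row tibble: number of models, observations, preferred
#'   model and its winning margin.
#' @export
glance.model_comparison <- function(x, ...) {
  tab <- x$table
  best <- which(tab$class == "preferred")[1]
  tibble::tibble(
    n_models = nrow(tab), n_obs = x$n_obs,
    preferred = tab$model[best],
    margin = min(tab$delta_aic[-best]),
    mildly_preferred = tab$mildly_preferred[best]
  )
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' @importFrom stats residuals
NULL
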