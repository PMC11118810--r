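#' Plot a connectivity map
#'
#' Sources are shown in the axial (x, y) plane, coloured and sized by
#' their iPLV to the seed; the seed is marked with a cross.
#'
#' @param object A `connectivity_map` with positions.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.connectivity_map <- function(object, ...) {
  if (is.null(object$positions)) stop("map carries no source positions")
  df <- data.frame(
    x = object$positions[, 1], y = object$positions[, 2],
    iplv = object$values
  )
  seed <- df[object$seed_index, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$iplv, size = .data$iplv)) +
    ggplot2::geom_point(data = seed, shape = 4, size = 4, stroke = 1.5) +
    ggplot2::scale_colour_viridis_c(option = "inferno") +
    ggplot2::labs(
      title = sprintf("Seed-based iPLV map (%s level, %.1f Hz)",
                      object$level, object$freq),
      x = "MNI x (mm)", y = "MNI y (mm)", colour = "iPLV"
    ) +
    ggplot2::guides(size = "none") +
    ggplot2::theme_minimal()
}

#' Plot a model comparison
#'
#' Delta-AIC per candidate model, coloured by plausibility class.
#'
#' @param object A `model_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.model_comparison <- function(object, ...) {
  tab <- object$table
  tab$model <- factor(tab$model, levels = tab$model[order(tab$aic)])
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$model, y = .data$delta_aic,
                                    fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$delta_plausible, linetype = 2) +
    ggplot2::labs(x = NULL, y = expression(Delta * AIC), fill = NULL) +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' Plot an HC/LC modulation result
#'
#' Group mean +- SEM of the percent MEP modulation in the two trial
#' subsets, with per-subject points.
#'
#' @param object A `modulation_result`.
#' @param labels Subset labels (default `c("HC", "LC")`).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.modulation_result <- function(object, labels = c("HC", "LC"), ...) {
  ps <- object$per_subject
  long <- tidyr::pivot_longer(ps, c("mod_a", "mod_b"),
    names_to = "subset", values_to = "modulation"
  )
  long$subset <- factor(ifelse(long$subset == "mod_a", labels[1], labels[2]),
    levels = labels
  )
  summ <- dplyr::summarise(
    dplyr::group_by(long, .data$subset),
    mean = mean(.data$modulation),
    sem = sd(.data$modulation) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$subset, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      width = 0.2
    ) +
    ggplot2::geom_jitter(
      data = long, ggplot2::aes(y = .data$modulation),
      width = 0.08, alpha = 0.6
    ) +
    ggplot2::labs(
      x = NULL, y = "MEP modulation (%)",
      subtitle = sprintf("diff = %.1f +- %.1f %%, one-tailed p = %.3g",
                         object$mean_diff, object$sem_diff, object$p)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
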