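#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bullseye plot of an RV polar map
#'
#' Polar tile plot of the per-sector maximum normalised counts; the
#' free-wall centre sits at the top, the septal edges at the sides, the
#' apex at the centre of the bullseye.
#'
#' @param object An `rv_polar_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rv_polar_map <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$psi * 180 / pi,
                                   y = .data$theta * 180 / pi,
                                   fill = .data$value)) +
    ggplot2::geom_tile(width = 360 / object$n_azimuth,
                       height = 180 / object$n_polar) +
    ggplot2::coord_polar(start = pi) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "RV/LV") +
    ggplot2::labs(x = "azimuth about free-wall centre (deg)",
                  y = "polar angle (deg)",
                  title = "RV polar map") +
    ggplot2::theme_minimal()
}

#' @export
plot.rv_polar_map <- function(x, ...) print(autoplot(x, ...))

#' Bland-Altman plot
#'
#' @param object A `bland_altman`.
#' @param ... Unused.
#' @return A ggplot with the mean difference and limits of agreement.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ylab <- if (object$percent) "difference (% of pair mean)" else
    "difference"
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean_diff,
                        linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower,
                                       object$loa_upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "pair mean", y = ylab,
                  title = "Bland-Altman agreement") +
    ggplot2::theme_minimal()
}

#' @export
plot.bland_altman <- function(x, ...) print(autoplot(x, ...))

#' ROC curve plot
#'
#' @param object An `rv_roc`.
#' @param ... Unused.
#' @return A ggplot of the ROC curve with the AUC in the title.
#' @export
autoplot.rv_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC curve (AUC %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' @export
plot.rv_roc <- function(x, ...) print(autoplot(x, ...))

#' Mid-slice view of a volume with optional mask overlay
#'
#' Quick-look display of one axial (short-axis) slice.
#'
#' @param vol A [scalar_volume()].
#' @param k Slice index (default: middle slice).
#' @param mask Optional logical array outlined on top.
#' @return A ggplot.
#' @export
plot_slice <- function(vol, k = NULL, mask = NULL) {
  d <- dim(vol$data)
  if (is.null(k)) k <- round(d[3] / 2)
  sl <- vol$data[, , k]
  df <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$value <- as.vector(sl)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "counts") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("slice k = %d", k)) +
    ggplot2::theme_minimal()
  if (!is.null(mask) && any(mask[, , k])) {
    mdf <- df[as.vector(mask[, , k]), c("x", "y")]
    p <- p + ggplot2::geom_tile(data = mdf,
                                ggplot2::aes(x = .data$x, y = .data$y),
                                fill = NA, colour = "red",
                                linewidth = 0.2, inherit.aes = FALSE)
  }
  p
}

#' @importFrom rlang .data
NULL
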