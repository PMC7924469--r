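#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_vline
#'   geom_abline labs theme_minimal scale_color_manual geom_tile geom_text
NULL

#' Plot an ultrafuzziness scan
#'
#' Ultrafuzziness against threshold position, with the selected ambiguity
#' threshold marked.
#'
#' @param object An [ambiguity_threshold()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot ultrafuzziness_scan
#' @export
autoplot.ultrafuzziness_scan <- function(object, ...) {
  ggplot(object$profile, aes(x = .data$g, y = .data$gamma)) +
    geom_line(color = "steelblue") +
    geom_vline(xintercept = object$tau, linetype = "dashed") +
    labs(x = "threshold position g", y = "ultrafuzziness",
         title = sprintf("Ambiguity threshold tau = %d", object$tau)) +
    theme_minimal()
}

#' Plot a box-counting curve
#'
#' The log-log relationship between box size and occupied-box count whose
#' slope is the fractal dimension; excluded single-box scales are hollow.
#'
#' @param object The `curve` attribute of a [fractal_dimension()] result
#'   (a `boxcount_curve` tibble).
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot boxcount_curve
#' @export
autoplot.boxcount_curve <- function(object, ...) {
  d <- attr(object, "dimension")
  ggplot(object, aes(x = log(1 / .data$eps), y = log(.data$n))) +
    geom_point(aes(shape = .data$used), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::stat_smooth(data = function(df) df[df$used, ], method = "lm",
                         formula = y ~ x, se = FALSE, linewidth = 0.4,
                         color = "firebrick") +
    labs(x = "log(1/eps)", y = "log N(eps)",
         title = sprintf("Box-counting dimension D = %.3f", d)) +
    theme_minimal()
}

#' Feature-space view of a lesion dataset
#'
#' Fractal dimension against convexity, colored by label: regular borders sit
#' at low dimension / high convexity, irregular borders at high dimension /
#' low convexity.
#'
#' @param features A [lesion_features()] tibble (columns `FD`, `C`, `label`).
#' @return A ggplot.
#' @export
plot_feature_space <- function(features) {
  df <- dplyr::mutate(features,
                      class = ifelse(.data$label == 1, "regular", "irregular"))
  ggplot(df, aes(x = .data$FD, y = .data$C, color = .data$class)) +
    geom_point(alpha = 0.8) +
    scale_color_manual(values = c(regular = "#2166ac", irregular = "#b2182b")) +
    labs(x = "fractal dimension", y = "convexity", color = NULL) +
    theme_minimal()
}

#' Plot a confusion matrix
#'
#' @param object An [evaluate()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot lesion_metrics
#' @export
autoplot.lesion_metrics <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  ggplot(df, aes(x = .data$predicted, y = .data$truth, fill = .data$Freq)) +
    geom_tile() +
    geom_text(aes(label = .data$Freq), color = "white", size = 5) +
    ggplot2::scale_fill_gradient(low = "grey40", high = "#b2182b", guide = "none") +
    labs(title = sprintf("accuracy %.1f%%", object$accuracy)) +
    theme_minimal()
}
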