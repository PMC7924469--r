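#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Gaussian naive Bayes model
#'
#' One row per class and feature with the fitted mean and variance.
#'
#' @param x A [gnb_fit()] result.
#' @param ... Ignored.
#' @return A tibble with columns `class`, `feature`, `mean`, `variance`.
#' @method tidy gnb_model
#' @export
tidy.gnb_model <- function(x, ...) {
  feats <- x$features %||% paste0("F", seq_len(ncol(x$mean)))
  tibble::tibble(
    class = rep(c("irregular", "regular"), each = ncol(x$mean)),
    feature = rep(feats, times = 2L),
    mean = c(x$mean[1L, ], x$mean[2L, ]),
    variance = c(x$var[1L, ], x$var[2L, ])
  )
}

#' @rdname tidy.gnb_model
#' @return `glance()`: a one-row tibble with the priors, feature count and n.
#' @method glance gnb_model
#' @export
glance.gnb_model <- function(x, ...) {
  tibble::tibble(prior_irregular = x$priors[["irregular"]],
                 prior_regular = x$priors[["regular"]],
                 n_features = ncol(x$mean), n = x$n)
}

#' Tidy classification metrics
#'
#' @param x An [evaluate()] result.
#' @param ... Ignored.
#' @return `tidy()`: one row per confusion cell; `glance()`: one row with the
#'   four rates (percent) and n.
#' @method tidy lesion_metrics
#' @export
tidy.lesion_metrics <- function(x, ...) {
  df <- as.data.frame(as.table(x$confusion), stringsAsFactors = FALSE)
  tibble::tibble(truth = df$truth, predicted = df$predicted, count = df$Freq)
}

#' @rdname tidy.lesion_metrics
#' @method glance lesion_metrics
#' @export
glance.lesion_metrics <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, sensitivity = x$sensitivity,
                 specificity = x$specificity, f_score = x$f_score, n = x$n)
}

#' Tidy a trained CNN
#'
#' @param x A [cnn_train()] result.
#' @param ... Ignored.
#' @return `tidy()`: one row per layer with parameter counts; `glance()`: one
#'   row with the architecture summary and final training loss.
#' @method tidy cnn_model
#' @export
tidy.cnn_model <- function(x, ...) {
  w <- x$weights
  conv <- purrr::imap(w$conv, function(l, i) {
    tibble::tibble(layer = sprintf("conv%d", i),
                   parameters = length(l$W) + length(l$b))
  })
  dplyr::bind_rows(
    dplyr::bind_rows(conv),
    tibble::tibble(layer = "dense1",
                   parameters = length(w$dense1$W) + length(w$dense1$b)),
    tibble::tibble(layer = "dense2",
                   parameters = length(w$dense2$W) + length(w$dense2$b))
  )
}

#' @rdname tidy.cnn_model
#' @method glance cnn_model
#' @export
glance.cnn_model <- function(x, ...) {
  tibble::tibble(
    conv_layers = length(x$spec$filters),
    dense_layers = 2L,
    input_size = x$spec$input_size,
    epochs = x$spec$epochs,
    final_loss = x$loss_history[length(x$loss_history)]
  )
}
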