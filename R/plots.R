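# ggplot2 views of the main result types.

#' Plot mean spectra by class
#'
#' Class-wise mean reflectance curves of a spectra table.
#'
#' @param table a [spectra_table()].
#' @return A ggplot object.
#' @export
plot_spectra <- function(table) {
  assert_that(inherits(table, "spectra_table"), "`table` must be a spectra_table")
  df <- dplyr::bind_rows(lapply(sort(unique(table$y)), function(cl)
    tibble::tibble(wavelength = table$wavelength,
                   reflectance = colMeans(table$X[table$y == cl, ,
                                                  drop = FALSE]),
                   class = factor(cl))))
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength, .data$reflectance,
                                   colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "mean reflectance",
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a wavelength-selection result
#'
#' The selector's criterion trace (RMSECV per run for CARS, best RMSEP per
#' subset size for SPA) with the winning point marked.
#'
#' @param object a `selection_result` from [cars_select()] or
#'   [spa_select()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.selection_result <- function(object, ...) {
  if (object$method == "CARS") {
    df <- object$trace
    ggplot2::ggplot(df, ggplot2::aes(.data$run, .data$rmsecv)) +
      ggplot2::geom_line() +
      ggplot2::geom_point(data = df[object$best_run, ], colour = "red") +
      ggplot2::labs(x = "sampling run", y = "RMSECV") +
      ggplot2::theme_minimal()
  } else {
    df <- object$trace
    ggplot2::ggplot(df, ggplot2::aes(.data$size, .data$best_rmsep)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::labs(x = "subset size", y = "best RMSEP") +
      ggplot2::theme_minimal()
  }
}

#' Plot a training history
#'
#' Loss and accuracy curves from [train_cnn()].
#'
#' @param history the `history` tibble of a [train_cnn()] result.
#' @return A ggplot object.
#' @export
plot_training_history <- function(history) {
  df <- dplyr::bind_rows(
    tibble::tibble(epoch = history$epoch, value = history$train_acc,
                   series = "train accuracy"),
    tibble::tibble(epoch = history$epoch, value = history$val_acc,
                   series = "validation accuracy"))
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "accuracy", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix
#'
#' Heat-map of counts with the predicted class on the x axis.
#'
#' @param cm a [confusion()] matrix.
#' @return A ggplot object.
#' @export
plot_confusion <- function(cm) {
  cm <- unclass(as.matrix(cm))
  df <- expand.grid(true = seq_len(nrow(cm)), predicted = seq_len(ncol(cm)))
  df$count <- as.vector(cm)
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::scale_y_reverse(breaks = seq_len(nrow(cm))) +
    ggplot2::scale_x_continuous(breaks = seq_len(ncol(cm))) +
    ggplot2::labs(x = "predicted class", y = "true class") +
    ggplot2::theme_minimal()
}
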