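# broom-style accessors and ggplot2 methods for fitted objects and
# evaluation results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a training fit: the per-epoch loss history in long format
#'
#' @param x a `pn_fit` from [train()].
#' @param ... unused.
#' @return tibble (epoch, series, loss) with series train_total, train_box,
#'   train_obj, train_cls, val_total, val_box.
#' @exportS3Method generics::tidy
tidy.pn_fit <- function(x, ...) {
  tidyr_longer <- function(df) {
    cols <- setdiff(names(df), c("epoch", "lr"))
    dplyr::bind_rows(lapply(cols, function(cn) {
      tibble::tibble(epoch = df$epoch, series = cn, loss = df[[cn]])
    }))
  }
  out <- tidyr_longer(x$history)
  out[!is.na(out$loss), ]
}

#' Summarize a training fit in one row
#'
#' @param x a `pn_fit`.
#' @param ... unused.
#' @exportS3Method generics::glance
glance.pn_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    variant = x$detector$cfg$variant,
    epochs = nrow(h),
    final_train_loss = h$train_total[nrow(h)],
    final_val_loss = h$val_total[nrow(h)],
    best_epoch = x$best_epoch,
    n_params = count_params_flops(x$detector,
                                  x$train_cfg$input_size)$params)
}

#' Tidy an evaluation result
#'
#' @param x a `pn_eval` from [stratified_eval()] / [evaluate_detector()].
#' @param ... unused.
#' @return the underlying tibble.
#' @exportS3Method generics::tidy
tidy.pn_eval <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "pn_eval")
  out
}

#' One-row summary of an evaluation result (the overall stratum)
#' @param x a `pn_eval`.
#' @param ... unused.
#' @exportS3Method generics::glance
glance.pn_eval <- function(x, ...) {
  out <- x[x$stratum == "overall", ]
  class(out) <- setdiff(class(out), "pn_eval")
  out
}

#' Plot training and validation loss curves
#'
#' @param object a `pn_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pn_fit <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$series %in% c("train_total", "train_box", "val_total", "val_box"), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL,
                  title = "Training and validation loss") +
    ggplot2::theme_minimal()
}

#' Plot per-stratum detection metrics
#'
#' @param object a `pn_eval`.
#' @param ... unused.
#' @return a ggplot (bar chart of AP50, AP50:95 and F1 per stratum).
#' @exportS3Method ggplot2::autoplot
autoplot.pn_eval <- function(object, ...) {
  d <- tidy(object)
  long <- dplyr::bind_rows(lapply(c("ap50", "ap50_95", "f1"), function(m) {
    tibble::tibble(stratum = d$stratum, metric = m, value = d[[m]])
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stratum, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL,
                  title = "Detection metrics by stratum") +
    ggplot2::theme_minimal()
}

#' Plot a scene with its ground-truth or predicted boxes
#'
#' @param image H x W x 3 array.
#' @param boxes `pn_boxes` (normalized).
#' @param colour box colour.
#' @return a ggplot.
#' @export
plot_scene <- function(image, boxes = NULL, colour = "yellow") {
  d <- dim(image)
  df <- expand.grid(y = seq_len(d[1]), x = seq_len(d[2]))
  df$fill <- grDevices::rgb(as.vector(image[, , 1]), as.vector(image[, , 2]),
                            as.vector(image[, , 3]))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(boxes) && nrow(boxes)) {
    bb <- tibble::tibble(
      xmin = (boxes$cx - boxes$w / 2) * d[2],
      xmax = (boxes$cx + boxes$w / 2) * d[2],
      ymin = (boxes$cy - boxes$h / 2) * d[1],
      ymax = (boxes$cy + boxes$h / 2) * d[1])
    p <- p + ggplot2::geom_rect(
      data = bb,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax),
      inherit.aes = FALSE, colour = colour, fill = NA, linewidth = 0.4)
  }
  p
}

#' @importFrom rlang .data
NULL
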