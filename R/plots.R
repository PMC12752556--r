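# ggplot2 visualisation methods for the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a synthetic patch with its ground-truth objects
#'
#' Renders the RGB image with object centroids and instance outlines
#' coloured by role.
#'
#' @param object a `synth_patch`.
#' @param show_centroids overlay centroids coloured by role.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.synth_patch <- function(object, show_centroids = TRUE, ...) {
  h <- nrow(object$mask); w <- ncol(object$mask)
  p <- ggplot2::ggplot() +
    ggplot2::annotation_raster(object$image, xmin = 0, xmax = w,
                               ymin = -h, ymax = 0) +
    ggplot2::coord_fixed(xlim = c(0, w), ylim = c(-h, 0), expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
  if (show_centroids && nrow(object$class_table) > 0) {
    tab <- object$class_table
    tab$role <- role_of_class(tab$class)
    p <- p + ggplot2::geom_point(
      data = tab,
      ggplot2::aes(x = .data$cx, y = -.data$cy, colour = .data$role,
                   shape = .data$is_cluster),
      size = 2) +
      ggplot2::labs(colour = "role", shape = "cluster")
  }
  p
}

#' Plot a training loss trace
#'
#' @param object a trained `seg_net` or `cell_net` (with `loss_trace`).
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.seg_net <- function(object, ...) plot_loss_trace(object$loss_trace)

#' @exportS3Method ggplot2::autoplot
autoplot.cell_net <- function(object, ...) plot_loss_trace(object$loss_trace)

plot_loss_trace <- function(trace) {
  if (is.null(trace)) stop("model has no loss trace (untrained?)",
                           call. = FALSE)
  df <- tibble::tibble(epoch = seq_along(trace), loss = trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean training loss") +
    ggplot2::theme_minimal()
}

#' Plot the cross-validation report of a slide classifier
#'
#' One point per grid configuration, CV accuracy against learning rate,
#' faceted by tree depth.
#'
#' @param object a `wsi_gbt` fit.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.wsi_gbt <- function(object, ...) {
  df <- object$cv_report
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$eta), .data$cv_accuracy,
                                   colour = factor(.data$nrounds),
                                   shape = factor(.data$subsample))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~max_depth, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "learning rate", y = "CV accuracy",
                  colour = "rounds", shape = "subsample") +
    ggplot2::theme_minimal()
}

#' Heatmap of a confusion table
#'
#' @param counts matrix/table with true labels on rows and predictions on
#'   columns.
#' @return a ggplot object.
#' @export
plot_confusion <- function(counts) {
  df <- as.data.frame(as.table(as.matrix(counts)))
  names(df) <- c("true", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "predicted", y = "true") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Compare appearance profiles channel by channel
#'
#' Means with +/- one standard deviation, per opponent-space channel, for
#' one or more profiles.
#'
#' @param ... named `appearance_profile` objects.
#' @return a ggplot object.
#' @export
plot_profiles <- function(...) {
  profs <- list(...)
  if (is.null(names(profs)) || any(names(profs) == ""))
    names(profs) <- paste0("profile", seq_along(profs))
  df <- dplyr::bind_rows(lapply(names(profs), function(nm) {
    p <- profs[[nm]]
    tibble::tibble(profile = nm,
                   channel = c("luminance", "chroma-1", "chroma-2"),
                   mean = unname(p$mean), sd = unname(p$sd))
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$channel, .data$mean,
                                   colour = .data$profile)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             position = ggplot2::position_dodge(0.4)) +
    ggplot2::labs(y = "channel value (log-LMS opponent space)") +
    ggplot2::theme_minimal()
}
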