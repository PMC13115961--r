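# ggplot2 display methods for the raster result types.

raster_df <- function(m, mask = NULL) {
  df <- tibble::tibble(
    row = rep(seq_len(nrow(m)), ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m))
  if (!is.null(mask)) df$value[!as.vector(as.matrix(mask))] <- NA
  df
}

gg_raster <- function(df, title, fill_lab) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = fill_lab) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.projection_image <- function(object, ...) {
  gg_raster(raster_df(object$values, object$mask),
            sprintf("projection: %s / %s", object$sample_id,
                    object$tissue_type), "P") +
    ggplot2::scale_fill_viridis_c(na.value = "grey90")
}

#' @export
autoplot.moran_result <- function(object, what = c("observed_I", "pseudo_p"),
                                  ...) {
  what <- match.arg(what)
  gg_raster(raster_df(object[[what]]),
            sprintf("%s: %s", what, object$sample_id), what) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90")
}

#' @export
autoplot.hotspot_map <- function(object, ...) {
  df <- raster_df(matrix(as.numeric(object), nrow(object)))
  gg_raster(df, sprintf("%s map: %s (alpha %.4g)", attr(object, "kind"),
                        attr(object, "sample_id"), attr(object, "alpha")),
            attr(object, "kind")) +
    ggplot2::scale_fill_gradient(low = "grey95", high = "firebrick")
}

#' @export
autoplot.sa_overlay <- function(object, ...) {
  on <- which(as.matrix(object$mask))
  nr <- nrow(object$mask)
  df <- tibble::tibble(row = ((on - 1L) %% nr) + 1L,
                       col = ((on - 1L) %/% nr) + 1L,
                       label = object$label[on])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "tissue-type overlay", x = NULL, y = NULL,
                  fill = "assignment") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sa_calibration <- function(object, ...) {
  ggplot2::ggplot(object$iou_curve,
                  ggplot2::aes(x = .data$alpha, y = .data$mean_iou)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$alpha_star, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$alpha_db, linetype = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(title = sprintf("reference calibration: alpha* = %.4f",
                                  object$alpha_star),
                  x = "alpha (log scale)", y = "mean IoU vs database") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mir_feature_ranking <- function(object, ...) {
  df <- dplyr::select(object$ranking, -"scores")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavenumber,
                                   y = .data$mean_importance)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_point(data = df[df$times_in_top10 > 0, ],
                        ggplot2::aes(size = .data$times_in_top10),
                        colour = "firebrick", alpha = 0.7) +
    ggplot2::labs(title = sprintf("band importance: %s", object$tissue_type),
                  x = "wavenumber (1/cm)", y = "mean permutation importance",
                  size = "times in top 10") +
    ggplot2::theme_minimal()
}
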