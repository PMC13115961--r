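# broom-style tidiers and re-exports.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Moran result into a per-pixel tibble
#'
#' @param x a [local_moran()] result.
#' @param ... unused.
#' @return tibble: `row`, `col`, `value`-free per-pixel columns
#'   `observed_I`, `pseudo_p`, `lag`, `quadrant` (on-mask pixels only).
#' @export
tidy.moran_result <- function(x, ...) {
  on <- which(as.matrix(x$mask))
  nr <- nrow(x$mask)
  tibble::tibble(
    row = ((on - 1L) %% nr) + 1L,
    col = ((on - 1L) %/% nr) + 1L,
    observed_I = x$observed_I[on],
    pseudo_p = x$pseudo_p[on],
    lag = if (is.null(x$lag)) NA_real_ else x$lag[on],
    quadrant = x$quadrant[on])
}

#' @rdname tidy.moran_result
#' @export
glance.moran_result <- function(x, ...) {
  tibble::tibble(sample_id = x$sample_id, n_used = x$n_used,
                 global_mean = x$global_mean, m2 = x$m2,
                 n_perm = x$n_perm, seed = x$seed)
}

#' Tidy methods for feature-selection results
#'
#' @param x a [discriminant_features()] or [rank_wavenumbers()] result.
#' @param ... unused.
#' @return a tibble (the feature table / the per-band ranking).
#' @export
tidy.discriminant_features <- function(x, ...) x$features

#' @rdname tidy.discriminant_features
#' @export
glance.discriminant_features <- function(x, ...) {
  tibble::tibble(tissue_type = x$tissue_type, n_features = nrow(x$features),
                 max_error = x$max_error,
                 n_ppf = sum(x$features$direction == "ppf"),
                 n_npf = sum(x$features$direction == "npf"))
}

#' @rdname tidy.discriminant_features
#' @export
tidy.mir_feature_ranking <- function(x, ...) {
  dplyr::select(x$ranking, -"scores")
}

#' Tidy methods for calibration and database objects
#'
#' @param x a [reference_sa()] or [build_database()] result.
#' @param ... unused.
#' @return the IoU curve / ratio table as a tibble.
#' @export
tidy.sa_calibration <- function(x, ...) x$iou_curve

#' @rdname tidy.sa_calibration
#' @export
glance.sa_calibration <- function(x, ...) {
  tibble::tibble(alpha_star = x$alpha_star, alpha_db = x$alpha_db,
                 best_mean_iou = max(x$iou_curve$mean_iou),
                 n_perm = x$n_perm, seed = x$seed, mode = x$mode,
                 references = paste(x$references, collapse = ","))
}

#' @rdname tidy.sa_calibration
#' @export
tidy.hotspot_db <- function(x, ...) x$ratios

#' Tidy an overlay into per-pixel assignments
#'
#' @param x an [overlay_maps()] result.
#' @param ... unused.
#' @return tibble `row`, `col`, `label`, `n_assigned` (on-mask pixels).
#' @export
tidy.sa_overlay <- function(x, ...) {
  on <- which(as.matrix(x$mask))
  nr <- nrow(x$mask)
  tibble::tibble(row = ((on - 1L) %% nr) + 1L,
                 col = ((on - 1L) %/% nr) + 1L,
                 label = x$label[on], n_assigned = x$count[on])
}

#' Tidy a metric report
#'
#' @param x a [cohort_report()] result.
#' @param ... unused.
#' @return `tidy()`: the per-rectangle table; `glance()`: per-tissue summary
#'   joined with the pooled metrics.
#' @export
tidy.metric_report <- function(x, ...) x$per_rect

#' @rdname tidy.metric_report
#' @export
glance.metric_report <- function(x, ...) {
  dplyr::left_join(x$summary,
                   dplyr::select(x$pooled, "tissue", "balanced_accuracy",
                                 "ppv", "standard_accuracy"),
                   by = "tissue")
}
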