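# Pixel-level evaluation of SA annotations against pathology label maps
# inside evaluation rectangles.

#' Confusion counts within an evaluation rectangle
#'
#' Compares a binary prediction (hotspot map, or one tissue's layer of an
#' overlay) with the pathology label map inside `rect` intersected with the
#' on-tissue mask. Unlabelled-truth pixels are excluded ("not considered").
#' Pixels the SA stage left unassigned count as negative predictions by
#' default; `unassigned = "exclude"` drops pixels flagged in
#' `unassigned_mask` from the denominator instead.
#'
#' @param pred logical matrix / [threshold_hotspots()] map: positive where
#'   the tissue was annotated.
#' @param truth a [label_map()].
#' @param tissue the tissue-type name evaluated (must be in the legend).
#' @param rect one row of [read_rectangles()] (or a list with `rect_id`,
#'   `row0`, `col0`, `row1`, `col1`, 1-based inclusive).
#' @param mask optional on-tissue mask.
#' @param unassigned `"negative"` (default) or `"exclude"`.
#' @param unassigned_mask logical matrix of SA-unassigned pixels (used when
#'   `unassigned = "exclude"`).
#' @return one-row tibble: `tissue`, `rect_id`, `TP`, `FP`, `FN`, `TN`, `n`.
#' @export
confusion_counts <- function(pred, truth, tissue, rect, mask = NULL,
                             unassigned = c("negative", "exclude"),
                             unassigned_mask = NULL) {
  unassigned <- match.arg(unassigned)
  stopifnot(inherits(truth, "label_map"))
  pred <- matrix(as.logical(pred), nrow(pred))
  check_same_shape(pred, truth, "pred/truth")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(pred), ncol(pred))
  mask <- as_mask(mask)
  r0 <- rect$row0; r1 <- rect$row1; c0 <- rect$col0; c1 <- rect$col1
  if (r0 < 1 || c0 < 1 || r1 > nrow(pred) || c1 > ncol(pred) || r0 > r1 ||
      c0 > c1) {
    stop("rectangle out of image bounds", call. = FALSE)
  }
  sel <- matrix(FALSE, nrow(pred), ncol(pred))
  sel[r0:r1, c0:c1] <- TRUE
  lab <- label_names(truth)
  sel <- sel & mask & !is.na(lab)
  if (unassigned == "exclude" && !is.null(unassigned_mask)) {
    sel <- sel & !unassigned_mask
  }
  if (!any(sel)) stop("empty evaluated set in rectangle", call. = FALSE)
  is_t <- lab == tissue
  TP <- sum(sel & pred & is_t)
  FP <- sum(sel & pred & !is_t)
  FN <- sum(sel & !pred & is_t)
  TN <- sum(sel & !pred & !is_t)
  tibble::tibble(tissue = tissue, rect_id = as.character(rect$rect_id),
                 TP = TP, FP = FP, FN = FN, TN = TN, n = TP + FP + FN + TN)
}

#' Annotation agreement metrics
#'
#' `standard_accuracy()` is the fraction of correctly assigned pixels
#' `(TP + TN) / (TP + TN + FP + FN)`; `balanced_accuracy()` is
#' `(TPR + TNR) / 2`, the prevalence-independent variant; `ppv()` is the
#' precision `TP / (TP + FP)`. Each takes a data frame with columns
#' `TP`, `FP`, `FN`, `TN` (as produced by [confusion_counts()]) and is
#' vectorised over rows.
#'
#' @param counts data frame with columns `TP`, `FP`, `FN`, `TN`.
#' @return numeric vector of metric values in `[0, 1]`.
#' @name metrics
NULL

#' @rdname metrics
#' @export
standard_accuracy <- function(counts) {
  tot <- counts$TP + counts$TN + counts$FP + counts$FN
  if (any(tot == 0)) stop("undefined metric: zero evaluated pixels",
                          call. = FALSE)
  (counts$TP + counts$TN) / tot
}

#' @rdname metrics
#' @export
balanced_accuracy <- function(counts) {
  pos <- counts$TP + counts$FN
  neg <- counts$TN + counts$FP
  if (any(pos == 0) || any(neg == 0)) {
    stop("undefined metric: a class is absent (report standard accuracy only)",
         call. = FALSE)
  }
  (counts$TP / pos + counts$TN / neg) / 2
}

#' @rdname metrics
#' @export
ppv <- function(counts) {
  denom <- counts$TP + counts$FP
  if (any(denom == 0)) stop("undefined metric: no positive predictions",
                            call. = FALSE)
  counts$TP / denom
}

#' Cohort-level metric report
#'
#' Per sample and tissue: the mean standard accuracy over that sample's
#' rectangles. Across samples: median and quartiles (linear interpolation)
#' of those per-sample means. Pooled balanced accuracy and PPV are computed
#' from the element-wise *summed* counts over all rectangles and samples of a
#' tissue (not the mean of per-rectangle values).
#'
#' @param counts tibble of [confusion_counts()] rows with an additional
#'   `sample_id` column.
#' @return object of class `metric_report`: tibbles `$per_rect`,
#'   `$per_sample`, `$summary` (accuracy quartiles per tissue) and `$pooled`
#'   (summed-count BA/PPV per tissue).
#' @export
cohort_report <- function(counts) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("sample_id", "tissue", "rect_id", "TP", "FP", "FN", "TN")
                %in% names(counts)))
  per_rect <- counts |>
    dplyr::mutate(standard_accuracy = standard_accuracy(counts))
  per_sample <- per_rect |>
    dplyr::group_by(.data$sample_id, .data$tissue) |>
    dplyr::summarise(
      n_rects = dplyr::n(),
      mean_standard_accuracy = mean(.data$standard_accuracy),
      .groups = "drop")
  summary <- per_sample |>
    dplyr::group_by(.data$tissue) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      q1 = unname(stats::quantile(.data$mean_standard_accuracy, 0.25,
                                  type = 7)),
      median = stats::median(.data$mean_standard_accuracy),
      q3 = unname(stats::quantile(.data$mean_standard_accuracy, 0.75,
                                  type = 7)),
      .groups = "drop")
  pooled <- counts |>
    dplyr::group_by(.data$tissue) |>
    dplyr::summarise(dplyr::across(c("TP", "FP", "FN", "TN"), sum),
                     .groups = "drop")
  pooled$balanced_accuracy <- vapply(seq_len(nrow(pooled)), function(i) {
    row <- pooled[i, ]
    if (row$TP + row$FN == 0 || row$TN + row$FP == 0) NA_real_
    else balanced_accuracy(row)
  }, numeric(1))
  pooled$ppv <- ifelse(pooled$TP + pooled$FP > 0,
                       pooled$TP / (pooled$TP + pooled$FP), NA_real_)
  pooled$standard_accuracy <- standard_accuracy(pooled)
  structure(list(per_rect = per_rect, per_sample = per_sample,
                 summary = summary, pooled = pooled),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n  per-tissue accuracy quartiles (per-sample means):\n")
  print(x$summary)
  cat("  pooled (summed counts):\n")
  print(x$pooled)
  invisible(x)
}

#' Write a metric report (CSV per rectangle + JSON summary)
#'
#' @param report a [cohort_report()] result.
#' @param csv_path,json_path output paths.
#' @return `csv_path` invisibly.
#' @export
write_report <- function(report, csv_path, json_path = NULL) {
  stopifnot(inherits(report, "metric_report"))
  utils::write.csv(report$per_rect, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(summary = report$summary, pooled = report$pooled),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
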