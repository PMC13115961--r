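#' Spectral cube container
#'
#' A `spectral_cube` holds a mid-infrared hyperspectral image: a 3-D numeric
#' array `rows x cols x bands` together with the band centres in wavenumbers
#' (cm^-1). Bands are always stored in ascending wavenumber order. Values are
#' transmittance-like intensities on input and unit-less after
#' [preprocess_cube()] (second-derivative spectra are conventionally reported
#' unit-less).
#'
#' Pixel coordinates are `(row, col)` with `row` increasing downwards; all R
#' APIs are 1-based, on-disk rectangle annotations are 0-based half-open (see
#' [read_rectangles()]).
#'
#' @param values numeric 3-D array, `rows x cols x bands`, all finite.
#' @param wavenumbers numeric vector of band centres (cm^-1), strictly
#'   monotonic; length must equal `dim(values)[3]`. Bands are reordered
#'   ascending if supplied descending.
#' @param pixel_size lateral pixel size in micrometres (default 25, the usual
#'   FT-IR imaging step size).
#' @param sample_id character scalar identifying the sample.
#'
#' @return An object of class `spectral_cube`.
#' @export
spectral_cube <- function(values, wavenumbers, pixel_size = 25,
                          sample_id = "sample") {
  values <- as.array(values)
  if (length(dim(values)) != 3L) {
    stop("`values` must be a 3-D array (rows x cols x bands)", call. = FALSE)
  }
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) != dim(values)[3]) {
    stop("band count mismatch: ", length(wavenumbers), " wavenumbers for ",
         dim(values)[3], " bands", call. = FALSE)
  }
  d <- diff(wavenumbers)
  if (length(d) && all(d < 0)) {            # descending: flip to ascending
    ord <- rev(seq_along(wavenumbers))
    wavenumbers <- wavenumbers[ord]
    values <- values[, , ord, drop = FALSE]
    d <- diff(wavenumbers)
  }
  if (length(d) && any(d <= 0)) {
    stop("`wavenumbers` must be strictly monotonic", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("cube values must all be finite", call. = FALSE)
  }
  structure(
    list(values = values, wavenumbers = wavenumbers,
         pixel_size = as.numeric(pixel_size),
         sample_id = as.character(sample_id)),
    class = "spectral_cube"
  )
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<spectral_cube '%s'> %d x %d pixels, %d bands (%.0f-%.0f cm-1), %.0f um/px\n",
    x$sample_id, d[1], d[2], d[3],
    min(x$wavenumbers), max(x$wavenumbers), x$pixel_size))
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$values)

#' Resolve wavenumbers to band indices
#'
#' Nearest-band matching with a tolerance of half the median sampling
#' interval, so a requested band on a 4 cm^-1 grid need not be numerically
#' exact.
#'
#' @param cube a [spectral_cube()].
#' @param wavenumber numeric vector of requested band centres (cm^-1).
#' @return integer vector of band indices into `cube$wavenumbers`.
#' @export
band_index <- function(cube, wavenumber) {
  stopifnot(inherits(cube, "spectral_cube"))
  wn <- cube$wavenumbers
  tol <- if (length(wn) > 1) stats::median(diff(wn)) / 2 else Inf
  vapply(wavenumber, function(w) {
    i <- which.min(abs(wn - w))
    if (abs(wn[i] - w) > tol + 1e-9) {
      stop(sprintf("no band within %.2f cm-1 of requested %.1f cm-1", tol, w),
           call. = FALSE)
    }
    i
  }, integer(1))
}

#' Binary on-tissue pixel mask
#'
#' Wraps a logical matrix (`TRUE` = on-tissue) with the sample dimensions.
#' Most functions also accept a plain logical or 0/1 matrix where a mask is
#' expected.
#'
#' @param values logical or 0/1 numeric matrix.
#' @return logical matrix of class `pixel_mask`.
#' @export
pixel_mask <- function(values) {
  m <- as.matrix(values)
  if (is.numeric(m)) {
    if (!all(m %in% c(0, 1))) stop("mask values must be 0/1", call. = FALSE)
    m <- m > 0
  }
  if (!is.logical(m)) stop("mask must be logical or 0/1", call. = FALSE)
  structure(m, class = c("pixel_mask", "matrix", "array"))
}

as_mask <- function(x) {
  if (inherits(x, "pixel_mask")) return(x)
  pixel_mask(x)
}

#' @export
as.matrix.pixel_mask <- function(x, ...) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' @export
as.matrix.hotspot_map <- function(x, ...) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' Integer tissue-type label map
#'
#' An integer matrix of per-pixel tissue codes plus a legend mapping codes to
#' tissue-type names. Pixels carrying `unlabeled_code` have no pathological
#' annotation and are excluded from training and evaluation.
#'
#' @param values integer matrix of tissue codes.
#' @param legend named character vector: `names(legend)` are the integer codes
#'   (as strings), values the tissue-type names.
#' @param unlabeled_code integer code for unannotated pixels (default 0).
#' @return object of class `label_map`.
#' @export
label_map <- function(values, legend, unlabeled_code = 0L) {
  m <- matrix(as.integer(values), nrow(values), ncol(values))
  codes <- setdiff(sort(unique(as.vector(m))), as.integer(unlabeled_code))
  if (!all(as.character(codes) %in% names(legend))) {
    stop("label codes missing from legend: ",
         paste(setdiff(as.character(codes), names(legend)), collapse = ", "),
         call. = FALSE)
  }
  structure(m, legend = vapply(legend, as.character, character(1)),
            unlabeled_code = as.integer(unlabeled_code),
            class = c("label_map", "matrix", "array"))
}

#' Per-pixel tissue names of a label map
#' @param labels a [label_map()].
#' @return character matrix (NA where unlabeled).
#' @export
label_names <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  legend <- attr(labels, "legend")
  out <- matrix(NA_character_, nrow(labels), ncol(labels))
  for (code in names(legend)) {
    out[labels == as.integer(code)] <- legend[[code]]
  }
  out
}

check_same_shape <- function(a, b, what = "grids") {
  da <- dim(a)[1:2]; db <- dim(b)[1:2]
  if (!identical(da, db)) {
    stop(sprintf("%s dimensions differ: %dx%d vs %dx%d",
                 what, da[1], da[2], db[1], db[2]), call. = FALSE)
  }
  invisible(TRUE)
}
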