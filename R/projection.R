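#' Projection image container
#'
#' Single-plane fusion of a tissue type's discriminant band images: the
#' univariate intensity field that spatial-autocorrelation analysis operates
#' on. Off-mask pixels carry 0 (the no-data value used for zero-padding in
#' cohort stitching) and are excluded from every statistic.
#'
#' @param values numeric matrix.
#' @param mask [pixel_mask()] of the same shape.
#' @param tissue_type tissue-type name.
#' @param baseline baseline offset used during projection (default 10).
#' @param sample_id sample identifier.
#' @return object of class `projection_image`.
#' @export
projection_image <- function(values, mask, tissue_type = "tissue",
                             baseline = 10, sample_id = "sample") {
  values <- as.matrix(values)
  mask <- as_mask(mask)
  check_same_shape(values, mask, "projection/mask")
  values[!mask] <- 0
  structure(list(values = values, mask = mask,
                 tissue_type = as.character(tissue_type),
                 baseline = as.numeric(baseline),
                 sample_id = as.character(sample_id)),
            class = "projection_image")
}

#' @export
print.projection_image <- function(x, ...) {
  cat(sprintf(
    "<projection_image '%s' / %s> %d x %d, %d on-mask px, baseline %g\n",
    x$sample_id, x$tissue_type, nrow(x$values), ncol(x$values),
    sum(x$mask), x$baseline))
  invisible(x)
}

#' Fuse discriminant band images into a projection image
#'
#' Per on-mask pixel `k`:
#' \deqn{P_k = \mathrm{baseline} + \sum_i T_k^i - \sum_j T_k^j}
#' where `i` runs over the positive predictive bands (ppf, intensity higher in
#' the tissue type of interest) and `j` over the negative predictive bands
#' (npf). The baseline offset (+10 by default) keeps typical values positive;
#' negative results are nevertheless permitted — the downstream statistics
#' use relative intensities, and clipping would distort the distribution.
#'
#' @param cube a preprocessed [spectral_cube()].
#' @param features a [discriminant_features()] object (or a data frame with
#'   columns `wavenumber` and `direction` in `{"ppf", "npf"}`).
#' @param mask on-tissue [pixel_mask()].
#' @param baseline baseline offset, default 10.
#' @return a [projection_image()].
#' @export
project_image <- function(cube, features, mask, baseline = 10) {
  stopifnot(inherits(cube, "spectral_cube"))
  feats <- if (inherits(features, "discriminant_features")) features$features
           else tibble::as_tibble(features)
  if (!all(c("wavenumber", "direction") %in% names(feats))) {
    stop("`features` needs columns wavenumber and direction", call. = FALSE)
  }
  if (!nrow(feats)) stop("empty feature set", call. = FALSE)
  if (!all(feats$direction %in% c("ppf", "npf"))) {
    stop("feature direction must be 'ppf' or 'npf'", call. = FALSE)
  }
  idx <- band_index(cube, feats$wavenumber)   # errors on unresolvable bands
  sign <- ifelse(feats$direction == "ppf", 1, -1)
  d <- dim(cube$values)
  P <- matrix(baseline, d[1], d[2])
  for (f in seq_along(idx)) {
    P <- P + sign[f] * cube$values[, , idx[f]]
  }
  tissue <- if (inherits(features, "discriminant_features"))
    features$tissue_type else "tissue"
  projection_image(P, mask, tissue, baseline, cube$sample_id)
}

#' Write / read a projection image (32-bit float TIFF + JSON sidecar)
#'
#' @param proj a [projection_image()].
#' @param path TIFF output path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_projection <- function(proj, path) {
  stopifnot(inherits(proj, "projection_image"))
  # TIFF float samples are stored on [0, 1]; keep the affine map in the sidecar
  rng <- range(proj$values)
  span <- if (diff(rng) > 0) diff(rng) else 1
  tiff::writeTIFF((proj$values - rng[1]) / span, path,
                  bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(tissue_type = proj$tissue_type, baseline = proj$baseline,
         sample_id = proj$sample_id, mask = which(proj$mask),
         value_range = rng),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_projection
#' @export
read_projection <- function(path) {
  v <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  rng <- meta$value_range
  span <- if (diff(rng) > 0) diff(rng) else 1
  v <- v * span + rng[1]
  mask <- matrix(FALSE, nrow(v), ncol(v))
  mask[meta$mask] <- TRUE
  projection_image(v, mask, meta$tissue_type, meta$baseline, meta$sample_id)
}
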