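# Spectral preprocessing: background normalization, smoothed 2nd derivative
# (Savitzky-Golay), SNV; plus k-means tissue masking.

# run code under a temporary RNG state so seeded helpers do not disturb the
# caller's stream
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# dense Savitzky-Golay differentiation operator: deriv = X %*% t(sg_op(...))
# edge rows use the sgolay edge filters, exactly as signal::sgolayfilt does
sg_op <- function(n_bands, window, polyorder, ts, m = 2) {
  F <- signal::sgolay(p = polyorder, n = window, m = m, ts = ts)
  F <- unclass(F)
  k <- (window - 1L) / 2L
  D <- matrix(0, n_bands, n_bands)
  for (i in seq_len(k)) D[i, 1:window] <- F[i, ]
  centre <- F[k + 1L, ]
  for (t in (k + 1L):(n_bands - k)) D[t, (t - k):(t + k)] <- centre
  for (i in seq_len(k)) {
    D[n_bands - k + i, (n_bands - window + 1L):n_bands] <- F[k + 1L + i, ]
  }
  D
}

#' Preprocess a spectral cube
#'
#' Standard MIR pipeline applied per pixel along the spectral axis:
#' 1. background normalization — divide by a reference background spectrum if
#'    one is supplied (skipped with a notice otherwise);
#' 2. smoothed second derivative (Savitzky-Golay, window `deriv_window`,
#'    polynomial order `deriv_polyorder`, differentiation step = the cube's
#'    wavenumber spacing);
#' 3. standard normal variate (SNV): per-pixel spectral mean subtracted,
#'    divided by the per-pixel spectral standard deviation.
#'
#' The output is unit-less. Pixels whose spectrum has zero standard deviation
#' after differentiation (e.g. constant spectra) cannot be SNV-scaled; they
#' are zeroed, flagged in `$flagged`, and a warning is raised so callers can
#' drop them from the tissue mask.
#'
#' @param cube a [spectral_cube()].
#' @param background optional numeric vector (one value per band) to divide
#'   out before differentiation.
#' @param deriv_window odd Savitzky-Golay window length (bands), default 9.
#' @param deriv_polyorder polynomial order, default 3; requires
#'   `deriv_window >= deriv_polyorder + 2`.
#' @return a [spectral_cube()] with unit-less values and an extra logical
#'   matrix element `$flagged` marking degenerate pixels.
#' @export
preprocess_cube <- function(cube, background = NULL, deriv_window = 9,
                            deriv_polyorder = 3) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$values)
  if (deriv_window %% 2 != 1) stop("`deriv_window` must be odd", call. = FALSE)
  if (deriv_window < deriv_polyorder + 2) {
    stop("`deriv_window` must be >= deriv_polyorder + 2", call. = FALSE)
  }
  if (d[3] < deriv_window) {
    stop("cube has fewer bands than `deriv_window`", call. = FALSE)
  }
  X <- matrix(cube$values, nrow = d[1] * d[2], ncol = d[3])
  if (!is.null(background)) {
    background <- as.numeric(background)
    if (length(background) != d[3]) {
      stop("`background` must have one value per band", call. = FALSE)
    }
    if (any(background == 0)) {
      stop("`background` contains zeros", call. = FALSE)
    }
    X <- sweep(X, 2, background, "/")
  } else {
    message("no background spectrum supplied; background normalization skipped")
  }
  ts <- stats::median(diff(cube$wavenumbers))
  D <- sg_op(d[3], as.integer(deriv_window), as.integer(deriv_polyorder), ts)
  X <- X %*% t(D)
  mu <- rowMeans(X)
  sdv <- sqrt(rowMeans((X - mu)^2) * d[3] / (d[3] - 1))
  bad <- sdv <= .Machine$double.eps * 100
  if (any(bad)) {
    warning(sum(bad), " pixel(s) with zero spectral standard deviation ",
            "flagged and zeroed", call. = FALSE)
    sdv[bad] <- 1
  }
  X <- (X - mu) / sdv
  X[bad, ] <- 0
  out <- spectral_cube(array(X, d), cube$wavenumbers, cube$pixel_size,
                       cube$sample_id)
  out$flagged <- matrix(bad, d[1], d[2])
  out
}

#' k-means tissue mask from a single band image
#'
#' Partitions the intensities of one band (default 1552 cm^-1, an amide-region
#' band with strong tissue contrast) into two clusters with k-means (k = 2)
#' and labels the tissue cluster 1. With `polarity = "high"` (default,
#' absorbance-like data) the cluster with the higher mean intensity is
#' tissue; `"low"` flips this for transmittance-like data.
#'
#' @param cube a [spectral_cube()] (raw data, before differentiation).
#' @param mask_band wavenumber (cm^-1) of the band to cluster, default 1552.
#' @param seed integer seed making the clustering deterministic.
#' @param polarity `"high"` or `"low"`: which intensity cluster is tissue.
#' @return a [pixel_mask()].
#' @export
make_tissue_mask <- function(cube, mask_band = 1552, seed = 1L,
                             polarity = c("high", "low")) {
  stopifnot(inherits(cube, "spectral_cube"))
  polarity <- match.arg(polarity)
  b <- band_index(cube, mask_band)
  img <- cube$values[, , b]
  v <- as.vector(img)
  if (diff(range(v)) == 0) {
    stop("degenerate clustering: all pixel intensities identical",
         call. = FALSE)
  }
  km <- with_local_seed(seed, stats::kmeans(v, centers = 2, nstart = 5))
  tissue_cluster <- if (polarity == "high") which.max(km$centers) else
    which.min(km$centers)
  pixel_mask(matrix(km$cluster == tissue_cluster, nrow(img), ncol(img)))
}
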