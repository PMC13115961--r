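#' Queen-contiguity spatial weights on a masked pixel grid
#'
#' Each on-tissue pixel is linked to its up-to-eight queen neighbours (edge or
#' corner adjacency); neighbours falling off the mask are dropped and the
#' remaining weights row-standardized (each neighbour weighted `1/k`).
#' Pixels whose entire neighbourhood is off-mask are flagged isolated: they
#' remain observations (they enter the global mean and variance) but receive
#' no local statistic.
#'
#' @param mask a [pixel_mask()] or logical matrix, at least one `TRUE` pixel.
#' @param style `"W"` row-standardized (default) or `"B"` binary weights.
#' @return object of class `spatial_weights`: neighbour index lists
#'   (positions in on-mask ordering), matching weight lists, the on-mask
#'   linear pixel indices, and an `isolated` flag vector.
#' @export
build_weights <- function(mask, style = c("W", "B")) {
  mask <- as_mask(mask)
  style <- match.arg(style)
  if (!any(mask)) stop("mask has no on-tissue pixels", call. = FALSE)
  nr <- nrow(mask); nc <- ncol(mask)
  pos <- matrix(NA_integer_, nr, nc)      # on-mask ordinal per pixel
  on <- which(mask)                       # column-major linear indices
  pos[on] <- seq_along(on)
  rows <- ((on - 1L) %% nr) + 1L
  cols <- ((on - 1L) %/% nr) + 1L
  offsets <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                   dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  nb_mat <- matrix(NA_integer_, length(on), 8L)
  for (o in seq_len(8L)) {
    rr <- rows + offsets[o, 1L]; cc <- cols + offsets[o, 2L]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    lin <- (cc[ok] - 1L) * nr + rr[ok]
    nb_mat[ok, o] <- pos[lin]             # NA when neighbour is off-mask
  }
  neighbors <- apply(nb_mat, 1L, function(x) x[!is.na(x)], simplify = FALSE)
  weights <- lapply(neighbors, function(nb) {
    k <- length(nb)
    if (k == 0L) numeric(0)
    else if (style == "W") rep(1 / k, k)
    else rep(1, k)
  })
  structure(
    list(neighbors = neighbors, weights = weights,
         index = on, isolated = lengths(neighbors) == 0L,
         dim = c(nr, nc), style = style),
    class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("<spatial_weights> %d on-mask pixels (%d isolated), queen, style %s\n",
              length(x$index), sum(x$isolated), x$style))
  invisible(x)
}
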