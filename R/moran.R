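#' Local Moran's I with conditional permutation inference
#'
#' For each on-mask pixel `i`, the local Moran statistic
#' \deqn{I_i = \frac{z_i}{m_2} \sum_j W_{ij} z_j, \qquad
#'       z_i = x_i - \bar x, \quad m_2 = \frac{1}{n}\sum_k z_k^2}
#' measures agreement between the pixel's deviation from the global mean and
#' its neighbourhood's deviation. Significance is assessed by conditional
#' permutation: the focal value is held fixed while its neighbour values are
#' drawn without replacement from all other on-mask observations, `n_perm`
#' times; the one-sided pseudo p-value is
#' `(count{I_perm >= I_obs} + 1) / (n_perm + 1)` for `I_obs >= 0` (mirrored
#' for negative observed values), so `p >= 1/(n_perm+1)` always.
#'
#' Each pixel's permutation stream is derived from the master `seed`, the
#' focal deviation's value and the neighbour count, and draws index into the
#' sorted pool of all other on-mask deviations: results are reproducible,
#' independent of traversal order, and exactly invariant when image and mask
#' are translated together or stitched at a different position of a super
#' image. Isolated pixels (no on-mask neighbours) contribute to the
#' global mean and variance but receive no statistic.
#'
#' @param x a [projection_image()], or a numeric matrix.
#' @param mask mask to use when `x` is a plain matrix (defaults to the
#'   projection's mask, or all-on).
#' @param weights optional precomputed [build_weights()] result; built from
#'   the mask otherwise.
#' @param n_perm number of conditional permutations (default 999).
#' @param seed integer master seed for the permutation streams.
#' @return object of class `moran_result` with matrices `observed_I`,
#'   `pseudo_p`, `lag`, and `quadrant` (`"HH"`, `"HL"`, `"LH"`, `"LL"`,
#'   `"isolated"`; `NA` off-mask), plus `global_mean`, `m2`, `n_used`,
#'   `n_perm`, `seed`, `mask`, `sample_id`.
#' @references Anselin, L. (1995) Local indicators of spatial association —
#'   LISA. Geographical Analysis 27:93-115.
#' @export
local_moran <- function(x, mask = NULL, weights = NULL, n_perm = 999,
                        seed = 1L) {
  if (inherits(x, "projection_image")) {
    values <- x$values
    if (is.null(mask)) mask <- x$mask
    sample_id <- x$sample_id
  } else {
    values <- as.matrix(x)
    sample_id <- "image"
  }
  if (is.null(mask)) mask <- pixel_mask(matrix(TRUE, nrow(values), ncol(values)))
  mask <- as_mask(mask)
  check_same_shape(values, mask, "values/mask")
  if (n_perm < 99) stop("`n_perm` must be >= 99", call. = FALSE)
  if (is.null(weights)) weights <- build_weights(mask)
  on <- weights$index
  xv <- values[on]
  n <- length(xv)
  if (length(unique(xv)) < 2L) {
    stop("degenerate input: fewer than 2 distinct on-mask values",
         call. = FALSE)
  }
  xbar <- mean(xv)
  z <- xv - xbar
  m2 <- mean(z^2)
  lag <- vapply(seq_len(n), function(i) {
    nb <- weights$neighbors[[i]]
    if (!length(nb)) return(NA_real_)
    sum(weights$weights[[i]] * z[nb])
  }, numeric(1))
  I_obs <- (z / m2) * lag
  p <- moran_perm_p(z, m2, weights$weights, I_obs,
                    as.integer(n_perm), as.numeric(seed))
  quad <- rep(NA_character_, n)
  quad[!weights$isolated] <- ifelse(
    z[!weights$isolated] > 0,
    ifelse(lag[!weights$isolated] > 0, "HH", "HL"),
    ifelse(lag[!weights$isolated] > 0, "LH", "LL"))
  quad[weights$isolated] <- "isolated"

  shape <- dim(values)
  to_grid <- function(v, init) {
    g <- matrix(init, shape[1], shape[2])
    g[on] <- v
    g
  }
  structure(
    list(observed_I = to_grid(I_obs, NA_real_),
         pseudo_p = to_grid(p, NA_real_),
         lag = to_grid(lag, NA_real_),
         quadrant = to_grid(quad, NA_character_),
         global_mean = xbar, m2 = m2, n_used = n,
         n_perm = as.integer(n_perm), seed = as.integer(seed),
         mask = mask, sample_id = sample_id),
    class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf(
    "<moran_result '%s'> %d on-mask pixels, %d permutations, seed %d\n",
    x$sample_id, x$n_used, x$n_perm, x$seed))
  cat(sprintf("  global mean %.4g, m2 %.4g; quadrants: %s\n",
              x$global_mean, x$m2,
              paste(names(table(x$quadrant)), table(x$quadrant),
                    sep = "=", collapse = " ")))
  invisible(x)
}

new_hotspot_map <- function(values, alpha, res, kind = "hotspot") {
  structure(values,
            alpha = alpha, n_perm = res$n_perm, seed = res$seed,
            global_mean = res$global_mean, sample_id = res$sample_id,
            kind = kind,
            class = c("hotspot_map", "matrix", "array"))
}

#' Threshold a Moran result into a binary hotspot map
#'
#' A hotspot pixel is significant at `alpha` *and* lies in the high-high
#' quadrant (high value in a high-value neighbourhood); significant low-low /
#' discordant pixels are not hotspots. Re-thresholding reuses the stored
#' p-value grid; no permutations are recomputed.
#'
#' @param res a [local_moran()] result.
#' @param alpha confidence level in (0, 1], default 0.01.
#' @return logical matrix of class `hotspot_map` (attributes: `alpha`,
#'   `n_perm`, `seed`, `global_mean`, `sample_id`).
#' @export
threshold_hotspots <- function(res, alpha = 0.01) {
  stopifnot(inherits(res, "moran_result"), alpha > 0, alpha <= 1)
  hs <- !is.na(res$pseudo_p) & res$pseudo_p <= alpha &
    !is.na(res$quadrant) & res$quadrant == "HH"
  new_hotspot_map(hs, alpha, res, "hotspot")
}

#' Threshold a Moran result into a coldspot map (significant low-low)
#'
#' Exposed for completeness; the annotation workflow itself uses hotspots of
#' high projection intensity only.
#'
#' @inheritParams threshold_hotspots
#' @return logical matrix of class `hotspot_map` with `kind = "coldspot"`.
#' @export
threshold_coldspots <- function(res, alpha = 0.01) {
  stopifnot(inherits(res, "moran_result"), alpha > 0, alpha <= 1)
  cs <- !is.na(res$pseudo_p) & res$pseudo_p <= alpha &
    !is.na(res$quadrant) & res$quadrant == "LL"
  new_hotspot_map(cs, alpha, res, "coldspot")
}

#' @export
print.hotspot_map <- function(x, ...) {
  cat(sprintf("<%s_map '%s'> %d x %d, %d positive px, alpha %.4g\n",
              attr(x, "kind"), attr(x, "sample_id"), nrow(x), ncol(x),
              sum(x), attr(x, "alpha")))
  invisible(x)
}

#' Overlay per-tissue hotspot maps into a multi-label annotation
#'
#' Pixels claimed by exactly one tissue map receive that tissue's name;
#' pixels claimed by several maps are flagged `"multiple"` (annotation
#' uncertainty at tissue borders), on-mask pixels claimed by none are
#' `"none"`; off-mask pixels are `NA`.
#'
#' @param maps named list of same-shape [threshold_hotspots()] maps, one per
#'   tissue type.
#' @param mask optional on-tissue mask; default all-on.
#' @return object of class `sa_overlay`: list with `label` (character
#'   matrix), `count` (integer matrix of claims), and `tissues`.
#' @export
overlay_maps <- function(maps, mask = NULL) {
  stopifnot(is.list(maps), length(maps) >= 1L)
  if (is.null(names(maps)) || any(names(maps) == "")) {
    stop("`maps` must be a named list (tissue types)", call. = FALSE)
  }
  shape <- dim(maps[[1]])
  for (m in maps) {
    if (!identical(dim(m), shape)) {
      stop("hotspot maps have mismatching dimensions", call. = FALSE)
    }
  }
  if (is.null(mask)) mask <- matrix(TRUE, shape[1], shape[2])
  mask <- as_mask(mask)
  check_same_shape(maps[[1]], mask, "map/mask")
  count <- Reduce(`+`, lapply(maps, function(m) matrix(as.integer(m), shape[1])))
  label <- matrix("none", shape[1], shape[2])
  for (tt in names(maps)) label[maps[[tt]] & count == 1L] <- tt
  label[count > 1L] <- "multiple"
  label[!mask] <- NA_character_
  count[!mask] <- NA_integer_
  structure(list(label = label, count = count, tissues = names(maps),
                 mask = mask),
            class = "sa_overlay")
}

#' @export
print.sa_overlay <- function(x, ...) {
  tab <- table(x$label[x$mask])
  cat("<sa_overlay> assignments:",
      paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Intersection over union of two binary maps
#'
#' `IoU = |A intersect B| / |A union B|`; two empty maps agree perfectly
#' (IoU 1).
#'
#' @param a,b logical matrices of equal shape.
#' @return scalar in `[0, 1]`.
#' @export
iou <- function(a, b) {
  check_same_shape(a, b, "maps")
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
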