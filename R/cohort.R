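# Interdependent SA: super-image stitching, cohort-wide processing, hotspot
# database and reference-based calibration.

#' Stitch projection images into a cohort "super image"
#'
#' Every projection is zero-padded to the common tile size and the tiles laid
#' out in a near-square grid separated by a one-pixel zero-padding gutter
#' (queen contiguity therefore never crosses samples). The combined mask
#' contains on-tissue pixels only, so padding is excluded from every moment
#' and from the permutation pool.
#'
#' @param projections list of [projection_image()] of one tissue type.
#' @return object of class `super_image`: `values`, `mask`, `tile_index`
#'   (integer grid, 0 = padding), `layout` tibble (`sample_id`, offsets and
#'   original extents) and `tissue_type`.
#' @export
stitch_projections <- function(projections) {
  if (!length(projections)) stop("empty projection list", call. = FALSE)
  stopifnot(all(vapply(projections, inherits, logical(1), "projection_image")))
  tt <- unique(vapply(projections, `[[`, character(1), "tissue_type"))
  if (length(tt) > 1L) {
    stop("projections mix tissue types: ", paste(tt, collapse = ", "),
         call. = FALSE)
  }
  ids <- vapply(projections, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample_ids", call. = FALSE)
  n <- length(projections)
  hs <- vapply(projections, function(p) nrow(p$values), integer(1))
  ws <- vapply(projections, function(p) ncol(p$values), integer(1))
  tile_h <- max(hs); tile_w <- max(ws)
  grid_c <- ceiling(sqrt(n)); grid_r <- ceiling(n / grid_c)
  H <- grid_r * tile_h + (grid_r - 1L)
  W <- grid_c * tile_w + (grid_c - 1L)
  values <- matrix(0, H, W)
  mask <- matrix(FALSE, H, W)
  tile_index <- matrix(0L, H, W)
  layout <- vector("list", n)
  for (s in seq_len(n)) {
    gr <- (s - 1L) %/% grid_c; gc <- (s - 1L) %% grid_c
    r0 <- gr * (tile_h + 1L) + 1L; c0 <- gc * (tile_w + 1L) + 1L
    p <- projections[[s]]
    rr <- r0:(r0 + nrow(p$values) - 1L); cc <- c0:(c0 + ncol(p$values) - 1L)
    values[rr, cc] <- p$values
    mask[rr, cc] <- p$mask
    sub <- tile_index[rr, cc]
    sub[as.matrix(p$mask)] <- s
    tile_index[rr, cc] <- sub
    layout[[s]] <- tibble::tibble(
      sample_id = p$sample_id, row_off = r0, col_off = c0,
      height = nrow(p$values), width = ncol(p$values))
  }
  structure(
    list(values = values, mask = pixel_mask(mask), tile_index = tile_index,
         layout = dplyr::bind_rows(layout), tissue_type = tt,
         sample_ids = ids),
    class = "super_image")
}

#' @export
print.super_image <- function(x, ...) {
  cat(sprintf("<super_image / %s> %d samples, %d x %d, %d on-mask px\n",
              x$tissue_type, nrow(x$layout), nrow(x$values), ncol(x$values),
              sum(x$mask)))
  invisible(x)
}

# crop a per-sample grid back out of a super-image-shaped grid
crop_tile <- function(grid, layout_row) {
  rr <- layout_row$row_off:(layout_row$row_off + layout_row$height - 1L)
  cc <- layout_row$col_off:(layout_row$col_off + layout_row$width - 1L)
  grid[rr, cc, drop = FALSE]
}

#' Disassemble a super-image-shaped grid into per-sample grids
#'
#' @param super a [stitch_projections()] result.
#' @param grid a matrix with the super image's dimensions (defaults to its
#'   values).
#' @return named list of per-sample matrices at their original extents.
#' @export
disassemble <- function(super, grid = super$values) {
  stopifnot(inherits(super, "super_image"))
  check_same_shape(grid, super$values, "grid/super")
  out <- lapply(seq_len(nrow(super$layout)), function(s) {
    crop_tile(grid, super$layout[s, ])
  })
  stats::setNames(out, super$sample_ids)
}

# per-sample moran_result views + hotspot maps from a super-image run
split_super_result <- function(super, res, alpha) {
  per <- lapply(seq_len(nrow(super$layout)), function(s) {
    lr <- super$layout[s, ]
    sub <- list(observed_I = crop_tile(res$observed_I, lr),
                pseudo_p = crop_tile(res$pseudo_p, lr),
                lag = crop_tile(res$lag, lr),
                quadrant = crop_tile(res$quadrant, lr),
                global_mean = res$global_mean, m2 = res$m2,
                n_used = res$n_used, n_perm = res$n_perm, seed = res$seed,
                mask = pixel_mask(crop_tile(as.matrix(super$mask), lr)),
                sample_id = lr$sample_id)
    class(sub) <- "moran_result"
    sub
  })
  names(per) <- super$sample_ids
  maps <- lapply(per, threshold_hotspots, alpha = alpha)
  list(moran = per, maps = maps)
}

#' Cohort-wide spatial autocorrelation
#'
#' Runs [local_moran()] once on the stitched super image, so the global mean,
#' the variance and the conditional-permutation pool span the on-tissue
#' pixels of *all* samples, then disassembles the result per sample. A
#' homogeneous low-intensity control therefore stops generating spurious
#' within-sample hotspots: its pixels sit below the cohort-wide mean.
#'
#' @param projections list of [projection_image()] (same tissue type).
#' @param alpha hotspot confidence level (default 0.01).
#' @param n_perm conditional permutations (default 999).
#' @param seed master seed.
#' @return object of class `cohort_sa`: `super`, the super-image
#'   `moran_result` (`$super_result`), per-sample `$moran` and hotspot
#'   `$maps`, and the parameters.
#' @export
cohort_sa <- function(projections, alpha = 0.01, n_perm = 999, seed = 1L) {
  super <- stitch_projections(projections)
  res <- local_moran(super$values, mask = super$mask, n_perm = n_perm,
                     seed = seed)
  res$sample_id <- "super_image"
  parts <- split_super_result(super, res, alpha)
  structure(
    list(super = super, super_result = res, moran = parts$moran,
         maps = parts$maps, alpha = alpha, n_perm = as.integer(n_perm),
         seed = as.integer(seed)),
    class = "cohort_sa")
}

#' @export
print.cohort_sa <- function(x, ...) {
  cat(sprintf("<cohort_sa> %d samples, alpha %.4g, %d permutations\n",
              length(x$maps), x$alpha, x$n_perm))
  invisible(x)
}

#' Build a hotspot database by cohort-wide processing
#'
#' Stores, per sample: the full Moran result (p-value grids included, so
#' later calibration re-thresholds without recomputation), the hotspot map at
#' `alpha`, the projection itself, the on-tissue area and the
#' hotspot-to-total-tissue-area ratio that drives reference selection.
#'
#' @inheritParams cohort_sa
#' @return object of class `hotspot_db`.
#' @export
build_database <- function(projections, alpha = 0.01, n_perm = 999,
                           seed = 1L) {
  cs <- cohort_sa(projections, alpha, n_perm, seed)
  ids <- cs$super$sample_ids
  samples <- lapply(seq_along(ids), function(s) {
    map <- cs$maps[[s]]
    area <- sum(cs$moran[[s]]$mask)
    list(projection = projections[[s]], moran = cs$moran[[s]], map = map,
         area = area, ratio = sum(map) / area)
  })
  names(samples) <- ids
  ratios <- tibble::tibble(
    sample_id = ids,
    area = unname(vapply(samples, `[[`, numeric(1), "area")),
    hotspot_px = unname(vapply(samples, function(s) sum(s$map), numeric(1))),
    ratio = unname(vapply(samples, `[[`, numeric(1), "ratio")))
  structure(
    list(samples = samples, ratios = ratios, alpha_db = alpha,
         n_perm = as.integer(n_perm), seed = as.integer(seed),
         tissue_type = cs$super$tissue_type),
    class = "hotspot_db")
}

#' @export
print.hotspot_db <- function(x, ...) {
  cat(sprintf("<hotspot_db / %s> %d samples, alpha_db %.4g\n",
              x$tissue_type, nrow(x$ratios), x$alpha_db))
  print(x$ratios)
  invisible(x)
}

#' Pick reference samples by hotspot-to-tissue-area ratio
#'
#' The default two references are the database samples with the lowest and
#' the highest ratio (the low-high combination); larger `n_refs` alternate
#' outward-in (lowest, highest, second lowest, ...). Ties are broken by
#' `sample_id` order.
#'
#' @param db a [build_database()] result.
#' @param n_refs number of references (default 2).
#' @return character vector of sample ids.
#' @export
pick_references <- function(db, n_refs = 2L) {
  stopifnot(inherits(db, "hotspot_db"))
  if (n_refs > nrow(db$ratios)) {
    stop("n_refs exceeds database size", call. = FALSE)
  }
  r <- db$ratios[order(db$ratios$ratio, db$ratios$sample_id), ]
  ids <- r$sample_id
  lo <- 1L; hi <- length(ids); out <- character(0)
  for (k in seq_len(n_refs)) {
    if (k %% 2L == 1L) { out <- c(out, ids[lo]); lo <- lo + 1L }
    else { out <- c(out, ids[hi]); hi <- hi - 1L }
  }
  out
}

#' Reference-based spatial autocorrelation for a new sample
#'
#' The new sample is stitched with the reference samples (by default the
#' database's low/high ratio pair) and SA is run once on that small group;
#' the group's moments and permutation pool are *not* inherited from the
#' database. The significance level is then calibrated: for every `alpha` on
#' the grid `[alpha_min, alpha_max]` (step `alpha_step`) the references'
#' p-value grids from the group run are thresholded and compared to their
#' database hotspot maps by intersection over union, and
#' \deqn{\alpha^* = \arg\max_\alpha \frac{1}{m}\sum_{i=1}^m
#'       IoU(R_i, \hat R_i(\alpha))}
#' (ties resolved to the smallest alpha). The new sample's hotspot map is its
#' group p-value grid thresholded at `alpha_star`. `mode = "mean_argmax"`
#' instead maximises each reference separately and uses the mean of the two
#' per-reference optima.
#'
#' The default `n_perm` is raised to 1999 so the pseudo-p granularity
#' `1/(n_perm+1)` matches the 0.0005 alpha step.
#'
#' @param new_projection [projection_image()] of the sample to annotate.
#' @param db a [build_database()] result.
#' @param alpha_min,alpha_max,alpha_step calibration grid (defaults 0.0005,
#'   0.5, 0.0005 — 1000 levels).
#' @param n_perm permutations for the group run (default 1999).
#' @param seed master seed.
#' @param n_refs number of references (default 2).
#' @param mode `"argmax_mean"` (default) or `"mean_argmax"`.
#' @return object of class `sa_calibration`: `alpha_star`, `iou_curve`
#'   tibble, `references`, the new sample's `new_map` and `new_moran`, and
#'   the per-reference group maps at `alpha_star`.
#' @export
reference_sa <- function(new_projection, db,
                         alpha_min = 0.0005, alpha_max = 0.5,
                         alpha_step = 0.0005, n_perm = 1999, seed = 1L,
                         n_refs = 2L, mode = c("argmax_mean", "mean_argmax")) {
  stopifnot(inherits(new_projection, "projection_image"),
            inherits(db, "hotspot_db"))
  mode <- match.arg(mode)
  if (nrow(db$ratios) < 2L) stop("database needs >= 2 entries", call. = FALSE)
  refs <- pick_references(db, n_refs)
  if (new_projection$sample_id %in% refs) {
    stop("the new sample duplicates reference '", new_projection$sample_id,
         "'; rename it or pick other references", call. = FALSE)
  }
  if (all(vapply(refs, function(id) sum(db$samples[[id]]$map) == 0,
                 logical(1)))) {
    stop("calibration degenerate: all reference hotspot maps in the ",
         "database are empty", call. = FALSE)
  }
  group <- c(list(new_projection),
             lapply(refs, function(id) db$samples[[id]]$projection))
  super <- stitch_projections(group)
  res <- local_moran(super$values, mask = super$mask, n_perm = n_perm,
                     seed = seed)
  alphas <- seq(alpha_min, alpha_max, by = alpha_step)
  parts <- split_super_result(super, res, alpha = db$alpha_db)
  ref_moran <- parts$moran[refs]
  # IoU of every grid alpha against the database maps (pure re-thresholding)
  iou_mat <- vapply(refs, function(id) {
    rm_ <- ref_moran[[id]]
    db_map <- db$samples[[id]]$map
    sig_hh <- !is.na(rm_$pseudo_p) & !is.na(rm_$quadrant) &
      rm_$quadrant == "HH"
    p <- rm_$pseudo_p
    vapply(alphas, function(a) iou(sig_hh & !is.na(p) & p <= a, db_map),
           numeric(1))
  }, numeric(length(alphas)))
  iou_mat <- matrix(iou_mat, nrow = length(alphas))
  mean_iou <- rowMeans(iou_mat)
  if (mode == "argmax_mean") {
    alpha_star <- alphas[which.max(mean_iou)]   # first max = smallest alpha
  } else {
    per_ref <- vapply(seq_along(refs),
                      function(j) alphas[which.max(iou_mat[, j])], numeric(1))
    alpha_star <- mean(per_ref)
  }
  new_moran <- parts$moran[[new_projection$sample_id]]
  new_map <- threshold_hotspots(new_moran, alpha_star)
  iou_curve <- tibble::tibble(alpha = alphas, mean_iou = mean_iou)
  for (j in seq_along(refs)) iou_curve[[paste0("iou_", refs[j])]] <- iou_mat[, j]
  structure(
    list(alpha_star = alpha_star, iou_curve = iou_curve, references = refs,
         new_map = new_map, new_moran = new_moran,
         ref_maps = lapply(ref_moran, threshold_hotspots, alpha = alpha_star),
         alpha_db = db$alpha_db, n_perm = as.integer(n_perm),
         seed = as.integer(seed), mode = mode),
    class = "sa_calibration")
}

#' @export
print.sa_calibration <- function(x, ...) {
  cat(sprintf(
    "<sa_calibration> alpha* = %.4f (db alpha %.4f), refs: %s, mode %s\n",
    x$alpha_star, x$alpha_db, paste(x$references, collapse = ", "), x$mode))
  cat(sprintf("  mean IoU at alpha*: %.3f\n", max(x$iou_curve$mean_iou)))
  invisible(x)
}

#' Persist / load a hotspot database
#'
#' Directory layout: `manifest.json` (ids, alpha_db, n_perm, seed, ratios)
#' plus per-sample p-grid/quadrant/value text matrices and hotspot-map PNGs,
#' so calibration can re-threshold without recomputation.
#'
#' @param db a [build_database()] result.
#' @param dir output directory.
#' @return `dir` invisibly; [read_database()] returns the `hotspot_db`.
#' @export
write_database <- function(db, dir) {
  stopifnot(inherits(db, "hotspot_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(sample_ids = names(db$samples), alpha_db = db$alpha_db,
         n_perm = db$n_perm, seed = db$seed, tissue_type = db$tissue_type,
         ratios = db$ratios),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  for (id in names(db$samples)) {
    s <- db$samples[[id]]
    base <- file.path(dir, id)
    utils::write.table(s$projection$values, paste0(base, "_projection.txt"),
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(s$moran$pseudo_p, paste0(base, "_p.txt"),
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(s$moran$observed_I, paste0(base, "_I.txt"),
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(s$moran$quadrant, paste0(base, "_quadrant.txt"),
                       row.names = FALSE, col.names = FALSE)
    write_mask(s$projection$mask, paste0(base, "_mask.png"))
    write_mask(pixel_mask(matrix(as.logical(s$map), nrow(s$map))),
               paste0(base, "_hotspots.png"))
    jsonlite::write_json(
      list(global_mean = s$moran$global_mean, m2 = s$moran$m2,
           n_used = s$moran$n_used, baseline = s$projection$baseline),
      paste0(base, "_meta.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_database
#' @export
read_database <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  read_mat <- function(f, mode = "numeric") {
    m <- as.matrix(utils::read.table(f, header = FALSE,
                                     colClasses = mode,
                                     stringsAsFactors = FALSE))
    dimnames(m) <- NULL
    m
  }
  samples <- lapply(man$sample_ids, function(id) {
    base <- file.path(dir, id)
    meta <- jsonlite::read_json(paste0(base, "_meta.json"),
                                simplifyVector = TRUE)
    mask <- read_mask(paste0(base, "_mask.png"))
    proj <- projection_image(read_mat(paste0(base, "_projection.txt")), mask,
                             man$tissue_type, meta$baseline, id)
    quad <- read_mat(paste0(base, "_quadrant.txt"), "character")
    moran <- structure(
      list(observed_I = read_mat(paste0(base, "_I.txt")),
           pseudo_p = read_mat(paste0(base, "_p.txt")),
           lag = NULL, quadrant = quad,
           global_mean = meta$global_mean, m2 = meta$m2,
           n_used = meta$n_used, n_perm = man$n_perm, seed = man$seed,
           mask = mask, sample_id = id),
      class = "moran_result")
    map <- new_hotspot_map(as.matrix(read_mask(paste0(base, "_hotspots.png"))),
                           man$alpha_db, moran)
    list(projection = proj, moran = moran, map = map,
         area = sum(mask), ratio = sum(map) / sum(mask))
  })
  names(samples) <- man$sample_ids
  structure(
    list(samples = samples, ratios = tibble::as_tibble(man$ratios),
         alpha_db = man$alpha_db, n_perm = as.integer(man$n_perm),
         seed = as.integer(man$seed), tissue_type = man$tissue_type),
    class = "hotspot_db")
}
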