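mk_proj <- function(v, mask = NULL, id = "s1", tissue = "tumor") {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(v), ncol(v))
  projection_image(v, mask, tissue, 10, id)
}

test_that("stitching conserves pixels, pads with gutters, and round-trips", {
  set.seed(2)
  p1 <- mk_proj(matrix(rnorm(25) + 10, 5, 5), id = "a")
  p2 <- mk_proj(matrix(rnorm(25) + 10, 5, 5),
                mask = matrix(runif(25) > 0.2, 5, 5), id = "b")
  sup <- stitch_projections(list(p1, p2))
  expect_equal(sum(sup$mask), sum(p1$mask) + sum(p2$mask))
  # gutter: tiles are separated, queen contiguity cannot cross
  expect_equal(ncol(sup$values), 5 + 1 + 5)
  expect_true(all(sup$values[, 6] == 0) || all(sup$mask[, 6] == FALSE))
  parts <- disassemble(sup)
  expect_equal(parts$a, p1$values)
  expect_equal(parts$b, p2$values)
  # unequal tiles are zero-padded to the common size
  p3 <- mk_proj(matrix(rnorm(24) + 10, 4, 6), id = "c")
  p4 <- mk_proj(matrix(rnorm(25) + 10, 5, 5), id = "d")
  sup2 <- stitch_projections(list(p3, p4))
  expect_equal(dim(sup2$values), c(5, 6 + 1 + 6))
  expect_equal(sum(sup2$mask), 24 + 25)
  expect_true(all(sup2$values[5, 1:6] == 0))    # padding row of the 4x6 tile
  parts2 <- disassemble(sup2)
  expect_equal(dim(parts2$c), c(4, 6))
  expect_equal(parts2$c, p3$values)
  expect_error(stitch_projections(list()), "empty")
})

test_that("cohort permutation pool spans all samples' on-mask values", {
  # two tiny samples with disjoint value ranges; draws for a pixel in sample
  # A must contain values only present in sample B
  v1 <- matrix(seq(1, 2, length.out = 16), 4, 4)
  v2 <- matrix(seq(100, 101, length.out = 16), 4, 4)
  sup <- stitch_projections(list(mk_proj(v1, id = "a"), mk_proj(v2, id = "b")))
  on <- which(as.matrix(sup$mask))
  x <- sup$values[on]
  z <- x - mean(x)
  zs <- sort(z)
  # replay the stream of the first on-mask pixel (8 wouldn't matter; any k)
  w <- build_weights(sup$mask)
  i <- 1L
  k <- length(w$neighbors[[i]])
  draws <- mirsa:::perm_pool_indices(7, z[i], k, length(z) - 1L, 500)
  pos <- which(zs >= z[i])[1]
  drawn_z <- zs[ifelse(draws + 1L < pos, draws + 1L, draws + 2L)]
  drawn_x <- drawn_z + mean(x)
  # both samples' value ranges appear among the draws
  expect_gt(sum(drawn_x > 50), 0)
  expect_gt(sum(drawn_x < 50), 0)
  # and the draw frequencies are near-uniform over the pool (chi-square)
  tab <- table(factor(as.vector(draws), levels = 0:(length(z) - 2L)))
  expect_gt(stats::chisq.test(tab)$p.value, 1e-6)
})

test_that("a cohort of identical samples yields identical per-sample maps", {
  set.seed(4)
  v <- matrix(rnorm(64) + 10, 8, 8); v[3:6, 3:6] <- v[3:6, 3:6] + 4
  projs <- lapply(c("a", "b", "c"), function(id) mk_proj(v, id = id))
  cs <- cohort_sa(projs, alpha = 0.05, n_perm = 199, seed = 11)
  expect_identical(unclass(cs$maps$a)[, ], unclass(cs$maps$b)[, ])
  expect_identical(unclass(cs$maps$a)[, ], unclass(cs$maps$c)[, ])
  expect_identical(cs$moran$a$pseudo_p, cs$moran$b$pseudo_p)
})

test_that("disassembled cohort maps exactly partition the super-image map", {
  ph <- simulate_projection_cohort(n_samples = 4, image_size = c(24, 24),
                                   fraction_homogeneous = 0, seed = 3)
  projs <- lapply(ph, `[[`, "projection")
  cs <- cohort_sa(projs, alpha = 0.05, n_perm = 199, seed = 5)
  super_map <- threshold_hotspots(cs$super_result, 0.05)
  parts <- disassemble(cs$super, unclass(super_map)[, ])
  for (id in names(cs$maps)) {
    expect_identical(parts[[id]], unclass(cs$maps[[id]])[, ])
  }
  expect_equal(sum(super_map), sum(vapply(cs$maps, sum, numeric(1))))
})

test_that("cohort-wide SA silences the homogeneous control that individual SA flags", {
  ph <- simulate_projection_cohort(n_samples = 7, seed = 29)
  hom <- which(vapply(ph, `[[`, logical(1), "homogeneous"))
  expect_length(hom, 1L)
  ctrl <- ph[[hom]]$projection
  ind <- threshold_hotspots(local_moran(ctrl, n_perm = 999, seed = 7), 0.01)
  expect_gt(sum(ind), 0)                       # spurious, non-empty
  cs <- cohort_sa(lapply(ph, `[[`, "projection"), alpha = 0.01,
                  n_perm = 999, seed = 7)
  expect_lt(mean(cs$maps[[hom]]), 0.01)        # < 1% of control pixels
})

test_that("cohort-wide and individual SA agree on a balanced heterogeneous sample", {
  ph <- simulate_projection_cohort(n_samples = 4, fraction_homogeneous = 0,
                                   seed = 31)
  projs <- lapply(ph, `[[`, "projection")
  cs <- cohort_sa(projs, alpha = 0.01, n_perm = 999, seed = 3)
  ind <- threshold_hotspots(local_moran(projs[[1]], n_perm = 999, seed = 3),
                            0.01)
  expect_gte(iou(cs$maps[[1]], ind), 0.7)
})

test_that("database ratios and reference picking follow the low-high rule", {
  ph <- simulate_projection_cohort(n_samples = 6, fraction_homogeneous = 0,
                                   seed = 41)
  projs <- lapply(ph, `[[`, "projection")
  db <- build_database(projs, alpha = 0.01, n_perm = 499, seed = 2)
  expect_equal(nrow(db$ratios), 6)
  for (id in names(db$samples)) {
    s <- db$samples[[id]]
    expect_equal(s$ratio, sum(s$map) / sum(s$projection$mask))
    expect_gte(s$ratio, 0); expect_lte(s$ratio, 1)
  }
  refs <- pick_references(db)
  ord <- db$ratios[order(db$ratios$ratio), ]
  expect_identical(refs, c(ord$sample_id[1], ord$sample_id[6]))
  expect_error(pick_references(db, 7), "exceeds")
  # tie rule: equal ratios fall back to sample_id order
  db2 <- db
  db2$ratios$ratio <- 0.5
  expect_identical(pick_references(db2),
                   c(sort(db$ratios$sample_id)[1],
                     sort(db$ratios$sample_id)[6]))
})

test_that("hotspot databases survive a disk round trip", {
  ph <- simulate_projection_cohort(n_samples = 3, image_size = c(16, 16),
                                   blob_radius = 4,
                                   fraction_homogeneous = 0, seed = 43)
  db <- build_database(lapply(ph, `[[`, "projection"), alpha = 0.05,
                       n_perm = 199, seed = 3)
  dir <- file.path(withr::local_tempdir(), "db")
  write_database(db, dir)
  back <- read_database(dir)
  expect_equal(back$alpha_db, db$alpha_db)
  expect_equal(back$ratios$ratio, db$ratios$ratio)
  id <- names(db$samples)[1]
  expect_equal(back$samples[[id]]$moran$pseudo_p,
               db$samples[[id]]$moran$pseudo_p, tolerance = 1e-12)
  expect_identical(unclass(back$samples[[id]]$map)[, ],
                   unclass(db$samples[[id]]$map)[, ])
})

test_that("reference calibration is self-consistent on a database sample", {
  ph <- simulate_projection_cohort(n_samples = 6, fraction_homogeneous = 0,
                                   seed = 47)
  projs <- lapply(ph, `[[`, "projection")
  db <- build_database(projs, alpha = 0.01, n_perm = 999, seed = 9)
  refs <- pick_references(db)
  new_id <- setdiff(names(db$samples), refs)[1]
  cal <- reference_sa(db$samples[[new_id]]$projection, db, n_perm = 1999,
                      seed = 13)
  # alpha* localizes near alpha_db (to the scale the flat-topped IoU curve
  # supports) and the calibrated map reproduces the database map
  expect_lte(abs(cal$alpha_star - db$alpha_db), 0.005)
  expect_gte(iou(cal$new_map, db$samples[[new_id]]$map), 0.9)
  # IoU of two explicit maps: 3 common pixels, union 5
  a <- matrix(FALSE, 2, 3); b <- a
  a[c(1, 2, 3, 4)] <- TRUE; b[c(2, 3, 4, 5)] <- TRUE
  expect_equal(iou(a, b), 3 / 5)
  # curve is defined everywhere and argmax ties resolve to smallest alpha
  expect_false(any(!is.finite(cal$iou_curve$mean_iou)))
  expect_equal(cal$alpha_star,
               cal$iou_curve$alpha[which.max(cal$iou_curve$mean_iou)])
  expect_equal(nrow(cal$iou_curve), 1000)
  expect_s3_class(tidy(cal), "tbl_df")
  expect_equal(glance(cal)$alpha_db, 0.01)
})

test_that("mean-of-per-reference-optima calibration mode is available", {
  ph <- simulate_projection_cohort(n_samples = 4, image_size = c(32, 32),
                                   fraction_homogeneous = 0, seed = 53)
  projs <- lapply(ph, `[[`, "projection")
  db <- build_database(projs, alpha = 0.01, n_perm = 499, seed = 3)
  new_id <- setdiff(names(db$samples), pick_references(db))[1]
  cal <- reference_sa(db$samples[[new_id]]$projection, db, n_perm = 999,
                      seed = 5, mode = "mean_argmax")
  per_ref <- vapply(cal$references, function(id) {
    col <- cal$iou_curve[[paste0("iou_", id)]]
    cal$iou_curve$alpha[which.max(col)]
  }, numeric(1))
  expect_equal(cal$alpha_star, mean(per_ref))
})
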