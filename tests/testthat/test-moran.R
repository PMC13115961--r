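test_that("queen weights: interior 8 neighbours, corner 3, isolated flagged", {
  w <- build_weights(matrix(TRUE, 5, 5))
  # on-mask ordering is column-major; pixel (3,3) is index 13
  expect_length(w$neighbors[[13]], 8)
  expect_equal(w$weights[[13]], rep(1 / 8, 8))
  expect_length(w$neighbors[[1]], 3)           # corner (1,1)
  expect_equal(w$weights[[1]], rep(1 / 3, 3))
  expect_true(all(vapply(seq_along(w$neighbors), function(i) {
    !i %in% w$neighbors[[i]]
  }, logical(1))))                              # no self-neighbours
  expect_true(all(abs(vapply(w$weights[lengths(w$weights) > 0], sum,
                             numeric(1)) - 1) < 1e-12))
  # pixel whose 8 neighbours are all off-mask is isolated
  m <- matrix(FALSE, 5, 5); m[1, 1] <- TRUE; m[4, 4] <- TRUE
  w2 <- build_weights(m)
  expect_true(all(w2$isolated))
  # binary style keeps unit weights
  w3 <- build_weights(matrix(TRUE, 3, 3), style = "B")
  expect_equal(w3$weights[[5]], rep(1, 8))
})

test_that("observed local I equals the double-loop oracle (masked too)", {
  set.seed(21)
  for (case in 1:3) {
    nr <- c(12, 20, 15)[case]; nc <- c(12, 20, 9)[case]
    v <- matrix(rnorm(nr * nc), nr, nc)
    m <- if (case == 3) matrix(runif(nr * nc) > 0.3, nr, nc)
         else matrix(TRUE, nr, nc)
    if (!any(m)) next
    res <- local_moran(v, m, n_perm = 99, seed = 1)
    bf <- brute_local_moran(v, m)
    expect_lt(max(abs(res$observed_I - bf$I), na.rm = TRUE), 1e-12)
    expect_equal(res$global_mean, bf$xbar)
    expect_equal(res$m2, bf$m2)
  }
})

test_that("pseudo p-values equal the loop oracle under shared streams", {
  set.seed(5)
  v <- matrix(rnorm(144), 12, 12)
  m <- matrix(TRUE, 12, 12)
  res <- local_moran(v, m, n_perm = 999, seed = 42)
  oracle <- oracle_pseudo_p(v, m, n_perm = 999, seed = 42)
  expect_identical(res$pseudo_p, oracle)
  expect_gte(min(res$pseudo_p), 1 / 1000)
})

test_that("alternating fields give non-positive interior I under queen weights", {
  # stripes: 6 of 8 queen neighbours carry the opposite sign -> I < 0
  v <- outer(1:10, 1:10, function(r, c) ifelse(r %% 2 == 0, 1, -1))
  res <- local_moran(v, matrix(TRUE, 10, 10), n_perm = 99, seed = 1)
  expect_true(all(res$observed_I[2:9, 2:9] < 0))
  # checkerboard: the 4 diagonal queen neighbours share the focal sign and
  # exactly cancel the 4 orthogonal ones, so interior I is 0 (not negative)
  v2 <- outer(1:10, 1:10, function(r, c) ifelse((r + c) %% 2 == 0, 1, -1))
  res2 <- local_moran(v2, matrix(TRUE, 10, 10), n_perm = 99, seed = 1)
  expect_equal(max(abs(res2$observed_I[2:9, 2:9])), 0)
})

test_that("quadrants follow the sign of deviation and lag", {
  set.seed(9)
  v <- matrix(rnorm(100), 10, 10)
  res <- local_moran(v, matrix(TRUE, 10, 10), n_perm = 99, seed = 2)
  z <- v - res$global_mean
  hh <- res$quadrant == "HH"
  expect_true(all(z[hh] > 0 & res$lag[hh] > 0))
  ll <- res$quadrant == "LL"
  expect_true(all(z[ll] <= 0 & res$lag[ll] <= 0))
})

test_that("hotspot thresholding is monotone, bounded, and repermutation-free", {
  set.seed(3)
  v <- matrix(rnorm(400), 20, 20); v[5:9, 5:9] <- v[5:9, 5:9] + 3
  res <- local_moran(v, matrix(TRUE, 20, 20), n_perm = 199, seed = 8)
  h1 <- threshold_hotspots(res, 0.01)
  h2 <- threshold_hotspots(res, 0.05)
  expect_true(all(h2[h1]))                       # alpha1 <= alpha2 nesting
  # below the attainable p floor the map is empty
  expect_equal(sum(threshold_hotspots(res, 1 / 400)), 0)
  # alpha = 1 selects every HH pixel
  expect_equal(sum(threshold_hotspots(res, 1)),
               sum(res$quadrant == "HH", na.rm = TRUE))
  # hotspots are HH-only
  expect_true(all(res$quadrant[as.matrix(h1)] == "HH"))
  cold <- threshold_coldspots(res, 0.05)
  expect_true(all(res$quadrant[as.matrix(cold)] == "LL"))
})

test_that("translating image and mask together shifts results identically", {
  set.seed(13)
  v <- matrix(rnorm(64), 8, 8); v[2:4, 2:4] <- v[2:4, 2:4] + 4
  pad <- function(off_r, off_c) {
    big <- matrix(0, 14, 14); m <- matrix(FALSE, 14, 14)
    big[off_r + 1:8, off_c + 1:8] <- v
    m[off_r + 1:8, off_c + 1:8] <- TRUE
    local_moran(big, m, n_perm = 199, seed = 6)
  }
  r1 <- pad(0, 0); r2 <- pad(4, 3)
  expect_identical(r1$pseudo_p[1:8, 1:8], r2$pseudo_p[4 + 1:8, 3 + 1:8])
  expect_equal(r1$observed_I[1:8, 1:8], r2$observed_I[4 + 1:8, 3 + 1:8])
  h1 <- threshold_hotspots(r1, 0.05); h2 <- threshold_hotspots(r2, 0.05)
  expect_identical(unclass(h1)[1:8, 1:8], unclass(h2)[4 + 1:8, 3 + 1:8])
})

test_that("a planted bright disk is recovered as a hotspot (IoU >= 0.8)", {
  set.seed(19)
  nr <- 48; nc <- 48
  disk <- (matrix(seq_len(nr), nr, nc) - 24)^2 +
    (matrix(seq_len(nc), nr, nc, byrow = TRUE) - 24)^2 <= 10^2
  v <- matrix(rnorm(nr * nc), nr, nc)
  v[disk] <- v[disk] + 4
  res <- local_moran(v, matrix(TRUE, nr, nc), n_perm = 999, seed = 4)
  h <- threshold_hotspots(res, 0.01)
  expect_gte(iou(h, disk), 0.8)
})

test_that("degenerate and undersized inputs are rejected", {
  expect_error(local_moran(matrix(1, 5, 5), n_perm = 999), "degenerate")
  expect_error(local_moran(matrix(rnorm(25), 5, 5), n_perm = 9), ">= 99")
})

test_that("overlays classify unique/multiple/none per the set oracle", {
  res <- local_moran(matrix(rnorm(100), 10, 10), n_perm = 99, seed = 1)
  mk <- function(px) {
    m <- matrix(FALSE, 10, 10); m[px] <- TRUE
    mirsa:::new_hotspot_map(m, 0.01, res)
  }
  a <- mk(1:20); b <- mk(15:30); c <- mk(c(1, 28:35))
  ov <- overlay_maps(list(tumor = a, stroma = b, necrosis = c))
  # enumeration oracle
  for (px in 1:40) {
    sets <- c("tumor", "stroma", "necrosis")[c(px %in% 1:20, px %in% 15:30,
                                               px %in% c(1, 28:35))]
    want <- if (length(sets) == 0) "none" else if (length(sets) > 1)
      "multiple" else sets
    expect_identical(ov$label[px], want)
  }
  # disjoint maps: never multiple
  ov2 <- overlay_maps(list(tumor = mk(1:10), stroma = mk(21:30)))
  expect_false(any(ov2$label == "multiple", na.rm = TRUE))
  # identical maps: all their pixels multiple
  ov3 <- overlay_maps(list(tumor = mk(5:12), stroma = mk(5:12)))
  expect_true(all(ov3$label[5:12] == "multiple"))
  expect_error(overlay_maps(list(a = a, b = mirsa:::new_hotspot_map(
    matrix(FALSE, 3, 3), 0.01, res))), "dimensions")
  expect_equal(nrow(tidy(ov)), 100)
})
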