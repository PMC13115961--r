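# One small synthetic scene reused across feature-selection tests: 24x24,
# 20 bands, band 5 fully separates tumor (higher) from stroma.
make_separable_scene <- function(seed = 7, nb = 20) {
  set.seed(seed)
  nr <- 24; nc <- 24
  wn <- seq(1000, by = 4, length.out = nb)
  arr <- array(rnorm(nr * nc * nb, 0, 1), c(nr, nc, nb))
  lab <- toy_labels(nr, nc)
  tumor <- label_names(lab) == "tumor"
  band5 <- arr[, , 5]
  band5[tumor] <- runif(sum(tumor), 3, 5)      # disjoint from N(0,1) range
  band5[!tumor] <- runif(sum(!tumor), -5, -3)
  arr[, , 5] <- band5
  list(cube = spectral_cube(arr, wn), labels = lab, wn = wn)
}

test_that("balanced sampling is seeded, capped and class-complete", {
  sc <- make_separable_scene()
  t1 <- sample_balanced_pixels(sc$cube, sc$labels, n_per_class = 50, seed = 3)
  t2 <- sample_balanced_pixels(sc$cube, sc$labels, n_per_class = 50, seed = 3)
  expect_identical(t1, t2)
  expect_equal(unname(table(t1$tissue)), c(50L, 50L), ignore_attr = TRUE)
  # duplicate draws are impossible (without replacement)
  expect_false(any(duplicated(t1[, c("tissue", "row", "col")])))
  # capping: ask for more than the smallest class holds
  expect_warning(
    t3 <- sample_balanced_pixels(sc$cube, sc$labels, n_per_class = 10000,
                                 seed = 3),
    "drawing")
  expect_equal(nrow(t3), 2 * min(table(label_names(sc$labels))))
  # zero-pixel class errors
  lab_bad <- label_map(matrix(1L, 24, 24),
                       c("1" = "tumor", "2" = "ghost"))
  expect_error(
    sample_balanced_pixels(sc$cube, lab_bad, 5, 1),
    NA)  # ghost never appears on the map, so only tumor is sampled
  lab0 <- label_map(matrix(0L, 24, 24), c("1" = "tumor"))
  expect_error(sample_balanced_pixels(sc$cube, lab0, 5, 1), "no labelled")
})

test_that("a perfectly separating band tops the ranking in every repeat", {
  sc <- make_separable_scene()
  # univariate AUC oracle: band 5 separates the classes perfectly
  tumor <- label_names(sc$labels) == "tumor"
  auc <- suppressMessages(
    as.numeric(pROC::auc(as.vector(tumor), as.vector(sc$cube$values[, , 5]),
                         quiet = TRUE)))
  expect_equal(auc, 1.0)
  rk <- rank_wavenumbers(sc$cube, sc$labels, "tumor", n_repeats = 5,
                         n_per_class = 60, num_trees = 100, seed = 2)
  row5 <- rk$ranking[rk$ranking$wavenumber == sc$wn[5], ]
  expect_equal(row5$times_in_top10, 5)
  expect_equal(which.max(rk$ranking$mean_importance), 5L)
  expect_true(sc$wn[5] %in% rk$candidates)
  expect_length(row5$scores[[1]], 5)
})

test_that("shuffled labels leave no band with outstanding importance", {
  sc <- make_separable_scene()
  set.seed(31)
  shuf <- matrix(sample(as.integer(sc$labels)), 24, 24)
  lab_shuf <- label_map(shuf, attr(sc$labels, "legend"))
  rk <- rank_wavenumbers(sc$cube, lab_shuf, "tumor", n_repeats = 4,
                         n_per_class = 60, num_trees = 100, seed = 5)
  # under the null, importances scatter around 0; nothing stands out the way
  # the planted band does in the structured scene
  imp <- rk$ranking$mean_importance
  expect_lt(max(imp), 0.05)
  rk_alt <- rank_wavenumbers(sc$cube, sc$labels, "tumor", n_repeats = 4,
                             n_per_class = 60, num_trees = 100, seed = 5)
  expect_gt(max(rk_alt$ranking$mean_importance), 10 * max(imp))
})

test_that("error test keeps separable bands, rejects uninformative ones", {
  sc <- make_separable_scene()
  fs <- error_test(sc$cube, sc$labels, "tumor",
                   candidates = c(sc$wn[5], sc$wn[1]))
  expect_s3_class(fs, "discriminant_features")
  expect_true(sc$wn[5] %in% fs$features$wavenumber)
  expect_false(sc$wn[1] %in% fs$features$wavenumber)  # pure noise band
  f5 <- fs$features[fs$features$wavenumber == sc$wn[5], ]
  expect_equal(f5$worst_error, 0)
  expect_equal(f5$direction, "ppf")
  # all candidates uninformative -> explicit no-features error
  expect_error(error_test(sc$cube, sc$labels, "tumor",
                          candidates = sc$wn[1:2]),
               "no discriminant features")
})

test_that("identical class distributions yield ~0.5 error (oracle check)", {
  # 50-pixel toy: same uniform grid of values in both classes
  nr <- 10; nc <- 5
  vals <- array(rep(seq(0, 1, length.out = 25), 2), c(nr, nc, 1))
  cube <- spectral_cube(vals, 1000)
  lab <- label_map(matrix(rep(1:2, each = 25), nr, nc),
                   c("1" = "tumor", "2" = "stroma"))
  expect_error(error_test(cube, lab, "tumor", 1000), "no discriminant")
  # exhaustive oracle: best achievable balanced error over every cutoff
  v <- seq(0, 1, length.out = 25)
  errs <- vapply(sort(unique(v)), function(ct) {
    (mean(v > ct) + mean(v <= ct)) / 2
  }, numeric(1))
  expect_equal(min(errs), 0.5)
})

test_that("error test is invariant to affine rescaling of a band", {
  sc <- make_separable_scene()
  fs1 <- error_test(sc$cube, sc$labels, "tumor", sc$wn[5])
  cube2 <- sc$cube
  cube2$values[, , 5] <- 3.7 * cube2$values[, , 5] - 12
  fs2 <- error_test(cube2, sc$labels, "tumor", sc$wn[5])
  expect_equal(fs1$features$worst_error, fs2$features$worst_error)
  expect_equal(fs1$features$direction, fs2$features$direction)
  expect_equal(3.7 * fs1$features$cutoff - 12, fs2$features$cutoff,
               tolerance = 1e-9)
})

test_that("stored cutoffs are within one grid step of the brute-force optimum", {
  set.seed(17)
  nr <- 10; nc <- 10
  v <- array(c(rnorm(50, 0, 1), rnorm(50, 1.5, 1)), c(nr, nc, 1))
  cube <- spectral_cube(v, 1000)
  lab <- label_map(matrix(rep(2:1, each = 50), nr, nc),
                   c("1" = "tumor", "2" = "stroma"))
  fs <- error_test(cube, lab, "tumor", 1000, max_error = 0.5, n_cutoff = 512)
  lab_names <- label_names(lab)
  v_t <- v[, , 1][lab_names == "tumor"]; v_s <- v[, , 1][lab_names == "stroma"]
  # brute force over every observed value as cutoff
  best <- min(vapply(sort(c(v_t, v_s)), function(ct) {
    (mean(v_t <= ct) + mean(v_s > ct)) / 2
  }, numeric(1)))
  step_err <- 1 / min(length(v_t), length(v_s))   # one sample's resolution
  expect_lte(fs$features$worst_error, best + step_err)
})

test_that("feature sets round-trip through their JSON form", {
  fs <- discriminant_features(
    "tumor",
    tibble::tibble(wavenumber = c(964, 1108, 1156),
                   direction = c("ppf", "npf", "ppf"),
                   cutoff = c(0.1, -0.2, 0.33),
                   worst_error = c(0.01, 0.2, 0)))
  f <- file.path(withr::local_tempdir(), "f.json")
  write_features(fs, f)
  back <- read_features(f)
  expect_equal(back$tissue_type, fs$tissue_type)
  expect_equal(as.data.frame(back$features), as.data.frame(fs$features))
  expect_equal(glance(fs)$n_ppf, 2)
  expect_equal(nrow(tidy(fs)), 3)
})
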