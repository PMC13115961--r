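#' Sample a balanced labelled spectra table
#'
#' Draws `n_per_class` labelled on-tissue pixels per tissue type, without
#' replacement, reproducibly by seed. If some class has fewer labelled pixels
#' the draw for *all* classes is capped at the minimum class size, with a
#' warning.
#'
#' @param cube a (preprocessed) [spectral_cube()].
#' @param labels a [label_map()] aligned to the cube.
#' @param n_per_class pixels to draw per tissue type (default 500).
#' @param seed integer seed.
#' @param mask optional on-tissue mask restricting eligible pixels.
#' @return tibble: `tissue`, `row`, `col`, then one numeric column per band
#'   named `wn_<wavenumber>`.
#' @export
sample_balanced_pixels <- function(cube, labels, n_per_class = 500, seed = 1L,
                                   mask = NULL) {
  stopifnot(inherits(cube, "spectral_cube"), inherits(labels, "label_map"))
  d <- dim(cube$values)
  check_same_shape(cube$values, labels, "cube/labels")
  lab_names <- label_names(labels)
  eligible <- !is.na(lab_names)
  if (!is.null(mask)) eligible <- eligible & as_mask(mask)
  classes <- sort(unique(lab_names[eligible]))
  if (!length(classes)) stop("no labelled on-tissue pixels", call. = FALSE)
  sizes <- vapply(classes, function(cl) sum(lab_names == cl & eligible),
                  integer(1))
  if (any(sizes == 0L)) {
    stop("tissue type(s) with zero labelled pixels: ",
         paste(classes[sizes == 0], collapse = ", "), call. = FALSE)
  }
  n_draw <- n_per_class
  if (min(sizes) < n_per_class) {
    n_draw <- min(sizes)
    warning(sprintf(
      "smallest class has %d labelled pixels; drawing %d per class instead of %d",
      min(sizes), n_draw, n_per_class), call. = FALSE)
  }
  X <- matrix(cube$values, nrow = d[1] * d[2], ncol = d[3])
  picks <- with_local_seed(seed, {
    lapply(classes, function(cl) {
      idx <- which(lab_names == cl & eligible)
      sort(sample(idx, n_draw))
    })
  })
  rows_list <- lapply(seq_along(classes), function(ci) {
    idx <- picks[[ci]]
    spec <- X[idx, , drop = FALSE]
    colnames(spec) <- paste0("wn_", format(cube$wavenumbers, trim = TRUE,
                                           scientific = FALSE))
    tibble::tibble(tissue = classes[ci],
                   row = ((idx - 1L) %% d[1]) + 1L,
                   col = ((idx - 1L) %/% d[1]) + 1L) |>
      dplyr::bind_cols(tibble::as_tibble(spec))
  })
  dplyr::bind_rows(rows_list)
}

#' Rank wavenumbers by random-forest permutation importance
#'
#' For each of `n_repeats` repeats a fresh balanced pixel sample is drawn, a
#' random forest is fitted to the one-vs-rest task (tissue of interest vs all
#' other types) and the permutation importance of every band recorded. A band
#' is a selection candidate if it ranks among the top ten in at least one
#' repeat. Ties in a repeat's ranking are broken by ascending wavenumber.
#'
#' @param cube a preprocessed [spectral_cube()].
#' @param labels a [label_map()].
#' @param tissue the tissue type of interest (must appear in the legend).
#' @param n_repeats importance repeats (default 10).
#' @param n_per_class balanced sample size per tissue type (default 500).
#' @param num_trees forest size (default 200).
#' @param seed integer seed; repeat `r` uses derived seed `seed + r`.
#' @param mask optional eligibility mask.
#' @param top_k ranking depth defining candidacy (default 10).
#' @return object of class `mir_feature_ranking`: tibble `$ranking` with
#'   per-band mean importance, per-repeat scores and `times_in_top10`, plus
#'   `$candidates` (wavenumbers) and metadata.
#' @export
rank_wavenumbers <- function(cube, labels, tissue, n_repeats = 10,
                             n_per_class = 500, num_trees = 200, seed = 1L,
                             mask = NULL, top_k = 10L) {
  stopifnot(inherits(cube, "spectral_cube"))
  legend <- attr(labels, "legend")
  if (!tissue %in% legend) {
    stop("tissue '", tissue, "' not in label legend", call. = FALSE)
  }
  n_classes <- length(unique(label_names(labels)[!is.na(label_names(labels))]))
  if (n_classes < 2L) stop("need >= 2 tissue classes", call. = FALSE)
  n_bands <- dim(cube$values)[3]
  if (n_bands < top_k) {
    warning("fewer bands than top_k; all bands become candidates",
            call. = FALSE)
  }
  scores <- matrix(NA_real_, n_bands, n_repeats)
  for (r in seq_len(n_repeats)) {
    tab <- suppressWarnings(
      sample_balanced_pixels(cube, labels, n_per_class, seed + r, mask))
    y <- factor(ifelse(tab$tissue == tissue, "ttoi", "rest"))
    Xcols <- grep("^wn_", names(tab))
    df <- data.frame(y = y, tab[, Xcols])
    fit <- ranger::ranger(
      y ~ ., data = df, num.trees = num_trees,
      importance = "permutation", seed = seed + r, num.threads = 1)
    scores[, r] <- as.numeric(fit$variable.importance)
  }
  mean_imp <- rowMeans(scores)
  # per-repeat top-k membership, ties broken by ascending wavenumber
  in_top <- matrix(FALSE, n_bands, n_repeats)
  k_eff <- min(top_k, n_bands)
  for (r in seq_len(n_repeats)) {
    ord <- order(-scores[, r], cube$wavenumbers)
    in_top[ord[seq_len(k_eff)], r] <- TRUE
  }
  ranking <- tibble::tibble(
    wavenumber = cube$wavenumbers,
    mean_importance = mean_imp,
    times_in_top10 = rowSums(in_top),
    scores = lapply(seq_len(n_bands), function(b) scores[b, ]))
  candidates <- ranking$wavenumber[ranking$times_in_top10 > 0]
  structure(
    list(ranking = ranking, candidates = candidates, tissue_type = tissue,
         n_repeats = n_repeats, n_per_class = n_per_class,
         num_trees = num_trees, seed = as.integer(seed)),
    class = "mir_feature_ranking")
}

#' @export
print.mir_feature_ranking <- function(x, ...) {
  cat(sprintf(
    "<mir_feature_ranking '%s'> %d bands, %d repeats, %d candidate(s)\n",
    x$tissue_type, nrow(x$ranking), x$n_repeats, length(x$candidates)))
  invisible(x)
}

#' Discriminant feature set
#'
#' Per-tissue selected wavenumbers with their predictive direction, optimal
#' intensity cutoff and worst single-class misassignment error.
#'
#' @param tissue_type tissue-type name.
#' @param features tibble with columns `wavenumber`, `direction`
#'   (`"ppf"`/`"npf"`), `cutoff`, `worst_error`.
#' @param max_error the error-test threshold the features passed.
#' @return object of class `discriminant_features`.
#' @export
discriminant_features <- function(tissue_type, features, max_error = 0.25) {
  features <- tibble::as_tibble(features)
  stopifnot(all(c("wavenumber", "direction", "cutoff", "worst_error") %in%
                  names(features)))
  structure(list(tissue_type = as.character(tissue_type),
                 features = features, max_error = max_error),
            class = "discriminant_features")
}

#' @export
print.discriminant_features <- function(x, ...) {
  cat(sprintf("<discriminant_features '%s'> %d feature(s), max_error %.2f\n",
              x$tissue_type, nrow(x$features), x$max_error))
  if (nrow(x$features)) {
    print(x$features, n = 20)
  }
  invisible(x)
}

# per-class misassignment error of every cutoff on a grid: for each non-TTOI
# class, the balanced mean of (fraction of its pixels on the TTOI side) and
# (fraction of TTOI pixels on the wrong side) — i.e. 1 minus the balanced
# accuracy of the single-cutoff classifier for that class pair. Identical
# distributions give 0.5, perfect separation 0.
cutoff_error_curve <- function(v_ttoi, v_by_class, ttoi_high, cuts) {
  ttoi_wrong <- if (ttoi_high) {
    vapply(cuts, function(ct) mean(v_ttoi <= ct), numeric(1))
  } else {
    vapply(cuts, function(ct) mean(v_ttoi > ct), numeric(1))
  }
  per_class <- vapply(v_by_class, function(v) {
    if (ttoi_high) {
      vapply(cuts, function(ct) mean(v > ct), numeric(1))
    } else {
      vapply(cuts, function(ct) mean(v <= ct), numeric(1))
    }
  }, numeric(length(cuts)))
  per_class <- (matrix(per_class, nrow = length(cuts)) + ttoi_wrong) / 2
  apply(per_class, 1L, max)    # worst class at each cutoff
}

#' Specificity error test for candidate wavenumbers
#'
#' For each candidate band, cutoffs are scanned over the band's observed
#' intensity range (`n_cutoff` equally spaced steps); at each cutoff, every
#' non-TTOI tissue type's error is the fraction of its pixels falling on the
#' TTOI side plus the fraction of TTOI pixels falling on the wrong side. The
#' cutoff minimising the worst per-class error is retained, and the band is
#' kept iff that worst error is at most `max_error` (default 25%). The
#' direction is `ppf` iff the TTOI mean exceeds the mean over all other
#' types at that band.
#'
#' @param cube a preprocessed [spectral_cube()].
#' @param labels a [label_map()].
#' @param tissue the tissue type of interest.
#' @param candidates candidate wavenumbers (from [rank_wavenumbers()]).
#' @param max_error maximum tolerated worst-class error (default 0.25).
#' @param n_cutoff cutoff grid resolution (default 512).
#' @param mask optional eligibility mask.
#' @return a [discriminant_features()] object; errors if no candidate passes
#'   (some tissue types lack specific wavenumber features — the test is
#'   allowed to say so).
#' @export
error_test <- function(cube, labels, tissue, candidates, max_error = 0.25,
                       n_cutoff = 512, mask = NULL) {
  stopifnot(inherits(cube, "spectral_cube"), length(candidates) >= 1L)
  lab_names <- label_names(labels)
  eligible <- !is.na(lab_names)
  if (!is.null(mask)) eligible <- eligible & as_mask(mask)
  classes <- sort(unique(lab_names[eligible]))
  if (!tissue %in% classes) {
    stop("tissue '", tissue, "' has no labelled pixels", call. = FALSE)
  }
  others <- setdiff(classes, tissue)
  d <- dim(cube$values)
  kept <- list()
  for (wn in candidates) {
    b <- band_index(cube, wn)
    band <- cube$values[, , b]
    v_ttoi <- band[lab_names == tissue & eligible]
    v_by_class <- lapply(others, function(cl) band[lab_names == cl & eligible])
    ttoi_high <- mean(v_ttoi) > mean(unlist(v_by_class))
    rng <- range(c(v_ttoi, unlist(v_by_class)))
    cuts <- seq(rng[1], rng[2], length.out = n_cutoff)
    err <- cutoff_error_curve(v_ttoi, v_by_class, ttoi_high, cuts)
    best <- which.min(err)
    if (err[best] <= max_error) {
      kept[[length(kept) + 1L]] <- tibble::tibble(
        wavenumber = wn,
        direction = if (ttoi_high) "ppf" else "npf",
        cutoff = cuts[best],
        worst_error = err[best])
    }
  }
  if (!length(kept)) {
    stop("no discriminant features for tissue type '", tissue,
         "': every candidate exceeded the ", round(100 * max_error),
         "% error threshold", call. = FALSE)
  }
  discriminant_features(tissue, dplyr::bind_rows(kept), max_error)
}

#' One-call discriminant feature selection
#'
#' [rank_wavenumbers()] followed by [error_test()]; the ranking is attached
#' as attribute `"ranking"`.
#'
#' @inheritParams rank_wavenumbers
#' @inheritParams error_test
#' @return a [discriminant_features()] object.
#' @export
select_features <- function(cube, labels, tissue, n_repeats = 10,
                            n_per_class = 500, num_trees = 200,
                            max_error = 0.25, n_cutoff = 512, seed = 1L,
                            mask = NULL) {
  rk <- rank_wavenumbers(cube, labels, tissue, n_repeats, n_per_class,
                         num_trees, seed, mask)
  fs <- error_test(cube, labels, tissue, rk$candidates, max_error, n_cutoff,
                   mask)
  attr(fs, "ranking") <- rk
  fs
}

#' Serialize / deserialize a discriminant feature set as JSON
#'
#' @param x a [discriminant_features()] object.
#' @param path JSON file path.
#' @return `path` invisibly; [read_features()] returns the object.
#' @export
write_features <- function(x, path) {
  stopifnot(inherits(x, "discriminant_features"))
  jsonlite::write_json(
    list(tissue = x$tissue_type, max_error = x$max_error,
         features = x$features),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  discriminant_features(j$tissue, tibble::as_tibble(j$features), j$max_error)
}
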