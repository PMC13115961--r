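# Workflow orchestration: seeded, manifest-tracked runs over a synthetic or
# on-disk cohort.

#' Default pipeline configuration
#'
#' All defaults match the workflow's standard parameters: confidence level
#' 0.01, 999 permutations, calibration grid 0.0005-0.5 in 0.0005 steps,
#' 500 pixels per class, 10 importance repeats, 25% error-test threshold.
#'
#' @param out_dir artifact directory.
#' @param tissue tissue type of interest (default "tumor").
#' @param ... overrides for any config field.
#' @return named list of class `run_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("mirsa_run_"),
                            tissue = "tumor", ...) {
  cfg <- list(
    out_dir = out_dir, tissue = tissue,
    alpha = 0.01, n_perm = 999,
    alpha_min = 0.0005, alpha_max = 0.5, alpha_step = 0.0005,
    n_per_class = 500, repeats = 10, num_trees = 200, max_error = 0.25,
    n_cutoff = 512, baseline = 10,
    deriv_window = 9, deriv_polyorder = 3,
    dialect = "envi",
    n_samples = 7, image_size = c(48, 48), fraction_homogeneous = 1 / 7,
    seed_simulate = 101L, seed_features = 202L, seed_sa = 303L)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Run the annotation pipeline on a synthetic cohort
#'
#' Stages (in dependency order): `simulate` (generate the cohort),
#' `preprocess`, `select-features` (on the first heterogeneous sample),
#' `project`, `sa-cohort` (cohort-wide hotspot maps), `evaluate` (three
#' equal-width evaluation rectangles per sample against the ground-truth
#' labels). Every run writes its artifacts plus a `manifest.json` echoing
#' the resolved configuration, seeds and package version; reruns with the
#' same config and seeds are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of
#'   `c("simulate","preprocess","select-features","project","sa-cohort","evaluate")`.
#' @return invisibly, a list with the run state (cohort, features,
#'   projections, SA results, report, manifest path).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "preprocess",
                                    "select-features", "project",
                                    "sa-cohort", "evaluate")) {
  all_stages <- c("simulate", "preprocess", "select-features", "project",
                  "sa-cohort", "evaluate")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- list(config = config)

  if ("simulate" %in% stages) {
    spec <- synthetic_spec(
      n_samples = config$n_samples, image_size = config$image_size,
      fraction_homogeneous = config$fraction_homogeneous,
      seed = config$seed_simulate)
    state$cohort <- generate_cohort(spec)
    for (s in state$cohort) {
      write_cube(s$cube, file.path(config$out_dir, s$cube$sample_id),
                 dialect = config$dialect)
      write_mask(s$mask, file.path(config$out_dir,
                                   paste0(s$cube$sample_id, "_mask.png")))
      write_label_map(s$labels,
                      file.path(config$out_dir,
                                paste0(s$cube$sample_id, "_labels.png")))
    }
  }
  if ("preprocess" %in% stages) {
    if (is.null(state$cohort)) {
      stop("stage 'preprocess' needs a cohort: run stage 'simulate' first",
           call. = FALSE)
    }
    state$preprocessed <- lapply(state$cohort, function(s) {
      pp <- suppressMessages(
        preprocess_cube(s$cube, deriv_window = config$deriv_window,
                        deriv_polyorder = config$deriv_polyorder))
      mask <- pixel_mask(as.matrix(s$mask) & !pp$flagged)
      list(cube = pp, mask = mask, labels = s$labels,
           homogeneous = s$homogeneous)
    })
  }
  if ("select-features" %in% stages) {
    if (is.null(state$preprocessed)) {
      stop("stage 'select-features' needs preprocessed cubes: run ",
           "'preprocess' first", call. = FALSE)
    }
    train <- state$preprocessed[[which(!vapply(state$preprocessed, `[[`,
                                               logical(1), "homogeneous"))[1]]]
    state$features <- select_features(
      train$cube, train$labels, config$tissue,
      n_repeats = config$repeats, n_per_class = config$n_per_class,
      num_trees = config$num_trees, max_error = config$max_error,
      n_cutoff = config$n_cutoff, seed = config$seed_features,
      mask = train$mask)
    write_features(state$features,
                   file.path(config$out_dir, "features.json"))
  }
  if ("project" %in% stages) {
    if (is.null(state$features)) {
      stop("stage 'project' needs a feature set: run 'select-features' first",
           call. = FALSE)
    }
    state$projections <- lapply(state$preprocessed, function(s) {
      project_image(s$cube, state$features, s$mask,
                    baseline = config$baseline)
    })
  }
  if ("sa-cohort" %in% stages) {
    if (is.null(state$projections)) {
      stop("stage 'sa-cohort' needs projections: run 'project' first",
           call. = FALSE)
    }
    state$sa <- cohort_sa(state$projections, alpha = config$alpha,
                          n_perm = config$n_perm, seed = config$seed_sa)
    for (id in names(state$sa$maps)) {
      write_mask(pixel_mask(matrix(as.logical(state$sa$maps[[id]]),
                                   nrow(state$sa$maps[[id]]))),
                 file.path(config$out_dir, paste0(id, "_hotspots.png")))
    }
  }
  if ("evaluate" %in% stages) {
    if (is.null(state$sa)) {
      stop("stage 'evaluate' needs hotspot maps: run 'sa-cohort' first",
           call. = FALSE)
    }
    counts <- dplyr::bind_rows(lapply(seq_along(state$cohort), function(i) {
      s <- state$preprocessed[[i]]
      id <- s$cube$sample_id
      nrw <- nrow(s$labels); ncl <- ncol(s$labels)
      thirds <- floor(seq(0, ncl, length.out = 4))
      dplyr::bind_rows(lapply(1:3, function(r) {
        rect <- list(rect_id = paste0("R", r), row0 = 1L, row1 = nrw,
                     col0 = thirds[r] + 1L, col1 = thirds[r + 1])
        cc <- confusion_counts(state$sa$maps[[id]], s$labels, config$tissue,
                               rect, mask = s$mask)
        cc$sample_id <- id
        cc
      }))
    }))
    state$report <- cohort_report(counts)
    write_report(state$report, file.path(config$out_dir, "report.csv"),
                 file.path(config$out_dir, "report.json"))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("mirsa")),
    stages = stages,
    config = unclass(config))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  state$manifest <- file.path(config$out_dir, "manifest.json")
  invisible(state)
}
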