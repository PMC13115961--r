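#' Read a hyperspectral cube
#'
#' Two dialects are supported:
#' * `"envi"`: an ASCII `key = value` header (`<path>.hdr`, keys `samples`,
#'   `lines`, `bands`, `wavelength = { ... }`) next to a band-sequential (BSQ)
#'   raw binary of little-endian 32-bit floats (`<path>` or `<path>.raw`).
#' * `"per_band_matrix"`: a directory of whitespace/comma-delimited numeric
#'   matrices, one per band, named `<wavenumber>.txt`.
#'
#' Bands are returned sorted ascending by wavenumber regardless of on-disk
#' order.
#'
#' @param path path to the ENVI binary/header stem or to the per-band
#'   directory.
#' @param dialect `"envi"` or `"per_band_matrix"`.
#' @param pixel_size,sample_id passed to [spectral_cube()]; `sample_id`
#'   defaults to the file/directory name.
#' @return a [spectral_cube()].
#' @export
read_cube <- function(path, dialect = c("envi", "per_band_matrix"),
                      pixel_size = 25, sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(raw|dat|hdr)$", "", basename(path))
  }
  if (dialect == "envi") {
    read_cube_envi(path, pixel_size, sample_id)
  } else {
    read_cube_per_band(path, pixel_size, sample_id)
  }
}

read_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  get_scalar <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?mi)^\\s*", key, "\\s*=\\s*([0-9]+)"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) stop("malformed ENVI header: missing key '", key, "'",
                            call. = FALSE)
    as.integer(m[2])
  }
  wl_m <- regmatches(txt, regexec("(?si)wavelength\\s*=\\s*\\{([^}]*)\\}",
                                  txt, perl = TRUE))[[1]]
  if (length(wl_m) < 2) {
    stop("malformed ENVI header: missing 'wavelength = { ... }'", call. = FALSE)
  }
  wl <- as.numeric(strsplit(wl_m[2], "[,\\s]+")[[1]])
  wl <- wl[!is.na(wl)]
  list(samples = get_scalar("samples"), lines = get_scalar("lines"),
       bands = get_scalar("bands"), wavelength = wl)
}

read_cube_envi <- function(path, pixel_size, sample_id) {
  stem <- sub("\\.(raw|dat|hdr)$", "", path)
  hdr_path <- paste0(stem, ".hdr")
  if (!file.exists(hdr_path)) stop("header not found: ", hdr_path, call. = FALSE)
  bin_path <- if (file.exists(path) && !grepl("\\.hdr$", path)) path else {
    cand <- c(paste0(stem, ".raw"), paste0(stem, ".dat"), stem)
    cand[file.exists(cand)][1]
  }
  if (is.na(bin_path) || !file.exists(bin_path)) {
    stop("binary not found for header ", hdr_path, call. = FALSE)
  }
  h <- read_envi_header(hdr_path)
  if (length(h$wavelength) != h$bands) {
    stop(sprintf("header declares %d bands but lists %d wavelengths",
                 h$bands, length(h$wavelength)), call. = FALSE)
  }
  n_expect <- h$samples * h$lines * h$bands
  n_avail <- file.size(bin_path) / 4
  if (n_avail != n_expect) {
    stop(sprintf("binary holds %d values but header declares %d (%d bands)",
                 n_avail, n_expect, h$bands), call. = FALSE)
  }
  raw <- readBin(bin_path, "double", n = n_expect, size = 4,
                 endian = "little")
  # BSQ: band-major; within a band, line (row) major
  arr <- array(NA_real_, c(h$lines, h$samples, h$bands))
  per_band <- h$lines * h$samples
  for (b in seq_len(h$bands)) {
    band <- raw[((b - 1) * per_band + 1):(b * per_band)]
    arr[, , b] <- matrix(band, nrow = h$lines, ncol = h$samples, byrow = TRUE)
  }
  spectral_cube(arr, h$wavelength, pixel_size, sample_id)
}

read_cube_per_band <- function(path, pixel_size, sample_id) {
  if (!dir.exists(path)) stop("directory not found: ", path, call. = FALSE)
  files <- list.files(path, pattern = "^[0-9.]+\\.txt$", full.names = TRUE)
  if (!length(files)) stop("no <wavenumber>.txt files in ", path, call. = FALSE)
  wn <- as.numeric(sub("\\.txt$", "", basename(files)))
  ord <- order(wn)
  files <- files[ord]; wn <- wn[ord]
  mats <- lapply(files, function(f) {
    as.matrix(utils::read.table(f, header = FALSE, sep = "",
                                colClasses = "numeric"))
  })
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("per-band matrices have inconsistent dimensions", call. = FALSE)
  }
  arr <- array(unlist(mats), c(dims[1, 1], dims[2, 1], length(mats)))
  spectral_cube(arr, wn, pixel_size, sample_id)
}

#' Write a hyperspectral cube
#'
#' @param cube a [spectral_cube()].
#' @param path output stem (ENVI: writes `<path>.hdr` + `<path>.raw`) or
#'   directory (per-band dialect).
#' @param dialect `"envi"` or `"per_band_matrix"`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, dialect = c("envi", "per_band_matrix")) {
  stopifnot(inherits(cube, "spectral_cube"))
  dialect <- match.arg(dialect)
  d <- dim(cube$values)
  if (dialect == "envi") {
    stem <- sub("\\.(raw|dat|hdr)$", "", path)
    hdr <- c(
      "ENVI",
      paste0("samples = ", d[2]),
      paste0("lines = ", d[1]),
      paste0("bands = ", d[3]),
      "data type = 4",
      "interleave = bsq",
      "byte order = 0",
      paste0("wavelength = { ",
             paste(format(cube$wavenumbers, trim = TRUE, scientific = FALSE),
                   collapse = ", "), " }"))
    writeLines(hdr, paste0(stem, ".hdr"))
    con <- file(paste0(stem, ".raw"), "wb")
    on.exit(close(con))
    for (b in seq_len(d[3])) {
      writeBin(as.vector(t(cube$values[, , b])), con, size = 4,
               endian = "little")
    }
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (b in seq_len(d[3])) {
      f <- file.path(path, paste0(format(cube$wavenumbers[b], trim = TRUE,
                                         scientific = FALSE), ".txt"))
      utils::write.table(cube$values[, , b], f, row.names = FALSE,
                         col.names = FALSE)
    }
  }
  invisible(path)
}

#' Read / write binary masks and label maps as 8-bit PNG
#'
#' Masks are stored with on-tissue = 255, off-tissue = 0; label maps store the
#' integer tissue code directly in the 8-bit channel, with the legend in a
#' JSON sidecar `<path>.json`.
#'
#' @param path PNG file path.
#' @return [read_mask()] a [pixel_mask()]; [read_label_map()] a [label_map()].
#' @name mask_io
NULL

#' @rdname mask_io
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  pixel_mask(img > 0.5)
}

#' @rdname mask_io
#' @param mask a [pixel_mask()] (or logical matrix).
#' @export
write_mask <- function(mask, path) {
  mask <- as_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask)), path)
  invisible(path)
}

#' @rdname mask_io
#' @export
read_label_map <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  codes <- matrix(as.integer(round(img * 255)), nrow(img))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    legend <- meta$legend
    unlab <- as.integer(meta$unlabeled_code)
  } else {
    vals <- setdiff(sort(unique(as.vector(codes))), 0L)
    legend <- stats::setNames(paste0("tissue_", vals), as.character(vals))
    unlab <- 0L
  }
  label_map(codes, legend, unlab)
}

#' @rdname mask_io
#' @param labels a [label_map()].
#' @export
write_label_map <- function(labels, path) {
  stopifnot(inherits(labels, "label_map"))
  if (max(labels) > 255L) stop("label codes exceed 8-bit range", call. = FALSE)
  png::writePNG(matrix(as.integer(labels) / 255, nrow(labels)), path)
  jsonlite::write_json(
    list(legend = as.list(attr(labels, "legend")),
         unlabeled_code = attr(labels, "unlabeled_code")),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read evaluation rectangles
#'
#' CSV columns `sample_id, rect_id, row0, col0, row1, col1`; coordinates are
#' 0-based and half-open on disk and converted to 1-based inclusive on read.
#'
#' @param path CSV file.
#' @return tibble with 1-based inclusive `row0, col0, row1, col1`.
#' @export
read_rectangles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "rect_id", "row0", "col0", "row1", "col1")
  if (!all(need %in% names(df))) {
    stop("rectangle CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    sample_id = as.character(df$sample_id),
    rect_id = as.character(df$rect_id),
    row0 = df$row0 + 1L, col0 = df$col0 + 1L,
    row1 = df$row1, col1 = df$col1)   # half-open end == inclusive 1-based end
}
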