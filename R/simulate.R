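# Seeded synthetic MIR cohorts with known ground truth: spectral phantoms for
# the full pipeline and projection-level phantoms for the SA stage.

# white noise smoothed with a separable Gaussian kernel, rescaled to unit sd
smooth_field <- function(nr, nc, sigma) {
  pad <- ceiling(3 * sigma)
  x <- matrix(stats::rnorm((nr + 2 * pad) * (nc + 2 * pad)),
              nr + 2 * pad, nc + 2 * pad)
  k <- stats::dnorm(seq(-pad, pad), sd = sigma)
  k <- k / sum(k)
  # separable convolution, then crop the padding
  x <- apply(x, 2, function(col) stats::filter(col, k, sides = 2))
  x <- t(apply(x, 1, function(row) stats::filter(row, k, sides = 2)))
  x <- x[(pad + 1):(pad + nr), (pad + 1):(pad + nc)]
  x <- x - mean(x)
  x / stats::sd(x)
}

disk_mask <- function(nr, nc, centre, radius) {
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (rr - centre[1])^2 + (cc - centre[2])^2 <= radius^2
}

#' Synthetic cohort specification
#'
#' Defaults describe the emulated study conditions: 64 x 64 pixel sections at
#' 25 um/px, fingerprint-region bands 750-1798 cm^-1 at 4 cm^-1 (263 bands),
#' four tissue types tiling each heterogeneous section as organic blob
#' regions, and one homogeneous control per seven samples carrying a single
#' non-tumour tissue. Each tissue owns one marker band (a peak only it
#' carries) and one anti-marker band (a peak carried by every *other*
#' tissue); after second-derivative + SNV preprocessing the marker becomes a
#' negative predictive feature (npf) and the anti-marker a positive one
#' (ppf), which is what the truth table records.
#'
#' @param n_samples number of sections (default 7).
#' @param image_size `c(rows, cols)` (default 64 x 64).
#' @param tissue_types data frame `tissue`, `marker_wn`, `anti_wn` or `NULL`
#'   for the built-in four-type panel (tumour, stroma, necrosis, parenchyma).
#' @param noise_sd iid absorbance noise sd (default 0.1).
#' @param marker_amplitude peak height of marker/anti-marker bands
#'   (default 1).
#' @param baseline_amplitude smooth baseline drift amplitude (default 0.3).
#' @param band_sigma Gaussian bandwidth of planted peaks, cm^-1 (default 8).
#' @param fraction_homogeneous fraction of samples that are homogeneous
#'   controls (default 1/7).
#' @param homogeneous_tissue tissue of the controls (default "parenchyma").
#' @param region_sigma smoothing length (px) of the blob geometry fields
#'   (default 6).
#' @param batch_gain_sd,batch_offset_sd per-sample multiplicative /
#'   additive batch-effect spread (defaults 0: off).
#' @param pixel_size um per pixel (default 25).
#' @param seed master seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 7, image_size = c(64, 64),
                           tissue_types = NULL, noise_sd = 0.1,
                           marker_amplitude = 1, baseline_amplitude = 0.3,
                           band_sigma = 8, fraction_homogeneous = 1 / 7,
                           homogeneous_tissue = "parenchyma",
                           region_sigma = 6, batch_gain_sd = 0,
                           batch_offset_sd = 0, pixel_size = 25, seed = 1L) {
  if (is.null(tissue_types)) {
    tissue_types <- tibble::tibble(
      tissue = c("tumor", "stroma", "necrosis", "parenchyma"),
      marker_wn = c(1102, 966, 1462, 1742),
      anti_wn = c(1174, 1306, 1610, 1026))
  }
  wn <- seq(750, by = 4, length.out = 263)
  stopifnot(all(tissue_types$marker_wn >= min(wn) & tissue_types$marker_wn <= max(wn)),
            all(tissue_types$anti_wn >= min(wn) & tissue_types$anti_wn <= max(wn)))
  n_hom <- round(n_samples * fraction_homogeneous)
  if (n_samples - n_hom < 1) stop("spec leaves no heterogeneous samples",
                                  call. = FALSE)
  structure(
    list(n_samples = n_samples, image_size = image_size,
         tissue_types = tibble::as_tibble(tissue_types),
         wavenumbers = wn, noise_sd = noise_sd,
         marker_amplitude = marker_amplitude,
         baseline_amplitude = baseline_amplitude, band_sigma = band_sigma,
         n_homogeneous = n_hom, homogeneous_tissue = homogeneous_tissue,
         region_sigma = region_sigma, batch_gain_sd = batch_gain_sd,
         batch_offset_sd = batch_offset_sd, pixel_size = pixel_size,
         seed = as.integer(seed)),
    class = "synthetic_spec")
}

# shared structural absorbance bands present in every tissue (amide-like)
shared_bands <- function() {
  tibble::tibble(centre = c(1080, 1240, 1400, 1548, 1652),
                 amplitude = c(1.5, 1.8, 2.0, 2.5, 3.0))
}

gaussian_band <- function(wn, centre, sigma) exp(-(wn - centre)^2 / (2 * sigma^2))

#' Generate a synthetic MIR cohort
#'
#' Heterogeneous samples tile the on-tissue area into one organic region per
#' tissue type (argmax over smoothed random fields); homogeneous controls
#' carry a single non-tumour tissue everywhere (emulating normal parenchyma
#' resections). Per pixel the absorbance spectrum is the sum of shared
#' structural bands, the tissue's marker band, the anti-marker bands of all
#' *other* tissues, a smooth baseline drift, and iid noise. Deterministic
#' given the spec seed.
#'
#' @param spec a [synthetic_spec()].
#' @return list of samples; each sample is a list with `cube`
#'   ([spectral_cube()]), `mask` ([pixel_mask()]), `labels` ([label_map()]),
#'   `homogeneous` flag and `truth` (tibble of planted `tissue`,
#'   `wavenumber`, `direction` in preprocessed space).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  tt <- spec$tissue_types
  n_tissue <- nrow(tt)
  wn <- spec$wavenumbers
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  legend <- stats::setNames(tt$tissue, as.character(seq_len(n_tissue)))
  truth <- dplyr::bind_rows(lapply(seq_len(n_tissue), function(i) {
    tibble::tibble(
      tissue = tt$tissue[i],
      wavenumber = c(tt$marker_wn[i], tt$anti_wn[i]),
      direction = c("npf", "ppf"))
  }))
  # spectral templates per tissue (marker + everyone else's anti-markers)
  templates <- lapply(seq_len(n_tissue), function(i) {
    s <- rep(0, length(wn))
    for (b in seq_len(nrow(shared_bands()))) {
      s <- s + shared_bands()$amplitude[b] *
        gaussian_band(wn, shared_bands()$centre[b], spec$band_sigma)
    }
    s <- s + spec$marker_amplitude *
      gaussian_band(wn, tt$marker_wn[i], spec$band_sigma)
    for (j in setdiff(seq_len(n_tissue), i)) {
      s <- s + spec$marker_amplitude *
        gaussian_band(wn, tt$anti_wn[j], spec$band_sigma)
    }
    s
  })
  is_hom <- rep(FALSE, spec$n_samples)
  if (spec$n_homogeneous > 0) {
    is_hom[seq(spec$n_samples, by = -1L, length.out = spec$n_homogeneous)] <-
      TRUE
  }
  hom_code <- which(tt$tissue == spec$homogeneous_tissue)
  if (!length(hom_code)) stop("homogeneous_tissue not in tissue panel",
                              call. = FALSE)
  with_local_seed(spec$seed, {
    lapply(seq_len(spec$n_samples), function(s) {
      # tissue support: a large organic blob covering most of the section
      supp <- smooth_field(nr, nc, spec$region_sigma) +
        2 * exp(-((matrix(seq_len(nr), nr, nc) - nr / 2)^2 +
                    (matrix(seq_len(nc), nr, nc, byrow = TRUE) - nc / 2)^2) /
                  (2 * (nr / 2.5)^2))
      mask <- supp > stats::quantile(supp, 0.2)
      if (is_hom[s]) {
        lab <- matrix(0L, nr, nc)
        lab[mask] <- hom_code
      } else {
        fields <- lapply(seq_len(n_tissue), function(i) {
          smooth_field(nr, nc, spec$region_sigma)
        })
        arg <- apply(array(unlist(fields), c(nr, nc, n_tissue)), c(1, 2),
                     which.max)
        lab <- matrix(0L, nr, nc)
        lab[mask] <- arg[mask]
      }
      # baseline drift: smooth-in-space amplitude times a slow spectral ramp
      drift_amp <- spec$baseline_amplitude * smooth_field(nr, nc, 12)
      ramp <- (wn - min(wn)) / diff(range(wn))
      gain <- 1 + stats::rnorm(1, 0, spec$batch_gain_sd)
      offset <- stats::rnorm(1, 0, spec$batch_offset_sd)
      vals <- array(0, c(nr, nc, length(wn)))
      flat <- matrix(0, nr * nc, length(wn))
      for (i in seq_len(n_tissue)) {
        px <- which(lab == i)
        if (length(px)) {
          flat[px, ] <- matrix(templates[[i]], length(px), length(wn),
                               byrow = TRUE)
        }
      }
      flat <- flat + outer(as.vector(drift_amp), ramp)
      flat <- gain * flat + offset +
        matrix(stats::rnorm(length(flat), 0, spec$noise_sd), nrow(flat))
      vals[] <- flat
      cube <- spectral_cube(vals, wn, spec$pixel_size,
                            sprintf("synth_%02d", s))
      list(cube = cube, mask = pixel_mask(mask),
           labels = label_map(lab, legend, 0L),
           homogeneous = is_hom[s], truth = truth)
    })
  })
}

#' Digitally punch circular cores from a sample
#'
#' Emulates biopsy-needle cores taken from a resection image: a circular
#' crop of cube, mask and labels around each centre. The core diameter in
#' pixels is `round(diameter_um / pixel_size_um)` (e.g. 825 um at 25 um/px
#' gives 33 px).
#'
#' @param sample list with `cube`, `mask`, `labels` (as one element of
#'   [generate_cohort()]'s output, or equivalents from real data).
#' @param centers list/matrix of `(row, col)` centres.
#' @param diameter_um core diameter in micrometres (default 825, a common
#'   G18-needle scale).
#' @param pixel_size_um lateral pixel size (default: the cube's).
#' @return list of core samples (`cube`, `mask`, `labels`, `centre`,
#'   `diameter_px`), each cropped to the core's bounding box with the mask
#'   restricted to the circle.
#' @export
punch_cores <- function(sample, centers, diameter_um = 825,
                        pixel_size_um = NULL) {
  cube <- sample$cube
  if (is.null(pixel_size_um)) pixel_size_um <- cube$pixel_size
  d_px <- round(diameter_um / pixel_size_um)
  radius <- d_px / 2
  if (is.matrix(centers)) centers <- asplit(centers, 1)
  nr <- dim(cube$values)[1]; nc <- dim(cube$values)[2]
  lapply(centers, function(ctr) {
    ctr <- as.numeric(ctr)
    if (ctr[1] - radius < 0.5 || ctr[1] + radius > nr + 0.5 ||
        ctr[2] - radius < 0.5 || ctr[2] + radius > nc + 0.5) {
      stop("core at (", ctr[1], ",", ctr[2], ") falls outside the image",
           call. = FALSE)
    }
    circ <- disk_mask(nr, nc, ctr, radius)
    rr <- range(which(rowSums(circ) > 0))
    cc <- range(which(colSums(circ) > 0))
    rows <- rr[1]:rr[2]; cols <- cc[1]:cc[2]
    sub_mask <- circ[rows, cols] & as.matrix(sample$mask)[rows, cols]
    lab <- matrix(sample$labels[rows, cols], length(rows))
    lab[!sub_mask] <- attr(sample$labels, "unlabeled_code")
    list(
      cube = spectral_cube(cube$values[rows, cols, , drop = FALSE],
                           cube$wavenumbers, cube$pixel_size,
                           paste0(cube$sample_id, "_core")),
      mask = pixel_mask(sub_mask),
      labels = label_map(lab, attr(sample$labels, "legend"),
                         attr(sample$labels, "unlabeled_code")),
      centre = ctr, diameter_px = d_px)
  })
}

#' Projection-level SA phantoms
#'
#' Generates per-sample projection images with known hotspot ground truth,
#' for benchmarking the spatial-autocorrelation stage directly: a standard
#' normal background plus correlated spatial texture, with organic
#' high-intensity blobs planted at `contrast` standard deviations in
#' heterogeneous samples. Homogeneous controls carry no blobs — only the
#' low-intensity background — emulating a normal-parenchyma resection
#' processed alongside tumour-bearing sections.
#'
#' @param n_samples number of samples (default 7).
#' @param image_size `c(rows, cols)` (default 64 x 64).
#' @param contrast blob elevation in background-sd units (default 4).
#' @param noise_sd iid background noise sd (default 1).
#' @param texture_sd sd of the correlated texture component (default 0.5).
#' @param n_blobs planted blobs per heterogeneous sample (default 2).
#' @param blob_radius mean blob radius in px (default 9).
#' @param fraction_homogeneous fraction of homogeneous controls
#'   (default 1/7).
#' @param tissue_type tissue label carried by the projections.
#' @param seed master seed.
#' @return list of samples: `projection` ([projection_image()]), `truth`
#'   (logical matrix of planted hotspot pixels), `homogeneous` flag.
#' @export
simulate_projection_cohort <- function(n_samples = 7, image_size = c(64, 64),
                                       contrast = 4, noise_sd = 1,
                                       texture_sd = 0.5, n_blobs = 2,
                                       blob_radius = 9,
                                       fraction_homogeneous = 1 / 7,
                                       tissue_type = "tumor", seed = 1L) {
  nr <- image_size[1]; nc <- image_size[2]
  if (min(nr, nc) <= 2 * (blob_radius + 2)) {
    stop("infeasible geometry: blobs of radius ", blob_radius,
         " do not fit a ", nr, "x", nc, " image", call. = FALSE)
  }
  n_hom <- round(n_samples * fraction_homogeneous)
  is_hom <- rep(FALSE, n_samples)
  if (n_hom > 0) {
    is_hom[seq(n_samples, by = -1L, length.out = n_hom)] <- TRUE
  }
  with_local_seed(seed, {
    lapply(seq_len(n_samples), function(s) {
      vals <- matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc) +
        texture_sd * smooth_field(nr, nc, 4)
      truth <- matrix(FALSE, nr, nc)
      if (!is_hom[s]) {
        for (b in seq_len(n_blobs)) {
          ctr <- c(stats::runif(1, blob_radius + 2, nr - blob_radius - 2),
                   stats::runif(1, blob_radius + 2, nc - blob_radius - 2))
          rad <- blob_radius * stats::runif(1, 0.8, 1.2)
          truth <- truth | disk_mask(nr, nc, ctr, rad)
        }
        vals[truth] <- vals[truth] + contrast * noise_sd
      }
      proj <- projection_image(vals + 10, matrix(TRUE, nr, nc), tissue_type,
                               baseline = 10,
                               sample_id = sprintf("phantom_%02d", s))
      list(projection = proj, truth = truth, homogeneous = is_hom[s])
    })
  })
}
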