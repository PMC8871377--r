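#' Synthetic OCT B-scan generator configuration
#'
#' Parameters controlling the seeded synthetic B-scan generator. Generated
#' scans emulate the qualitative morphology that distinguishes AMD from
#' normal retina on OCT: a stack of roughly horizontal bright retinal bands
#' over a dark background for normal scans, localized upward bumps (drusen)
#' on the lowest bright band (the retinal pigment epithelium, RPE) for dry
#' AMD, and a dark sub-retinal fluid dome elevating the central bands for
#' wet AMD. Multiplicative speckle noise is applied last.
#'
#' @param height,width canvas size in pixels.
#' @param n_layers number of bright retinal bands (>= 2).
#' @param layer_contrast intensity gap between bands and background, in
#'   `[0, 1]`. At 0 the bands (and the fluid dome's darkening) vanish and the
#'   image is pure speckle: labels then carry no pixel information, which is
#'   the "impossible" end of the difficulty dial.
#' @param speckle_sd standard deviation of the multiplicative speckle
#'   multiplier `1 + eps`, `eps ~ N(0, speckle_sd^2)` (truncated below at 0).
#' @param drusen_count number of drusen bumps for dry AMD (>= 1).
#' @param drusen_amplitude peak RPE elevation of each druse, pixels; must be
#'   `< height / 4` so lesions stay inside the frame.
#' @param drusen_width Gaussian width (sd) of each druse, pixels.
#' @param fluid_depth dome height of the wet-AMD sub-retinal fluid pocket,
#'   pixels; must be `< height / 3`.
#' @param fluid_width full width of the fluid dome's compact support, pixels.
#' @param tilt_jitter maximum random global tilt of the retina, pixels
#'   (edge-to-center displacement).
#' @param seed integer seed; identical configuration (seed included) gives
#'   bit-identical output.
#' @param preset `"custom"` (use arguments as given), `"easy"` (low noise,
#'   large lesions: the separable end of the difficulty dial) or `"noise"`
#'   (zero layer contrast, heavy speckle: structureless images whose labels
#'   are independent of the pixels).
#' @return a `synth_config` list.
#' @export
#' @examples
#' cfg <- synth_config(seed = 7)
#' img <- generate_normal(cfg)
#' dim(img$pixels)
synth_config <- function(height = 224, width = 224, n_layers = 5,
                         layer_contrast = 0.5, speckle_sd = 0.08,
                         drusen_count = 3, drusen_amplitude = 12,
                         drusen_width = 8, fluid_depth = 30,
                         fluid_width = 90, tilt_jitter = 6, seed = 1,
                         preset = c("custom", "easy", "noise")) {
  preset <- match.arg(preset)
  if (preset == "easy") {
    speckle_sd <- 0.02
    layer_contrast <- 0.5
    drusen_amplitude <- 14
    fluid_depth <- 30
  } else if (preset == "noise") {
    layer_contrast <- 0
    speckle_sd <- 0.15
  }
  assert_positive_int(height, "height")
  assert_positive_int(width, "width")
  assert_positive_int(n_layers, "n_layers")
  if (n_layers < 2) abort("`n_layers` must be >= 2")
  if (layer_contrast < 0 || layer_contrast > 1) {
    abort("`layer_contrast` must lie in [0, 1]")
  }
  if (speckle_sd < 0) abort("`speckle_sd` must be >= 0")
  if (drusen_count < 0 || drusen_count != floor(drusen_count)) {
    abort("`drusen_count` must be a non-negative integer")
  }
  if (drusen_amplitude < 0 || drusen_amplitude >= height / 4) {
    abort("`drusen_amplitude` must lie in [0, height/4)")
  }
  if (fluid_depth < 0 || fluid_depth >= height / 3) {
    abort("`fluid_depth` must lie in [0, height/3)")
  }
  if (drusen_count > 0 && drusen_width * 6 * (drusen_count + 1) > width) {
    abort("drusen geometry does not fit: reduce `drusen_count` or `drusen_width`")
  }
  if (fluid_width >= width) abort("`fluid_width` must be smaller than `width`")
  structure(
    list(height = as.integer(height), width = as.integer(width),
         n_layers = as.integer(n_layers), layer_contrast = layer_contrast,
         speckle_sd = speckle_sd, drusen_count = as.integer(drusen_count),
         drusen_amplitude = drusen_amplitude, drusen_width = drusen_width,
         fluid_depth = fluid_depth, fluid_width = fluid_width,
         tilt_jitter = tilt_jitter, seed = as.integer(seed)),
    class = "synth_config")
}

# Smooth per-band wiggle: two low-frequency sinusoids with random phase.
band_wiggle <- function(width, amplitude = 1.5) {
  x <- seq_len(width) / width
  amplitude * (sin(2 * pi * (stats::runif(1, 0.5, 1.5) * x + stats::runif(1))) * 0.7 +
               sin(2 * pi * (stats::runif(1, 2, 3) * x + stats::runif(1))) * 0.3)
}

# Band centerlines shared by all three classes: evenly spaced rows between
# 35% and 72% of the canvas height, a common parabolic sag, a global tilt
# drawn within +/- tilt_jitter, and a small smooth per-band wiggle. Rows grow
# downward, so "elevation" subtracts from a centerline.
base_centerlines <- function(config) {
  h <- config$height; w <- config$width; L <- config$n_layers
  x <- seq_len(w)
  xc <- (x - (w + 1) / 2) / ((w + 1) / 2)           # [-1, 1] across columns
  tilt <- stats::runif(1, -config$tilt_jitter, config$tilt_jitter)
  sag <- stats::runif(1, 0, 0.03 * h)
  common <- tilt * xc + sag * xc^2
  tops <- seq(0.35 * h, 0.72 * h, length.out = L)
  cl <- matrix(0, nrow = L, ncol = w)
  for (b in seq_len(L)) {
    cl[b, ] <- tops[b] + common + band_wiggle(w)
  }
  cl
}

# Render bands as additive Gaussian intensity profiles over a dark
# background, then fill the fluid region (if any) below the elevated RPE.
render_scan <- function(config, centerlines, fluid = NULL) {
  h <- config$height; w <- config$width
  bg <- 0.08
  sigma <- 2.5
  img <- matrix(bg, nrow = h, ncol = w)
  if (!is.null(fluid)) {
    # dark serous fluid: pocket between the elevated RPE and its baseline
    fl_val <- max(0, bg * (1 - config$layer_contrast / 0.5))
    for (j in which(fluid$cols)) {
      lo <- ceiling(fluid$top[j]); hi <- floor(fluid$bottom[j])
      if (hi >= lo) img[max(1, lo):min(h, hi), j] <- fl_val
    }
  }
  rows <- seq_len(h)
  for (j in seq_len(w)) {
    prof <- rep(0, h)
    for (b in seq_len(nrow(centerlines))) {
      prof <- prof + exp(-(rows - centerlines[b, j])^2 / (2 * sigma^2))
    }
    img[, j] <- img[, j] + config$layer_contrast * prof
  }
  pmin(img, 1)
}

apply_speckle <- function(img, sd) {
  if (sd <= 0) return(img)
  mult <- pmax(0, 1 + stats::rnorm(length(img), sd = sd))
  pmin(pmax(img * mult, 0), 1)
}

new_oct_image <- function(pixels, label, meta) {
  structure(
    list(pixels = pixels, label = label,
         binary_label = if (label == "NORMAL") "NORMAL" else "AMD",
         meta = meta),
    class = "oct_image")
}

#' Generate a synthetic normal B-scan
#'
#' @param config a [synth_config()].
#' @param seed overrides `config$seed` when given.
#' @return an `oct_image`: `pixels` (height x width matrix in `[0, 1]`),
#'   `label`, derived `binary_label`, and `meta` holding the noise-free band
#'   centerlines and their pre-lesion baseline (used by downstream tests and
#'   by the lesion generators).
#' @export
generate_normal <- function(config, seed = config$seed) {
  with_seed(seed, {
    cl <- base_centerlines(config)
    img <- apply_speckle(render_scan(config, cl), config$speckle_sd)
    new_oct_image(img, "NORMAL",
                  list(centerlines = cl, baseline = cl, seed = seed))
  })
}

#' Generate a synthetic dry-AMD B-scan (drusen)
#'
#' Drusen are rendered as localized Gaussian upward bumps on the lowest
#' bright band (the RPE surrogate). Bump centers are placed one per equal
#' segment of the usable width, which guarantees the per-druse deviation
#' intervals are disjoint.
#'
#' @inheritParams generate_normal
#' @return an `oct_image` labeled `DRY_AMD`; `meta$baseline` holds the
#'   undeformed RPE centerline and `meta$lesion_cols` the columns whose RPE
#'   deviates by more than a quarter pixel.
#' @export
generate_dry_amd <- function(config, seed = config$seed) {
  if (config$drusen_count < 1) {
    abort("dry AMD requires `drusen_count` >= 1 (otherwise the scan is an unlabeled normal)")
  }
  if (config$drusen_amplitude <= 0) {
    abort("dry AMD requires `drusen_amplitude` > 0: a zero-height druse is no lesion")
  }
  with_seed(seed, {
    cl <- base_centerlines(config)
    baseline <- cl
    w <- config$width; nd <- config$drusen_count
    dw <- config$drusen_width; amp <- config$drusen_amplitude
    margin <- 3 * dw
    seg <- (w - 2 * margin) / nd
    centers <- margin + (seq_len(nd) - 1) * seg +
      stats::runif(nd, min(3 * dw, seg / 2), max(seg - 3 * dw, seg / 2))
    x <- seq_len(w)
    bump <- rep(0, w)
    for (cx in centers) bump <- bump + amp * exp(-(x - cx)^2 / (2 * dw^2))
    rpe <- nrow(cl)
    cl[rpe, ] <- cl[rpe, ] - bump       # upward deformation of the RPE
    img <- apply_speckle(render_scan(config, cl), config$speckle_sd)
    new_oct_image(img, "DRY_AMD",
                  list(centerlines = cl, baseline = baseline,
                       drusen_centers = centers, lesion_cols = bump > 0.25,
                       seed = seed))
  })
}

#' Generate a synthetic wet-AMD B-scan (sub-retinal fluid)
#'
#' A raised-cosine dome of height `fluid_depth` and compact support
#' `fluid_width` elevates all retinal bands around a central column; the
#' pocket between the elevated RPE and its flat baseline is filled with dark
#' serous fluid.
#'
#' @inheritParams generate_normal
#' @return an `oct_image` labeled `WET_AMD`; `meta$elevation` holds the
#'   per-column dome profile.
#' @export
generate_wet_amd <- function(config, seed = config$seed) {
  if (config$fluid_depth < 1) {
    abort("wet AMD requires `fluid_depth` >= 1")
  }
  with_seed(seed, {
    cl <- base_centerlines(config)
    baseline <- cl
    if (min(cl[1, ]) - config$fluid_depth < 3) {
      abort("fluid geometry exceeds the frame: reduce `fluid_depth`")
    }
    w <- config$width
    half <- config$fluid_width / 2
    cx <- (w + 1) / 2 + stats::runif(1, -0.1, 0.1) * w
    x <- seq_len(w)
    inside <- abs(x - cx) < half
    elev <- ifelse(inside,
                   config$fluid_depth * 0.5 * (1 + cos(pi * (x - cx) / half)),
                   0)
    cl <- sweep(cl, 2, elev, `-`)       # macula rises: all bands shift up
    rpe <- nrow(baseline)
    fluid <- list(cols = elev > 0.5,
                  top = cl[rpe, ] + 2,       # just beneath the elevated RPE
                  bottom = baseline[rpe, ] + 2)
    img <- apply_speckle(render_scan(config, cl, fluid = fluid),
                         config$speckle_sd)
    new_oct_image(img, "WET_AMD",
                  list(centerlines = cl, baseline = baseline,
                       elevation = elev, lesion_cols = elev > 0.25,
                       fluid = fluid, seed = seed))
  })
}

#' Generate a labeled synthetic dataset
#'
#' Per-image RNG streams are derived from the top-level seed by
#' counter-based splitting (class stream x image counter), so the per-class
#' counts never perturb the pixels of other images; the final shuffle uses
#' its own derived stream.
#'
#' @param config a [synth_config()].
#' @param n_normal,n_dry,n_wet per-class image counts (>= 0).
#' @param seed top-level seed; defaults to `config$seed`.
#' @return an `oct_imageset`: `images` (list of `oct_image`) and `manifest`
#'   (a tibble with `id`, `label`, `binary_label`, `seed`, aligned with
#'   `images`).
#' @export
generate_dataset <- function(config, n_normal, n_dry, n_wet,
                             seed = config$seed) {
  counts <- c(NORMAL = n_normal, DRY_AMD = n_dry, WET_AMD = n_wet)
  if (any(counts < 0)) abort("per-class counts must be >= 0")
  gens <- list(NORMAL = generate_normal, DRY_AMD = generate_dry_amd,
               WET_AMD = generate_wet_amd)
  images <- list()
  for (ci in seq_along(counts)) {
    cls <- names(counts)[ci]
    n <- counts[[ci]]
    if (n == 0) next
    imgs <- map(seq_len(n), function(i) {
      gens[[cls]](config, seed = derive_seed(seed, ci, i))
    })
    images <- c(images, imgs)
  }
  if (length(images) > 1) {
    ord <- with_seed(derive_seed(seed, 99L), sample.int(length(images)))
    images <- images[ord]
  }
  manifest <- tibble(
    id = sprintf("img_%04d", seq_along(images)),
    label = map_chr(images, "label"),
    binary_label = map_chr(images, "binary_label"),
    seed = map_int(images, function(im) im$meta$seed))
  structure(list(images = images, manifest = manifest),
            class = "oct_imageset")
}

#' @importFrom purrr map_chr
#' @export
print.oct_imageset <- function(x, ...) {
  cat(sprintf("<oct_imageset> %d images\n", length(x$images)))
  print(dplyr::count(x$manifest, .data$label))
  invisible(x)
}

#' Write an image set to disk
#'
#' Writes one PNG per image into `<dir>/<label>/` plus a `manifest.csv`
#' (filename, label, binary_label, seed) at the root, mirroring the
#' folder-per-class layout of the public OCT datasets.
#'
#' @param imageset an `oct_imageset`.
#' @param dir output directory (created if missing).
#' @return the manifest tibble, invisibly, with a `path` column added.
#' @export
write_imageset <- function(imageset, dir) {
  stopifnot(inherits(imageset, "oct_imageset"))
  for (lab in unique(imageset$manifest$label)) {
    dir.create(file.path(dir, lab), recursive = TRUE, showWarnings = FALSE)
  }
  paths <- character(length(imageset$images))
  for (i in seq_along(imageset$images)) {
    im <- imageset$images[[i]]
    paths[i] <- file.path(dir, im$label,
                          paste0(imageset$manifest$id[i], ".png"))
    # EBImage indexes (x, y); transpose so rows render as image rows
    EBImage::writeImage(t(im$pixels), paths[i])
  }
  manifest <- dplyr::mutate(imageset$manifest, path = paths)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
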