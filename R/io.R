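#' Scan a folder-per-class image directory
#'
#' Enumerates `root/<LABEL>/*.{png,jpg,jpeg,tif,tiff}` deterministically
#' (sorted paths). Files that fail to decode are kept in the manifest and
#' flagged, never silently dropped.
#'
#' @param root dataset root containing one subdirectory per class label
#'   (`NORMAL`, `AMD`, or `NORMAL`/`DRY_AMD`/`WET_AMD`).
#' @param check decode every file to flag corrupt entries (slower).
#' @return tibble with `path`, `label`, `binary_label`, `ok`.
#' @export
scan_dataset <- function(root, check = TRUE) {
  if (!dir.exists(root)) abort(sprintf("dataset root does not exist: %s", root))
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  known <- c("NORMAL", "AMD", "DRY_AMD", "WET_AMD")
  classes <- intersect(classes, known)
  if (length(classes) == 0) {
    abort(sprintf("no class subfolders (%s) under %s",
                  paste(known, collapse = "/"), root))
  }
  rows <- list()
  for (cl in classes) {
    files <- sort(list.files(file.path(root, cl),
                             pattern = "\\.(png|jpg|jpeg|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0) next
    ok <- rep(TRUE, length(files))
    if (check) {
      for (i in seq_along(files)) {
        ok[i] <- !inherits(try(suppressWarnings(
          EBImage::readImage(files[i])), silent = TRUE), "try-error")
      }
    }
    rows[[cl]] <- tibble(path = files, label = cl,
                         binary_label = if (cl == "NORMAL") "NORMAL" else "AMD",
                         ok = ok)
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) abort(sprintf("no images found under %s", root))
  out
}

#' Load one image as a standardized array
#'
#' Decodes a PNG/JPEG/TIFF, converts to grayscale-replicated RGB, rescales
#' intensities to `[0, 1]` and bilinearly resizes to `target_size`, the
#' input contract of the embedding network (224 x 224 x 3 by default).
#'
#' @param path image file.
#' @param target_size `c(height, width)`.
#' @param channels number of output channels (grayscale replicated).
#' @return numeric array `height x width x channels` in `[0, 1]`.
#' @export
load_image <- function(path, target_size = c(224, 224), channels = 3) {
  img <- tryCatch(suppressWarnings(EBImage::readImage(path)),
                  error = function(e) {
    abort(sprintf("cannot decode image %s: %s", path, conditionMessage(e)))
  })
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3) dat <- rowMeans(dat, dims = 2)  # to grayscale
  gray <- t(dat)                                   # EBImage stores (x, y)
  gray <- pmin(pmax(gray, 0), 1)
  h <- target_size[1]; w <- target_size[2]
  if (nrow(gray) != h || ncol(gray) != w) {
    gray <- t(EBImage::imageData(EBImage::resize(EBImage::Image(t(gray)),
                                                 w = w, h = h)))
    gray <- pmin(pmax(gray, 0), 1)
  }
  array(rep(gray, channels), c(h, w, channels))
}

#' Load a scanned dataset into memory
#'
#' Builds an `oct_imageset` from a [scan_dataset()] manifest (or a root
#' directory). Unreadable images are skipped with a warning, so one corrupt
#' file never aborts a screening batch.
#'
#' @param x a manifest tibble from [scan_dataset()], or a root directory.
#' @param target_size image size passed to [load_image()].
#' @return an `oct_imageset`.
#' @export
load_imageset <- function(x, target_size = c(224, 224)) {
  manifest <- if (is.character(x)) scan_dataset(x) else x
  images <- list(); keep <- logical(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    px <- tryCatch(load_image(manifest$path[i], target_size),
                   error = function(e) NULL)
    if (is.null(px)) {
      warn(sprintf("skipping unreadable image: %s", manifest$path[i]))
      next
    }
    keep[i] <- TRUE
    images[[length(images) + 1]] <- structure(
      list(pixels = px, label = manifest$label[i],
           binary_label = manifest$binary_label[i],
           meta = list(path = manifest$path[i])),
      class = "oct_image")
  }
  kept <- manifest[keep, ]
  kept$id <- if ("id" %in% names(kept)) kept$id else basename(kept$path)
  structure(list(images = images, manifest = kept), class = "oct_imageset")
}
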