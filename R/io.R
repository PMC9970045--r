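# Manifest and image I/O. Manifests are CSV (image_id, path, optional
# region_label / mask_path); images are 8-bit 3-channel PNG or TIFF.

#' Read and validate a cohort manifest
#'
#' @param path CSV file with a header containing at least `image_id` and
#'   `path` columns; `region_label` and `mask_path` are optional.
#' @return A data frame of class `cohort_manifest`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop_stainref("schema", "manifest file not found: %s", path)
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "path")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols))
    stop_stainref("schema", "manifest schema: missing column(s) %s",
                  paste(missing_cols, collapse = ", "))
  dup <- unique(m$image_id[duplicated(m$image_id)])
  if (length(dup))
    stop_stainref("schema", "duplicate id(s) in manifest: %s",
                  paste(dup, collapse = ", "))
  gone <- m$path[!file.exists(m$path)]
  if (length(gone))
    stop_stainref("data", "manifest path(s) do not exist: %s",
                  paste(gone, collapse = ", "))
  class(m) <- c("cohort_manifest", class(m))
  m
}

#' Read an 8-bit RGB image
#'
#' Supports PNG and TIFF. An alpha channel is dropped with a warning;
#' grayscale or 16-bit inputs are rejected.
#'
#' @param path image file path.
#' @return rows x cols x 3 numeric array of intensities in \[0, 255\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    if (!is.null(info$bit.depth) && info$bit.depth > 8)
      stop_stainref("data", "unsupported bit depth (%d) in %s",
                    info$bit.depth, path)
    vals <- img * 255
  } else if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(raw, "bits.per.sample")
    if (!is.null(bits) && bits > 8)
      stop_stainref("data", "unsupported bit depth (%d) in %s", bits, path)
    vals <- raw * 255
  } else {
    stop_stainref("schema", "unsupported image format: %s", path)
  }
  if (length(dim(vals)) != 3L)
    stop_stainref("data", "not a 3-channel image: %s", path)
  if (dim(vals)[3] == 4L) {
    warning(sprintf("alpha channel dropped: %s", path))
    vals <- vals[, , 1:3, drop = FALSE]
  }
  if (dim(vals)[3] != 3L)
    stop_stainref("data", "unsupported channel count (%d) in %s",
                  dim(vals)[3], path)
  out <- round(vals)
  attributes(out) <- list(dim = dim(out))
  out
}

#' Write an 8-bit RGB (or grayscale) image
#'
#' PNG round-trips integer 8-bit data losslessly; TIFF is written
#' uncompressed.
#'
#' @param img rows x cols x 3 array in \[0, 255\], or a matrix in \[0, 1\]
#'   for grayscale PNG export.
#' @param path destination (`.png`, `.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  scaled <- if (is.matrix(img)) img else img / 255
  if (ext == "png") {
    png::writePNG(scaled, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, compression = "none")
  } else {
    stop_stainref("schema", "unsupported image format: %s", path)
  }
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' Writes one PNG per tile, a manifest CSV (`image_id`, `path`) and a
#' ground-truth JSON (stain matrices, lab factors, gamma parameters,
#' seeds), making the generated cohort consumable by the manifest-based
#' pipeline.
#'
#' @param cohort a [make_cohort()] result.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- attr(cohort, "spec")
  paths <- vapply(cohort, function(el) {
    p <- file.path(dir, paste0(el$id, ".png"))
    write_image(el$image, p)
    p
  }, character(1))
  manifest <- data.frame(image_id = vapply(cohort, `[[`, character(1), "id"),
                         path = paths)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  truth <- list(
    spec = spec[setdiff(names(spec), "base_stain_matrix")],
    base_stain_matrix = spec$base_stain_matrix,
    images = lapply(cohort, function(el)
      list(id = el$id, w_true = el$w_true, lab_factor = el$lab_factor,
           seed = el$seed))
  )
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(mpath)
}

#' Load the images of a manifest
#'
#' @param manifest a `cohort_manifest` (or path to one).
#' @return Named list of RGB arrays, names = `image_id`.
#' @export
load_cohort_images <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stats::setNames(lapply(manifest$path, read_image), manifest$image_id)
}

#' Serialize / deserialize a convergence report
#'
#' JSON round-trip at full floating-point precision.
#'
#' @param report a `convergence_report`.
#' @param path JSON destination / source.
#' @return `write_report`: `path` invisibly; `read_report`: the report.
#' @export
write_report <- function(report, path) {
  payload <- list(
    subset_sizes = report$subset_sizes,
    labic = lapply(report$labic, unclass),
    sd_per_perm = report$sd_per_perm,
    range_per_size = as.list(report$range_per_size),
    levene_vs_next = report$levene_vs_next,
    failed = report$failed, seed = report$seed
  )
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  labic <- lapply(x$labic, function(m) {
    if (is.matrix(m)) m
    else matrix(unlist(m), nrow = length(m), byrow = TRUE)
  })
  structure(list(subset_sizes = x$subset_sizes, labic = labic,
                 sd_per_perm = x$sd_per_perm,
                 range_per_size = unlist(x$range_per_size),
                 levene_vs_next = x$levene_vs_next, failed = x$failed,
                 seed = x$seed),
            class = "convergence_report")
}
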