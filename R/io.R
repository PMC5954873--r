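#' Load a scanned plate image
#'
#' Reads a grayscale PNG or TIFF, rescales intensities to `[0, 1]` and
#' attaches the lane layout.  Colour scans must declare how to collapse
#' channels; scans with dark background (spots lighter than background) can be
#' inverted on load so that downstream code always sees dark spots on a light
#' background.
#'
#' @param path image file (`.png`, `.tif`/`.tiff`).
#' @param layout a [lane_layout()] describing the plate.
#' @param channel channel policy for colour images: `"error"` (default),
#'   `"mean"`, `"luma"` (Rec. 601 weights) or a channel index.
#' @param invert logical; flip intensities (`1 - x`) for dark-background scans.
#' @param solvent_system_id carried into the plate metadata.
#' @return An object of class `sqtlc_plate` (without ground truth).
#' @export
load_plate_image <- function(path, layout, channel = "error",
                             invert = FALSE, solvent_system_id = NA) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(arr)) == 3) {
    if (identical(channel, "error"))
      stop("colour image; declare a channel policy ",
           "(channel = \"mean\", \"luma\" or an index)", call. = FALSE)
    arr <- if (identical(channel, "mean")) {
      apply(arr[, , 1:min(3, dim(arr)[3]), drop = FALSE], c(1, 2), mean)
    } else if (identical(channel, "luma")) {
      0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else arr[, , as.integer(channel)]
  }
  if (!is.matrix(arr)) stop("image did not decode to a 2-D raster",
                            call. = FALSE)
  rng <- range(arr)
  if (rng[2] > 1 || rng[1] < 0)  # non-normalised readers; rescale defensively
    arr <- (arr - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  if (invert) arr <- 1 - arr
  validate_lane_layout(layout)
  if (layout$origin_y > nrow(arr) || layout$front_y < 1 ||
      max(layout$application_xs) > ncol(arr))
    stop("layout out of raster bounds", call. = FALSE)
  structure(list(pixels = arr, layout = layout, truth = NULL, spec = NULL,
                 provenance = list(source = path),
                 solvent_system_id = solvent_system_id),
            class = "sqtlc_plate")
}

#' Write a plate image to disk
#'
#' @param plate an `sqtlc_plate` (or a numeric matrix in `[0, 1]`).
#' @param path output file; format chosen by extension (`.png` 8-bit,
#'   `.tif`/`.tiff` 16-bit grayscale).
#' @return `path`, invisibly.
#' @export
write_plate_image <- function(plate, path) {
  px <- if (is.matrix(plate)) plate else plate$pixels
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(px, path),
    tif = ,
    tiff = tiff::writeTIFF(px, path, bits.per.sample = 16),
    stop("unsupported image format: .", ext, call. = FALSE))
  invisible(path)
}

#' Read / write a lane-layout sidecar
#'
#' Layout sidecars are JSON (or YAML, if the `yaml` package is available)
#' files with keys `origin_y`, `front_y`, `application_xs`, `lane_half_width`,
#' `rs_amounts_ug` and `test_lane_index`.
#'
#' @param path sidecar file (`.json`, `.yml`/`.yaml`).
#' @return `read_layout()` returns a [lane_layout()]; `write_layout()` returns
#'   `path` invisibly.
#' @export
read_layout <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML sidecars", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  lane_layout(lst$origin_y, lst$front_y, lst$application_xs,
              lane_half_width = lst$lane_half_width,
              rs_amounts_ug = lst$rs_amounts_ug,
              test_lane_index = lst$test_lane_index)
}

#' @rdname read_layout
#' @param layout a [lane_layout()].
#' @export
write_layout <- function(layout, path) {
  lst <- unclass(layout)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML sidecars", call. = FALSE)
    yaml::write_yaml(lst, path)
  } else jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write ground truth / detections to CSV
#'
#' @param x data frame (plate `truth` or a detections table).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spot_csv <- function(x, path) {
  x <- x[, setdiff(names(x), "region"), drop = FALSE]  # drop pixel lists
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
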