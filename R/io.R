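# Image and histogram I/O. Digital images are stored as 16-bit grayscale
# TIFF; expected images as 32-bit float TIFF divided by a power-of-two scale
# (an exact mantissa shift). A JSON sidecar (<path>.json) carries the units
# tag and reconstruction metadata, since baseline TIFF tags cannot hold
# arbitrary key-values portably.

#' Write an image to TIFF (with JSON metadata sidecar)
#'
#' `digital_image`s are written as 16-bit integer grayscale TIFF;
#' `expected_image`s as 32-bit float TIFF scaled by a power of two recorded
#' in the sidecar, so the round trip is exact at float32 precision (bit-exact
#' for digital images). The sidecar `<path>.json` records the units tag,
#' class, and scale.
#'
#' @param image An `expected_image` or `digital_image`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  if (inherits(image, "digital_image")) {
    meta <- list(class = "digital_image", units = attr(image, "units"),
                 bit_depth = attr(image, "bit_depth"),
                 saturated = isTRUE(attr(image, "saturated")),
                 scale = 65535)
    tiff::writeTIFF(unclass(image) / 65535, path, bits.per.sample = 16L,
                    compression = "none")
  } else if (inherits(image, "expected_image")) {
    mx <- max(image, 0)
    scale <- if (mx <= 0) 1 else 2^ceiling(log2(mx))
    meta <- list(class = "expected_image", units = attr(image, "units"),
                 pixel_pitch_um = attr(image, "pixel_pitch_um"),
                 scale = scale)
    tiff::writeTIFF(unclass(image) / scale, path, bits.per.sample = 32L,
                    compression = "none", reduce = FALSE)
  } else stop_arg("'image' must be an expected_image or digital_image")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image written by [write_image()]
#'
#' @param path TIFF path (the `<path>.json` sidecar must sit alongside).
#' @return The reconstructed `expected_image` or `digital_image`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_arg("image file not found: ", path)
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop_arg("metadata sidecar not found: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  raw <- tiff::readTIFF(path, as.is = FALSE)
  if (identical(meta$class, "digital_image")) {
    m <- matrix(as.integer(round(raw * meta$scale)), nrow(raw), ncol(raw))
    new_digital_image(m, meta$bit_depth, isTRUE(meta$saturated))
  } else {
    new_expected_image(raw * meta$scale, meta$pixel_pitch_um)
  }
}

#' Intensity histogram of a digital image
#'
#' Counts pixels in equal-width bins spanning `[min, max]` of the image (or
#' in user-supplied bin edges). The counts always sum to the pixel count.
#'
#' @param image A `digital_image` (or numeric matrix).
#' @param n_bins Number of equal-width bins (ignored when `edges` is given).
#' @param edges Optional ascending bin-edge vector.
#' @return An `intensity_histogram` data frame with columns `bin_left`,
#'   `bin_right`, `count`.
#' @export
intensity_histogram <- function(image, n_bins = 64L, edges = NULL) {
  v <- as.vector(unclass(image))
  if (!length(v)) stop_arg("empty image")
  if (is.null(edges)) {
    lo <- min(v); hi <- max(v)
    if (lo == hi) hi <- lo + 1   # constant image: one bin holds everything
    edges <- seq(lo, hi, length.out = n_bins + 1L)
  } else {
    if (is.unsorted(edges, strictly = TRUE)) stop_arg("edges must ascend")
    if (min(v) < edges[1L] || max(v) > edges[length(edges)])
      stop_arg("edges do not span the image range")
  }
  idx <- findInterval(v, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(data.frame(bin_left = edges[-length(edges)],
                       bin_right = edges[-1L], count = counts),
            class = c("intensity_histogram", "data.frame"))
}

#' @export
plot.intensity_histogram <- function(x, log = FALSE, ...) {
  h <- if (log) log10(1 + x$count) else x$count
  graphics::barplot(h, names.arg = signif((x$bin_left + x$bin_right) / 2, 3),
                    xlab = "A/D counts",
                    ylab = if (log) "log10(1 + pixels)" else "pixels", ...)
  invisible(x)
}

#' Write an intensity histogram as CSV
#'
#' Columns `bin_left,bin_right,count`.
#'
#' @param hist An [intensity_histogram()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_histogram <- function(hist, path) {
  utils::write.csv(as.data.frame(hist), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
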