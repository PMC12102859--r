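#' Construct a raw carcass image
#'
#' A `raw_image` is the unit every geometric transform operates on: a
#' height x width x 3 intensity array on the 0--255 scale, row 1 at the
#' top of the picture, plus a string identifier carried through the
#' pipeline into crop filenames and manifests.
#'
#' @param pixels Numeric array, `h x w x 3`, values in `[0, 255]`.
#' @param source_id Character scalar identifying the source picture.
#' @return An object of class `raw_image` with fields `pixels` and
#'   `source_id`.
#' @export
raw_image <- function(pixels, source_id = "image") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    abort_dimension("'pixels' must be an h x w x 3 array")
  d <- dim(pixels)
  if (d[1] < 8L || d[2] < 8L)
    abort_dimension(sprintf(
      "image too small (%d x %d); need at least 8 x 8", d[1], d[2]))
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    abort_input("pixel intensities must lie in [0, 255] with no NA")
  structure(list(pixels = pixels, source_id = as.character(source_id)),
            class = "raw_image")
}

#' @export
print.raw_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raw_image '%s': %d x %d x 3, range [%g, %g]>\n",
              x$source_id, d[1], d[2], min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Decode and normalize an image file to 3-channel RGB
#'
#' Accepts any raster format the imaging backend can decode (PNG, JPEG
#' and TIFF natively). Single-channel images are replicated across the
#' three channels; an alpha channel is composited on black and dropped,
#' so a fully transparent image becomes all zeros.
#'
#' @param x Path to an image file, an `h x w (x c)` numeric array on
#'   either the `[0, 1]` or `[0, 255]` scale, or an existing `raw_image`
#'   (returned unchanged).
#' @param source_id Identifier for the image; defaults to the file name
#'   without extension.
#' @return A [raw_image].
#' @export
normalize_format <- function(x, source_id = NULL) {
  if (inherits(x, "raw_image")) return(x)
  if (is.character(x)) {
    path <- x
    if (is.null(source_id))
      source_id <- tools::file_path_sans_ext(basename(path))
    if (!file.exists(path))
      abort_format(sprintf("cannot read image: no such file '%s'", path))
    img <- tryCatch(
      suppressWarnings(EBImage::readImage(path)),
      error = function(e) abort_format(sprintf(
        "cannot decode '%s' as a raster image (%s)", path,
        conditionMessage(e))))
    arr <- as.array(EBImage::imageData(img))
    # imaging backend stores x (columns) first; transpose to rows-first
    arr <- if (length(dim(arr)) == 2L) t(arr) else aperm(arr, c(2L, 1L, 3L))
    return(raw_image(normalize_channels(arr * 255), source_id))
  }
  if (is.numeric(x) && !is.null(dim(x))) {
    if (is.null(source_id)) source_id <- "array"
    scale <- if (max(x) <= 1) 255 else 1
    return(raw_image(normalize_channels(x * scale), source_id))
  }
  abort_format("input is neither a file path, a numeric array, nor a raw_image")
}

# h x w (x c) array on the 0..255 scale -> h x w x 3, alpha composited
# on black, channels replicated or dropped as needed.
normalize_channels <- function(arr) {
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  d <- dim(arr)
  if (d[1] == 0L || d[2] == 0L) abort_dimension("zero-sized image")
  nch <- d[3]
  out <- if (nch == 1L) {
    array(arr[, , 1L], c(d[1], d[2], 3L))
  } else if (nch == 2L) {  # grey + alpha
    array(arr[, , 1L] * (arr[, , 2L] / 255), c(d[1], d[2], 3L))
  } else if (nch == 3L) {
    arr
  } else if (nch == 4L) {  # RGBA composited on black
    a <- arr[, , 4L] / 255
    array(c(arr[, , 1L] * a, arr[, , 2L] * a, arr[, , 3L] * a),
          c(d[1], d[2], 3L))
  } else {
    abort_format(sprintf("unsupported channel count: %d", nch))
  }
  round(out)
}

#' Luminance of a raw image
#'
#' Rec. 601 luma (`0.299 R + 0.587 G + 0.114 B`), the scalar intensity
#' that foreground segmentation thresholds.
#'
#' @param img A [raw_image].
#' @return Numeric `h x w` matrix in `[0, 255]`.
#' @export
luminance <- function(img) {
  p <- img$pixels
  0.299 * p[, , 1L] + 0.587 * p[, , 2L] + 0.114 * p[, , 3L]
}

#' Write a raw image to a PNG file
#'
#' @param img A [raw_image].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_raw_image <- function(img, path) {
  png::writePNG(img$pixels / 255, path)
  invisible(path)
}
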