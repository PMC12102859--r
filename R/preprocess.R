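#' Pre-processing configuration
#'
#' Settings for the image standardization chain. `model_input_size` is
#' the side length, in pixels, of the square ear crops the classifiers
#' consume; `min_foreground_area` is the smallest acceptable carcass (or
#' ear) component, as a fraction of the image (or quadrant) area, below
#' which segmentation is declared failed.
#'
#' @param model_input_size Side of the square ear crop (pixels).
#' @param min_foreground_area Minimum retained component area as a
#'   fraction of total pixels.
#' @param luminance_threshold_mode `"otsu"` (data-driven, default) or
#'   `"fixed"`.
#' @param fixed_threshold Threshold on the 0--255 luminance scale, used
#'   only when `luminance_threshold_mode = "fixed"`.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(model_input_size = 64L,
                              min_foreground_area = 0.01,
                              luminance_threshold_mode = c("otsu", "fixed"),
                              fixed_threshold = 128) {
  model_input_size <- as.integer(model_input_size)
  if (is.na(model_input_size) || model_input_size < 8L)
    abort_config("model_input_size must be an integer >= 8")
  if (min_foreground_area <= 0 || min_foreground_area >= 1)
    abort_config("min_foreground_area must be in (0, 1)")
  structure(list(
    model_input_size = model_input_size,
    min_foreground_area = min_foreground_area,
    luminance_threshold_mode = match.arg(luminance_threshold_mode),
    fixed_threshold = fixed_threshold
  ), class = "preprocess_config")
}

# Otsu's threshold on a 0..255 luminance matrix: maximizes between-class
# variance over integer thresholds; ties resolved to the lowest
# threshold. Foreground = luminance strictly above the returned value.
otsu_threshold <- function(lum) {
  bins <- tabulate(pmin(pmax(floor(lum), 0), 255) + 1L, nbins = 256L)
  n <- sum(bins)
  levels <- 0:255
  w0 <- cumsum(bins)                    # count with value <= t
  sum0 <- cumsum(bins * levels)
  total <- sum0[256]
  w1 <- n - w0
  mu0 <- ifelse(w0 > 0, sum0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (total - sum0) / w1, 0)
  sigma_b <- w0 * w1 * (mu0 - mu1)^2
  t <- which.max(sigma_b[1:255]) - 1L   # threshold in 0..254
  t
}

#' Segment the carcass foreground
#'
#' Thresholds the luminance channel (Otsu by default), keeps the largest
#' 8-connected component, and fills its interior holes. This is the
#' package's background-removal contract, adequate for a pale carcass on
#' a darker background.
#'
#' @param img A [raw_image].
#' @param min_foreground_area Minimum component area as a fraction of
#'   image pixels; below it a segmentation-failure error is raised.
#' @param threshold_mode `"otsu"` or `"fixed"`.
#' @param fixed_threshold Luminance cutoff when `threshold_mode = "fixed"`.
#' @return An object of class `foreground_mask`: list with `mask`
#'   (integer h x w matrix of 0/1), `component_area` (pixels in the
#'   retained, hole-filled component) and `threshold`.
#' @export
segment_foreground <- function(img, min_foreground_area = 0.01,
                               threshold_mode = c("otsu", "fixed"),
                               fixed_threshold = 128) {
  threshold_mode <- match.arg(threshold_mode)
  lum <- luminance(img)
  if (threshold_mode == "otsu") {
    thr <- otsu_threshold(lum)
    if (floor(max(lum)) == floor(min(lum)))
      abort_segmentation(sprintf(
        "no luminance contrast to segment in '%s'", img$source_id))
  } else {
    thr <- fixed_threshold
  }
  binary <- matrix(as.integer(lum > thr), nrow(lum), ncol(lum))
  labels <- label_components8(binary)
  sizes <- attr(labels, "sizes")
  min_px <- min_foreground_area * length(binary)
  if (length(sizes) == 0L || max(sizes) < min_px)
    abort_segmentation(sprintf(
      "no foreground component reaches %.3g of image area in '%s'",
      min_foreground_area, img$source_id))
  keep <- which.max(sizes)              # ties: first label found
  mask <- fill_holes_cpp(matrix(as.integer(labels == keep),
                                nrow(binary), ncol(binary)))
  structure(list(mask = mask, component_area = sum(mask), threshold = thr),
            class = "foreground_mask")
}

#' Crop an image to its foreground bounding box
#'
#' Standardizes framing by cutting the image to the tight, inclusive
#' bounding box of the carcass mask, so that the lowest and most lateral
#' carcass points become the image edges.
#'
#' @param img A [raw_image].
#' @param mask The [segment_foreground] result for `img`.
#' @return The cropped [raw_image]; the box is attached as attribute
#'   `crop_box` (`r1, r2, c1, c2`, 1-based inclusive).
#' @export
standardize_crop <- function(img, mask) {
  m <- if (inherits(mask, "foreground_mask")) mask$mask else mask
  if (!identical(dim(m), dim(img$pixels)[1:2]))
    abort_input("mask dimensions do not match the image")
  rows <- which(rowSums(m) > 0)
  cols <- which(colSums(m) > 0)
  if (length(rows) == 0L) abort_input("empty mask: nothing to crop to")
  box <- c(r1 = rows[1], r2 = rows[length(rows)],
           c1 = cols[1], c2 = cols[length(cols)])
  out <- raw_image(img$pixels[box[1]:box[2], box[3]:box[4], , drop = FALSE],
                   img$source_id)
  attr(out, "crop_box") <- box
  out
}

#' Split a standardized image into its four quadrants
#'
#' Cuts at the horizontal and vertical midlines. For odd dimensions the
#' lower half and the right half receive the extra row/column, biasing
#' retention toward the ear-bearing lower quadrants. Reassembling the
#' four parts reproduces the input exactly.
#'
#' @param img A [raw_image] (the standardized crop).
#' @return Named list of four `raw_image`s: `upper_left`, `upper_right`,
#'   `lower_left`, `lower_right`.
#' @export
split_quadrants <- function(img) {
  d <- dim(img$pixels)
  if (d[1] < 2L || d[2] < 2L)
    abort_dimension("image must be at least 2 x 2 to split into quadrants")
  hr <- seq_len(d[1] %/% 2L)            # upper rows
  lc <- seq_len(d[2] %/% 2L)            # left cols
  part <- function(r, c, tag) {
    structure(list(pixels = img$pixels[r, c, , drop = FALSE],
                   source_id = paste0(img$source_id, "_", tag)),
              class = "raw_image")
  }
  list(upper_left  = part(hr, lc, "UL"),
       upper_right = part(hr, setdiff(seq_len(d[2]), lc), "UR"),
       lower_left  = part(setdiff(seq_len(d[1]), hr), lc, "LL"),
       lower_right = part(setdiff(seq_len(d[1]), hr),
                          setdiff(seq_len(d[2]), lc), "LR"))
}

# Nearest-neighbour resize of an h x w x 3 array to size x size.
# Deterministic and zero-preserving (background stays exactly 0).
resize_nearest <- function(pixels, size) {
  d <- dim(pixels)
  ri <- pmin(pmax(floor((seq_len(size) - 0.5) * d[1] / size) + 1L, 1L), d[1])
  ci <- pmin(pmax(floor((seq_len(size) - 0.5) * d[2] / size) + 1L, 1L), d[2])
  pixels[ri, ci, , drop = FALSE]
}

#' Isolate the auricle from a lower-quadrant image
#'
#' Second round of background removal: segments the quadrant, keeps the
#' largest component (the ear), zeroes everything outside it, crops to
#' the ear's bounding box, pads with zeros to a square (short dimension
#' centred, odd remainder to the bottom/right), and resizes to the model
#' input size by nearest neighbour.
#'
#' @param quadrant_img A lower-quadrant [raw_image].
#' @param side `"left"` or `"right"`, in the image frame (no anatomical
#'   claim).
#' @param config A [preprocess_config].
#' @param source_id Identifier for provenance; defaults to the
#'   quadrant's id stripped of its quadrant suffix.
#' @return An object of class `ear_crop`: list with square `pixels`
#'   (`model_input_size` sided, background exactly 0), `side`,
#'   `source_id` and `quadrant`.
#' @export
isolate_ear <- function(quadrant_img, side = c("left", "right"),
                        config = preprocess_config(), source_id = NULL) {
  side <- match.arg(side)
  if (is.null(source_id))
    source_id <- sub("_(LL|LR)$", "", quadrant_img$source_id)
  seg <- tryCatch(
    segment_foreground(quadrant_img, config$min_foreground_area,
                       config$luminance_threshold_mode,
                       config$fixed_threshold),
    auriscreen_segmentation_error = function(e) abort_ear_missing(sprintf(
      "no ear found in %s quadrant of '%s': %s", side, source_id,
      conditionMessage(e))))
  masked <- quadrant_img$pixels * rep(as.numeric(seg$mask), 3L)
  cropped <- standardize_crop(raw_image2(masked, source_id), seg)
  px <- cropped$pixels
  d <- dim(px)
  size <- max(d[1:2])
  canvas <- array(0, c(size, size, 3L))
  r0 <- (size - d[1]) %/% 2L            # extra pixel goes to the bottom
  c0 <- (size - d[2]) %/% 2L            # and to the right
  canvas[r0 + seq_len(d[1]), c0 + seq_len(d[2]), ] <- px
  structure(list(
    pixels = resize_nearest(canvas, config$model_input_size),
    side = side, source_id = source_id,
    quadrant = paste0("lower_", side)
  ), class = "ear_crop")
}

# Internal constructor skipping range checks (used on already-validated
# pixel data, e.g. after masking).
raw_image2 <- function(pixels, source_id) {
  structure(list(pixels = pixels, source_id = source_id),
            class = "raw_image")
}

#' @export
print.ear_crop <- function(x, ...) {
  cat(sprintf("<ear_crop '%s' side=%s: %d x %d>\n", x$source_id, x$side,
              dim(x$pixels)[1], dim(x$pixels)[2]))
  invisible(x)
}

#' Full pre-processing chain for one photograph
#'
#' Applies `normalize_format` -> `segment_foreground` ->
#' `standardize_crop` -> `split_quadrants` -> `isolate_ear` (on both
#' lower quadrants). Deterministic for fixed input and configuration.
#' A failure in a whole-image stage skips the picture; a failure in one
#' quadrant is recorded while the other ear is still returned.
#'
#' @param x Image path, numeric array, or [raw_image].
#' @param config A [preprocess_config].
#' @return List with `crops` (named list with up to two [isolate_ear]
#'   results, `left` and `right`) and `failures` (data frame with
#'   columns `source_id`, `side`, `stage`, `reason`; zero rows when
#'   everything succeeded).
#' @export
preprocess_image <- function(x, config = preprocess_config()) {
  failures <- data.frame(source_id = character(), side = character(),
                         stage = character(), reason = character(),
                         stringsAsFactors = FALSE)
  fail <- function(source_id, side, stage, reason) {
    rbind(failures, data.frame(source_id = source_id, side = side,
                               stage = stage, reason = reason,
                               stringsAsFactors = FALSE))
  }
  img <- tryCatch(normalize_format(x), auriscreen_error = function(e) e)
  if (inherits(img, "condition")) {
    sid <- if (is.character(x)) tools::file_path_sans_ext(basename(x)) else "unknown"
    return(list(crops = list(),
                failures = fail(sid, NA_character_, "normalize_format",
                                conditionMessage(img))))
  }
  whole <- tryCatch({
    seg <- segment_foreground(img, config$min_foreground_area,
                              config$luminance_threshold_mode,
                              config$fixed_threshold)
    standardize_crop(img, seg)
  }, auriscreen_error = function(e) e)
  if (inherits(whole, "condition"))
    return(list(crops = list(),
                failures = fail(img$source_id, NA_character_,
                                "segment_foreground",
                                conditionMessage(whole))))
  quads <- tryCatch(split_quadrants(whole), auriscreen_error = function(e) e)
  if (inherits(quads, "condition"))
    return(list(crops = list(),
                failures = fail(img$source_id, NA_character_,
                                "split_quadrants", conditionMessage(quads))))
  crops <- list()
  for (side in c("left", "right")) {
    q <- if (side == "left") quads$lower_left else quads$lower_right
    res <- tryCatch(
      isolate_ear(q, side, config, source_id = img$source_id),
      auriscreen_error = function(e) e)
    if (inherits(res, "condition")) {
      failures <- fail(img$source_id, side, "isolate_ear",
                       conditionMessage(res))
    } else {
      crops[[side]] <- res
    }
  }
  list(crops = crops, failures = failures)
}

#' Pre-process a directory of photographs
#'
#' Runs [preprocess_image] on every decodable image in `input_dir`,
#' writes each ear crop as `<source_id>_<L|R>.png` into `output_dir`,
#' and writes a `manifest.csv` recording per-ear status. Failed images
#' are skipped and logged, never fatal.
#'
#' @param input_dir Directory of input photographs (png/jpg/jpeg/tif).
#' @param output_dir Output directory (created if needed).
#' @param config A [preprocess_config].
#' @return The manifest data frame (columns `source_id`, `side`,
#'   `status`, `output_path`, `failure_reason`), invisibly.
#' @export
preprocess_dir <- function(input_dir, output_dir,
                           config = preprocess_config()) {
  files <- list.files(input_dir,
                      pattern = "\\.(png|jpe?g|tiff?)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (!dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)
  rows <- list()
  for (f in sort(files)) {
    res <- preprocess_image(f, config)
    sid <- tools::file_path_sans_ext(basename(f))
    for (side in c("left", "right")) {
      crop <- res$crops[[side]]
      if (!is.null(crop)) {
        out <- file.path(output_dir,
                         sprintf("%s_%s.png", crop$source_id,
                                 if (side == "left") "L" else "R"))
        png::writePNG(crop$pixels / 255, out)
        rows[[length(rows) + 1L]] <- data.frame(
          source_id = crop$source_id, side = side, status = "ok",
          output_path = out, failure_reason = NA_character_,
          stringsAsFactors = FALSE)
      } else {
        why <- res$failures
        why <- why$reason[is.na(why$side) | why$side == side]
        rows[[length(rows) + 1L]] <- data.frame(
          source_id = sid, side = side, status = "failed",
          output_path = NA_character_,
          failure_reason = paste(why, collapse = "; "),
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source_id = character(), side = character(),
               status = character(), output_path = character(),
               failure_reason = character(), stringsAsFactors = FALSE)
  write.csv(manifest, file.path(output_dir, "manifest.csv"),
            row.names = FALSE)
  invisible(manifest)
}

#' Read ear crops written by [preprocess_dir]
#'
#' @param dir Directory containing `<source_id>_<L|R>.png` files.
#' @return Named list of `ear_crop` objects keyed `<source_id>_<L|R>`.
#' @export
read_ear_crops <- function(dir) {
  files <- sort(list.files(dir, pattern = "_(L|R)\\.png$",
                           full.names = TRUE))
  crops <- lapply(files, function(f) {
    base <- tools::file_path_sans_ext(basename(f))
    side <- if (grepl("_L$", base)) "left" else "right"
    sid <- sub("_(L|R)$", "", base)
    px <- png::readPNG(f) * 255
    if (length(dim(px)) == 2L) px <- array(px, c(dim(px), 3L))
    structure(list(pixels = round(px[, , 1:3, drop = FALSE]), side = side,
                   source_id = sid, quadrant = paste0("lower_", side)),
              class = "ear_crop")
  })
  names(crops) <- vapply(files, function(f)
    tools::file_path_sans_ext(basename(f)), "")
  crops
}
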