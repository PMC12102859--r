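test_that("segmentation recovers a high-contrast rectangle exactly", {
  img <- make_test_image(100, 100, background = 5,
                         rects = list(c(31, 70, 31, 70, 250)))
  seg <- segment_foreground(img)
  expect_equal(seg$component_area, 1600)
  expect_true(all(seg$mask[31:70, 31:70] == 1))
  expect_equal(sum(seg$mask), 1600)
})

test_that("an all-dark image is a segmentation failure", {
  img <- make_test_image(50, 50, background = 0)
  expect_error(segment_foreground(img),
               class = "auriscreen_segmentation_error")
})

test_that("only the largest of several bright components is kept", {
  # blobs of 500 and 900 px at known, well-separated positions
  img <- make_test_image(100, 100, background = 5,
                         rects = list(c(5, 24, 5, 29, 240),    # 20x25 = 500
                                      c(60, 89, 50, 79, 240))) # 30x30 = 900
  seg <- segment_foreground(img)
  expect_equal(seg$component_area, 900)
  expect_true(all(seg$mask[60:89, 50:79] == 1))
  expect_true(all(seg$mask[5:24, 5:29] == 0))
})

test_that("interior holes are filled", {
  img <- make_test_image(60, 60, background = 5,
                         rects = list(c(10, 49, 10, 49, 240),
                                      c(25, 34, 25, 34, 5)))  # dark hole
  seg <- segment_foreground(img)
  expect_equal(seg$component_area, 1600)  # 40x40 with the hole filled
})

test_that("standardize_crop takes the tight bounding box", {
  img <- make_test_image(100, 100, background = 5,
                         rects = list(c(11, 50, 31, 70, 240)))
  seg <- segment_foreground(img)
  out <- standardize_crop(img, seg)
  expect_identical(dim(out$pixels)[1:2], c(40L, 40L))
  # full-frame mask: identity
  full <- make_test_image(40, 30, background = 200)
  segf <- segment_foreground(full, threshold_mode = "fixed",
                             fixed_threshold = 100)
  expect_identical(standardize_crop(full, segf)$pixels, full$pixels)
})

test_that("crop box matches a brute-force min/max scan on an L-mask", {
  img <- make_test_image(80, 80, background = 5)
  px <- img$pixels
  px[20:60, 15:25, ] <- 240           # vertical bar
  px[50:60, 15:55, ] <- 240           # foot of the L
  img <- raw_image(px, "L")
  seg <- segment_foreground(img)
  out <- standardize_crop(img, seg)
  fg <- which(luminance(img) > seg$threshold, arr.ind = TRUE)
  expect_identical(dim(out$pixels)[1:2],
                   c(diff(range(fg[, 1])) + 1L, diff(range(fg[, 2])) + 1L))
  # idempotence: cropping the crop changes nothing
  seg2 <- segment_foreground(out)
  expect_identical(standardize_crop(out, seg2)$pixels, out$pixels)
  # tightness: every edge row/col of the crop touches foreground
  m <- segment_foreground(out)$mask
  expect_true(all(c(sum(m[1, ]), sum(m[nrow(m), ]),
                    sum(m[, 1]), sum(m[, ncol(m)])) > 0))
})

test_that("quadrant split follows the odd-dimension rule", {
  img <- make_test_image(100, 100, background = 100)
  q <- split_quadrants(img)
  expect_identical(dim(q$lower_left$pixels)[1:2], c(50L, 50L))
  odd <- make_test_image(101, 101, background = 100)
  qo <- split_quadrants(odd)
  expect_identical(dim(qo$lower_left$pixels)[1:2], c(51L, 50L))
  expect_identical(dim(qo$upper_right$pixels)[1:2], c(50L, 51L))
  expect_no_error(split_quadrants(make_test_image(8, 8, background = 1)))
  tiny <- structure(list(pixels = array(0, c(1, 5, 3)), source_id = "t"),
                    class = "raw_image")
  expect_error(split_quadrants(tiny), class = "auriscreen_dimension_error")
})

test_that("the four quadrants reassemble the image exactly", {
  set.seed(21)
  for (i in 1:25) {
    h <- sample(8:40, 1); w <- sample(8:40, 1)
    px <- array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3))
    img <- raw_image(px, "r")
    q <- split_quadrants(img)
    top <- abind_cols(q$upper_left$pixels, q$upper_right$pixels)
    bot <- abind_cols(q$lower_left$pixels, q$lower_right$pixels)
    expect_identical(abind_rows(top, bot), px)
  }
})

test_that("isolate_ear zeroes background, pads square and centres", {
  # bright 30x20 rectangle inside a 64x64 quadrant; crop size 30 so the
  # nearest-neighbour resize is the identity
  q <- make_test_image(64, 64, background = 5,
                       rects = list(c(11, 40, 21, 40, 230)))
  crop <- isolate_ear(q, "left", preprocess_config(model_input_size = 30))
  expect_s3_class(crop, "ear_crop")
  expect_identical(dim(crop$pixels), c(30L, 30L, 3L))
  nz <- crop$pixels[, , 1] > 0
  expect_true(all(which(colSums(nz) > 0) == 6:25))  # centred horizontally
  expect_true(all(rowSums(nz) > 0))
  expect_true(all(crop$pixels[!array(rep(nz, 3), dim(crop$pixels))] == 0))
  # nonzero pixels form a single 8-connected component
  lab <- auriscreen:::label_components8(matrix(as.integer(nz), 30, 30))
  expect_equal(length(attr(lab, "sizes")), 1)
  # empty quadrant
  expect_error(isolate_ear(make_test_image(64, 64, background = 0), "left"),
               class = "auriscreen_ear_missing_error")
})

test_that("the full chain is deterministic and recovers generator ears", {
  cfg <- synth_config(seed = 9)
  r <- render_carcass(cfg, seed = 31, source_id = "chain")
  f <- tempfile(fileext = ".png")
  write_raw_image(r$image, f)
  a <- preprocess_image(f)
  b <- preprocess_image(f)
  expect_identical(names(a$crops), c("left", "right"))
  expect_equal(nrow(a$failures), 0)
  expect_identical(a$crops$left$pixels, b$crops$left$pixels)
  expect_identical(a$crops$right$pixels, b$crops$right$pixels)
  expect_identical(a$crops$left$side, "left")
  expect_identical(a$crops$left$quadrant, "lower_left")
})

test_that("translating the carcass leaves ear crops pixel-identical", {
  cfg <- synth_config(seed = 13, noise_sd = 0)
  base <- render_carcass(cfg, seed = 41, offset = c(0L, 0L))
  for (off in list(c(8L, 0L), c(0L, -6L), c(-5L, 7L))) {
    shifted <- render_carcass(cfg, seed = 41, offset = off)
    a <- preprocess_image(base$image)
    b <- preprocess_image(shifted$image)
    expect_identical(a$crops$left$pixels, b$crops$left$pixels)
    expect_identical(a$crops$right$pixels, b$crops$right$pixels)
  }
})

test_that("an empty lower-left quadrant yields one crop and one record", {
  # bright band connected to a lower-right blob via a thin bridge, so
  # the carcass is one component but the lower-left quadrant is dark
  img <- make_test_image(100, 100, background = 5,
                         rects = list(c(11, 30, 11, 90, 240),   # band
                                      c(11, 88, 86, 90, 240),   # bridge
                                      c(70, 88, 60, 90, 240)))  # blob
  res <- preprocess_image(img)
  expect_identical(names(res$crops), "right")
  expect_equal(nrow(res$failures), 1)
  expect_identical(res$failures$side, "left")
  expect_identical(res$failures$stage, "isolate_ear")
})

test_that("directory preprocessing writes crops and a manifest", {
  src <- file.path(tempdir(), "pp_in"); out <- file.path(tempdir(), "pp_out")
  unlink(c(src, out), recursive = TRUE); dir.create(src)
  cfg <- synth_config(seed = 2)
  for (i in 1:3) {
    r <- render_carcass(cfg, seed = 50 + i, source_id = sprintf("im%02d", i))
    write_raw_image(r$image, file.path(src, sprintf("im%02d.png", i)))
  }
  writeLines("junk", file.path(src, "broken.png"))
  man <- preprocess_dir(src, out)
  expect_equal(nrow(man), 8)           # 4 files x 2 ears
  expect_equal(sum(man$status == "ok"), 6)
  expect_equal(sum(man$status == "failed"), 2)
  expect_true(all(file.exists(man$output_path[man$status == "ok"])))
  expect_true(file.exists(file.path(out, "manifest.csv")))
  crops <- read_ear_crops(out)
  expect_length(crops, 6)
  expect_identical(dim(crops[[1]]$pixels), c(64L, 64L, 3L))
})
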