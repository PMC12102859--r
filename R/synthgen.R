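#' Configuration of the synthetic slaughter-line image generator
#'
#' The generator emulates the features the classifiers rely on: a pale,
#' roughly symmetric, head-down carcass silhouette on a darker
#' background, with one auricle hanging into each lower quadrant. Ear
#' contours come in three classes: smooth (healthy), carrying a jagged
#' multi-tooth notch that removes a calibrated fraction of the ear area
#' (biting lesion), or altered by slaughter processing (a clean
#' straight-line truncation, or a smooth low-amplitude ripple of the
#' whole contour, "strain"). An ear carrying both a lesion and an
#' artefact is labelled 1 (lesion), matching the labelling rule used at
#' the abattoir.
#'
#' @param n_images Number of carcass images (two ears each).
#' @param class_probs Probabilities of healthy / lesion / artefact per
#'   ear; defaults mirror a realistic test-line mix (~75/11/14).
#' @param lesion_severity Range of the fraction of ear area a lesion
#'   removes.
#' @param artefact_kind_probs Probabilities of `straight_cut` vs
#'   `strain` given an artefact.
#' @param both_lesion_and_artefact_prob Probability that a lesion ear
#'   additionally carries an artefact (still labelled 1).
#' @param image_size Height and width of the rendered image, pixels.
#' @param background_range,foreground_range Base intensity ranges
#'   (0--255) for background and carcass.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param label_noise_rate Probability that the simulated observer-A
#'   label of an ear is flipped to one of the other two classes
#'   (uniformly); ground truth is unaffected.
#' @param split_fractions Train / test / supplementary fractions for
#'   the dataset split manifest; the default is the nominal 63/27/10
#'   split (exact ratios 199/314, 85/314, 30/314).
#' @param seed Integer master seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_images = 100L,
                         class_probs = c(healthy = 0.75, lesion = 0.11,
                                         artefact = 0.14),
                         lesion_severity = c(0.05, 0.5),
                         artefact_kind_probs = c(straight_cut = 0.6,
                                                 strain = 0.4),
                         both_lesion_and_artefact_prob = 0.05,
                         image_size = c(256L, 256L),
                         background_range = c(20, 60),
                         foreground_range = c(170, 230),
                         noise_sd = 8,
                         label_noise_rate = 0,
                         split_fractions = c(train = 199, test = 85,
                                             supplementary = 30) / 314,
                         seed = 1L) {
  if (n_images < 1L) abort_config("'n_images' must be >= 1")
  if (length(class_probs) != 3L || any(class_probs < 0) ||
      abs(sum(class_probs) - 1) > 1e-8)
    abort_config("'class_probs' must be 3 non-negative values summing to 1")
  if (length(lesion_severity) != 2L || lesion_severity[1] <= 0 ||
      lesion_severity[2] >= 1 || diff(lesion_severity) < 0)
    abort_config("'lesion_severity' must be an increasing range inside (0, 1)")
  if (abs(sum(artefact_kind_probs) - 1) > 1e-8)
    abort_config("'artefact_kind_probs' must sum to 1")
  image_size <- rep(as.integer(image_size), length.out = 2L)
  if (any(image_size < 96L))
    abort_config("'image_size' must be at least 96 x 96 to fit an ear per quadrant")
  if (label_noise_rate < 0 || label_noise_rate > 1)
    abort_config("'label_noise_rate' must be in [0, 1]")
  if (abs(sum(split_fractions) - 1) > 1e-8)
    abort_config("'split_fractions' must sum to 1")
  structure(list(
    n_images = as.integer(n_images),
    class_probs = setNames(as.numeric(class_probs),
                           c("healthy", "lesion", "artefact")),
    lesion_severity = as.numeric(lesion_severity),
    artefact_kind_probs = setNames(as.numeric(artefact_kind_probs),
                                   c("straight_cut", "strain")),
    both_lesion_and_artefact_prob = both_lesion_and_artefact_prob,
    image_size = image_size,
    background_range = as.numeric(background_range),
    foreground_range = as.numeric(foreground_range),
    noise_sd = noise_sd,
    label_noise_rate = label_noise_rate,
    split_fractions = split_fractions,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# Ellipse membership over the pixel grid (rr, cc are coordinate
# matrices), optionally with a smooth radial ripple of the boundary.
ellipse_mask <- function(rr, cc, cr, ccol, ar, ac,
                         ripple = NULL) {
  dr <- (rr - cr) / ar
  dc <- (cc - ccol) / ac
  norm <- sqrt(dr^2 + dc^2)
  lim <- if (is.null(ripple)) 1 else {
    theta <- atan2(dc, dr)
    1 + ripple$amplitude * sin(ripple$k * theta + ripple$phase)
  }
  norm <= lim
}

# Remove a cap of the ear mask along direction `ang` (radians from
# straight down), cutting off `target` pixels. `jag` is a per-lateral-
# pixel edge displacement (0 for a clean straight cut); the cut depth
# is found by bisection on the pixel count, so the removed area is
# exact to within a few pixels.
cut_cap <- function(mask, rr, cc, cr, ccol, ang, target, jag_fun) {
  idx <- which(mask)
  u_r <- cos(ang); u_c <- sin(ang)
  proj <- (rr[idx] - cr) * u_r + (cc[idx] - ccol) * u_c
  lat <- -(rr[idx] - cr) * u_c + (cc[idx] - ccol) * u_r
  jag <- jag_fun(lat)
  lo <- min(proj - jag) - 1; hi <- max(proj - jag) + 1
  count_at <- function(d) sum(proj > d - jag)
  for (it in 1:50) {
    mid <- (lo + hi) / 2
    if (count_at(mid) > target) lo <- mid else hi <- mid
  }
  d <- if (abs(count_at(lo) - target) < abs(count_at(hi) - target)) lo else hi
  out <- mask
  out[idx[proj > d - jag]] <- FALSE
  out
}

# Sawtooth jag profile: teeth of width `tw` pixels with independent
# random amplitudes, sampled once and closed over.
make_jag <- function(max_lat = 200, tw = NULL, amp_range = c(2.5, 7)) {
  tw <- if (is.null(tw)) sample(3:5, 1L) else tw
  n_teeth <- ceiling(2 * max_lat / tw) + 2L
  amps <- runif(n_teeth, amp_range[1], amp_range[2])
  function(lat) {
    l <- lat + max_lat
    tooth <- pmin(pmax(floor(l / tw), 0), n_teeth - 1L)
    within <- (l - tooth * tw) / tw
    amps[tooth + 1L] * within
  }
}

#' Render one synthetic carcass image with per-ear ground truth
#'
#' Deterministic given `(config, seed, offset)`: the same seed yields a
#' bit-identical image and truth. `offset` shifts the whole carcass
#' within the frame without redrawing any random quantity, which is how
#' the translation-invariance property of the pre-processing chain is
#' exercised.
#'
#' @param config A [synth_config].
#' @param seed Seed for this image (defaults to `config$seed`).
#' @param source_id Identifier stored in the image and truth rows.
#' @param offset Integer `(rows, cols)` translation of the carcass.
#' @param return_masks If `TRUE`, also return the final and unmodified
#'   (template) ear masks, for area verification.
#' @return List with `image` (a [raw_image]), `truth` (two-row data
#'   frame: `source_id`, `side`, `label`, `severity`, `artefact_kind`,
#'   `area_px`, `template_area_px`) and, optionally, `masks`.
#' @export
render_carcass <- function(config = synth_config(), seed = config$seed,
                           source_id = "img0001", offset = c(0L, 0L),
                           return_masks = FALSE) {
  H <- config$image_size[1]; W <- config$image_size[2]
  withr_seed(seed, {
    # frame placement
    Hc <- round(H * runif(1, 0.72, 0.80))
    Wc <- round(W * runif(1, 0.72, 0.80))
    # the carcass occupies rows r_off..r_off + ~1.02*Hc (ear tips)
    r_off <- round(runif(1, 0.02, 0.98) * (H - ceiling(1.04 * Hc))) +
      offset[1]
    c_off <- round(runif(1, 0.02, 0.98) * (W - Wc)) + offset[2]
    if (r_off < 0 || c_off < 0 || r_off + 1.04 * Hc > H || c_off + Wc > W)
      abort_config("carcass does not fit in the frame at this offset")
    rr <- matrix(seq_len(H), H, W)
    cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    ctr_c <- c_off + Wc / 2
    body <- ellipse_mask(rr, cc, r_off + 0.28 * Hc, ctr_c,
                         0.26 * Hc, 0.50 * Wc)
    # head: trapezoid narrowing toward the snout (downward)
    h_top <- r_off + 0.38 * Hc; h_bot <- r_off + 0.60 * Hc
    hw <- 0.22 * Wc + (0.12 - 0.22) * Wc * (rr - h_top) / (h_bot - h_top)
    head <- rr >= h_top & rr <= h_bot & abs(cc - ctr_c) <= hw
    scene <- body | head
    truth <- list(); masks <- list()
    for (side in c("left", "right")) {
      sgn <- if (side == "left") -1 else 1
      e_cr <- r_off + Hc * (0.72 + runif(1, -0.015, 0.015))
      e_cc <- ctr_c + sgn * Wc * (0.24 + runif(1, -0.012, 0.012))
      e_ar <- 0.26 * Hc * runif(1, 0.92, 1.08)
      e_ac <- 0.095 * Wc * runif(1, 0.92, 1.08)
      template <- ellipse_mask(rr, cc, e_cr, e_cc, e_ar, e_ac)
      # class assignment
      u <- runif(1)
      cls <- if (u < config$class_probs[1]) "healthy" else
        if (u < config$class_probs[1] + config$class_probs[2]) "lesion" else
          "artefact"
      has_lesion <- cls == "lesion"
      has_artefact <- cls == "artefact" ||
        (has_lesion && runif(1) < config$both_lesion_and_artefact_prob)
      kind <- if (has_artefact) {
        if (runif(1) < config$artefact_kind_probs[["straight_cut"]])
          "straight_cut" else "strain"
      } else NA_character_
      severity <- if (has_lesion)
        runif(1, config$lesion_severity[1], config$lesion_severity[2])
      else NA_real_
      ear <- template
      if (has_artefact && kind == "strain") {
        ripple <- list(amplitude = runif(1, 0.06, 0.12),
                       k = sample(4:7, 1L), phase = runif(1, 0, 2 * pi))
        ear <- ellipse_mask(rr, cc, e_cr, e_cc, e_ar, e_ac, ripple)
      }
      if (has_artefact && kind == "straight_cut") {
        extent <- runif(1, 0.10, 0.30)
        ang <- runif(1, -0.9, 0.9)
        ear <- cut_cap(ear, rr, cc, e_cr, e_cc, ang,
                       round(extent * sum(ear)),
                       function(lat) rep(0, length(lat)))
      }
      if (has_lesion) {
        ang <- runif(1, -1.2, 1.2)       # notch at the tip region
        jag <- make_jag(max_lat = max(H, W))
        ear <- cut_cap(ear, rr, cc, e_cr, e_cc, ang,
                       round(severity * sum(ear)), jag)
      }
      label <- if (has_lesion) 1L else if (has_artefact) 2L else 0L
      truth[[side]] <- data.frame(
        source_id = source_id, side = side, label = label,
        severity = severity, artefact_kind = kind,
        area_px = sum(ear), template_area_px = sum(template),
        stringsAsFactors = FALSE)
      masks[[side]] <- list(ear = ear, template = template)
      scene <- scene | ear
    }
    # intensities
    bg <- runif(1, config$background_range[1], config$background_range[2])
    fg <- runif(1, config$foreground_range[1], config$foreground_range[2])
    chan_mult <- c(1, 0.93, 0.90)       # faintly pink carcass
    px <- array(0, c(H, W, 3L))
    for (ch in 1:3)
      px[, , ch] <- ifelse(scene, fg * chan_mult[ch], bg)
    if (config$noise_sd > 0)
      px <- px + array(rnorm(H * W * 3L, 0, config$noise_sd), c(H, W, 3L))
    px <- round(pmin(pmax(px, 0), 255))
    out <- list(image = raw_image(px, source_id),
                truth = rbind(truth$left, truth$right))
    if (return_masks) out$masks <- masks
    out
  })
}

#' Train / test / supplementary split assignment
#'
#' Apportions `n_images` images to the three splits by largest-remainder
#' rounding of `fractions` and assigns images to splits over a seeded
#' shuffle. Both ears of an image always share its split.
#'
#' @param n_images Number of images to assign.
#' @param fractions Named fractions summing to 1 (default: the nominal
#'   63/27/10 split, exact ratios 199/314, 85/314, 30/314).
#' @param seed Integer seed for the shuffle.
#' @param ids Optional image identifiers.
#' @return Data frame with columns `source_id`, `split`.
#' @export
dataset_split <- function(n_images,
                          fractions = c(train = 199, test = 85,
                                        supplementary = 30) / 314,
                          seed = 1L, ids = NULL) {
  if (abs(sum(fractions) - 1) > 1e-8)
    abort_config("'fractions' must sum to 1")
  if (is.null(ids)) ids <- sprintf("img%05d", seq_len(n_images))
  withr_seed(seed, {
    counts <- apportion(n_images, fractions)
    assignment <- rep(c("train", "test", "supplementary"), counts)
    data.frame(source_id = ids,
               split = assignment[order(sample.int(n_images))],
               stringsAsFactors = FALSE)
  })
}

# Largest-remainder apportionment of n items to the given fractions.
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a full synthetic dataset
#'
#' Renders `n_images` carcass images (seeded as `seed + i`), assigns
#' each image to a train / test / supplementary split by
#' largest-remainder apportionment of `split_fractions` over a seeded
#' shuffle, and derives an observer-A-style label table (ground truth,
#' optionally corrupted at `label_noise_rate`).
#'
#' When `out_dir` is given, writes `images/<source_id>.png`,
#' `truth.csv`, `labels.csv` (columns `source_id`, `side`, `label`,
#' `observer`) and `split.csv`, and omits the in-memory images from the
#' return value.
#'
#' @param config A [synth_config].
#' @param out_dir Optional output directory.
#' @return List with `truth`, `labels`, `split` data frames and either
#'   `images` (named list of [raw_image]s; `out_dir = NULL`) or `paths`.
#' @export
generate_dataset <- function(config = synth_config(), out_dir = NULL) {
  n <- config$n_images
  ids <- sprintf("img%05d", seq_len(n))
  img_dir <- NULL
  if (!is.null(out_dir)) {
    img_dir <- file.path(out_dir, "images")
    ok <- dir.exists(img_dir) || dir.create(img_dir, recursive = TRUE,
                                            showWarnings = FALSE)
    if (!ok || file.access(out_dir, 2L) != 0L)
      abort_input(sprintf("cannot write to output directory '%s'", out_dir))
  }
  images <- if (is.null(out_dir)) vector("list", n) else NULL
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    r <- render_carcass(config, seed = config$seed + i, source_id = ids[i])
    truth[[i]] <- r$truth
    if (is.null(out_dir)) {
      images[[i]] <- r$image
    } else {
      write_raw_image(r$image, file.path(img_dir, paste0(ids[i], ".png")))
    }
  }
  truth <- do.call(rbind, truth)
  labels <- withr_seed(config$seed + n + 1L, {
    lab <- truth$label
    if (config$label_noise_rate > 0) {
      flip <- runif(length(lab)) < config$label_noise_rate
      lab[flip] <- vapply(lab[flip], function(l)
        sample(setdiff(0:2, l), 1L), 0L)
    }
    data.frame(source_id = truth$source_id, side = truth$side,
               label = lab, observer = "A", stringsAsFactors = FALSE)
  })
  split <- dataset_split(n, config$split_fractions,
                         seed = config$seed + n + 2L, ids = ids)
  out <- list(truth = truth, labels = labels, split = split,
              config = config)
  if (is.null(out_dir)) {
    names(images) <- ids
    out$images <- images
  } else {
    write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
    write.csv(labels, file.path(out_dir, "labels.csv"), row.names = FALSE)
    write.csv(split, file.path(out_dir, "split.csv"), row.names = FALSE)
    out$paths <- list(
      images = img_dir,
      truth = file.path(out_dir, "truth.csv"),
      labels = file.path(out_dir, "labels.csv"),
      split = file.path(out_dir, "split.csv"))
  }
  out
}

#' Simulate raters from per-rater confusion matrices
#'
#' Each rater's label for an ear is drawn independently from the row of
#' that rater's confusion matrix corresponding to the true label
#' (rows = truth 0..2, columns = assigned 0..2, rows summing to 1).
#'
#' @param truth_labels Integer vector of true labels in `{0, 1, 2}`.
#' @param confusion_specs List of 3 x 3 row-stochastic matrices, one
#'   per rater (optionally named).
#' @param seed Integer seed.
#' @param ear_ids Optional ear identifiers.
#' @return A [rater_table].
#' @export
simulate_raters <- function(truth_labels, confusion_specs, seed = 1L,
                            ear_ids = NULL) {
  truth_labels <- as.integer(truth_labels)
  if (!all(truth_labels %in% 0:2))
    abort_input("truth labels must be in {0, 1, 2}")
  for (cs in confusion_specs) {
    if (!is.matrix(cs) || !all(dim(cs) == 3L) || any(cs < 0) ||
        any(abs(rowSums(cs) - 1) > 1e-8))
      abort_spec("each confusion spec must be a 3 x 3 row-stochastic matrix")
  }
  k <- length(confusion_specs)
  rater_ids <- names(confusion_specs) %||% LETTERS[seq_len(k)]
  lab <- withr_seed(seed, {
    m <- matrix(0L, length(truth_labels), k)
    for (j in seq_len(k)) {
      cs <- confusion_specs[[j]]
      for (i in seq_along(truth_labels))
        m[i, j] <- sample(0:2, 1L, prob = cs[truth_labels[i] + 1L, ])
    }
    m
  })
  rater_table(lab, rater_ids = rater_ids, ear_ids = ear_ids)
}
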