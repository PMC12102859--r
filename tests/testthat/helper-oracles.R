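# Independent oracles and fixture builders shared across test files.
# Everything here is deliberately written without reusing the package's
# own computation paths.

# Brute-force Cohen's kappa: tally the contingency table by explicit
# double loop and evaluate the formula directly.
kappa_bruteforce <- function(a, b) {
  n <- length(a)
  tab <- matrix(0, 3, 3)
  for (i in seq_len(n))
    tab[a[i] + 1, b[i] + 1] <- tab[a[i] + 1, b[i] + 1] + 1
  po <- sum(diag(tab)) / n
  pe <- 0
  for (k in 1:3) pe <- pe + sum(tab[k, ]) / n * sum(tab[, k]) / n
  if (pe == 1) return(if (po == 1) 1 else NA_real_)
  (po - pe) / (1 - pe)
}

# Exhaustive pairwise confusion tally (loop, no table()).
confusion_bruteforce <- function(truth, pred) {
  m <- matrix(0L, 3, 3)
  for (i in seq_along(truth))
    m[truth[i] + 1, pred[i] + 1] <- m[truth[i] + 1, pred[i] + 1] + 1L
  m
}

# Analytic kappa implied by a truth prior and two raters' confusion
# rows: joint P(a=i, b=j) = sum_t pi_t C1[t,i] C2[t,j].
kappa_analytic <- function(prior, C1, C2) {
  joint <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    joint[i, j] <- sum(prior * C1[, i] * C2[, j])
  po <- sum(diag(joint))
  pe <- sum(rowSums(joint) * colSums(joint))
  (po - pe) / (1 - pe)
}

# Flat grey test image with optional bright rectangles:
# rects is a list of c(r1, r2, c1, c2, value).
make_test_image <- function(h, w, background = 10, rects = list(),
                            source_id = "test") {
  px <- array(background, c(h, w, 3))
  for (rc in rects)
    px[rc[1]:rc[2], rc[3]:rc[4], ] <- rc[5]
  raw_image(px, source_id)
}

# Concatenate h x w x 3 arrays side by side / on top of each other.
abind_cols <- function(a, b) {
  out <- array(vector(typeof(a), 1), c(dim(a)[1], dim(a)[2] + dim(b)[2], 3))
  out[, seq_len(dim(a)[2]), ] <- a
  out[, dim(a)[2] + seq_len(dim(b)[2]), ] <- b
  out
}
abind_rows <- function(a, b) {
  out <- array(vector(typeof(a), 1), c(dim(a)[1] + dim(b)[1], dim(a)[2], 3))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

# Renders and preprocesses one image
# at a time so full-size datasets never sit in memory together. Image
# seeds follow the generate_dataset convention (config seed + index).
stream_ear_dataset <- function(n_images, seed = 1, input_size = 64, ...) {
  cfg <- synth_config(n_images = n_images, seed = seed, ...)
  pcfg <- preprocess_config(model_input_size = input_size)
  crops <- list(); labels <- integer(); ids <- character()
  for (i in seq_len(n_images)) {
    id <- sprintf("img%05d", i)
    r <- render_carcass(cfg, seed = cfg$seed + i, source_id = id)
    pp <- preprocess_image(r$image, pcfg)
    for (side in names(pp$crops)) {
      crops[[length(crops) + 1]] <- pp$crops[[side]]
      labels <- c(labels, r$truth$label[r$truth$side == side])
      ids <- c(ids, paste0(id, "_", side))
    }
  }
  list(crops = crops, labels = labels, ids = ids,
       image_ids = sub("_(left|right)$", "", ids), config = cfg)
}

# A 300-ear, 3-rater table with the given unanimous class counts and
# lone-dissent attribution (counts named by rater index 1..3); dissents
# flip the majority label 0 to 1 (or 1 to 0 for variety).
build_unanimity_table <- function(unanimous = c(185, 85, 16),
                                  dissents = c(2, 4, 8)) {
  rows <- list()
  for (cl in 0:2)
    rows <- c(rows, replicate(unanimous[cl + 1], rep(cl, 3),
                              simplify = FALSE))
  for (r in 1:3) {
    for (i in seq_len(dissents[r])) {
      maj <- if (i %% 2 == 0) 0L else 1L
      row <- rep(maj, 3)
      row[r] <- if (maj == 0L) 1L else 0L
      rows <- c(rows, list(row))
    }
  }
  rater_table(do.call(rbind, rows), rater_ids = c("A", "B", "C"))
}
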