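#' Architecture specification for one cascade stage
#'
#' Both cascade stages share a single small architecture: six alternating
#' layers — three convolutions (feature extraction), two max-pooling
#' layers (summarization), and one fully connected sigmoid output giving
#' a single probability. Convolutions use 'same' zero padding and
#' rectified-linear activations.
#'
#' @param input_size Side of the square RGB input, in pixels. Must be
#'   divisible by `pool_size^2`.
#' @param filters Integer vector of length 3: filter counts of the three
#'   convolution stages.
#' @param kernel_size Odd convolution kernel side.
#' @param pool_size Max-pooling window and stride.
#' @param seed Integer seed for weight initialization.
#' @return A list of class `cnn_spec`; its `layers` field records the
#'   mandated sequence `conv, pool, conv, pool, conv, fc`.
#' @export
cnn_spec <- function(input_size = 64L, filters = c(16L, 32L, 32L),
                     kernel_size = 3L, pool_size = 2L, seed = 1L) {
  input_size <- as.integer(input_size)
  filters <- as.integer(filters)
  if (length(filters) != 3L || any(is.na(filters)) || any(filters < 1L))
    abort_spec("'filters' must be three positive integers (one per convolution stage)")
  if (kernel_size %% 2L != 1L || kernel_size < 1L)
    abort_spec("'kernel_size' must be odd and positive")
  if (pool_size < 2L)
    abort_spec("'pool_size' must be at least 2")
  if (input_size %% (pool_size^2) != 0L)
    abort_spec(sprintf("input_size (%d) must be divisible by pool_size^2 (%d)",
                       input_size, pool_size^2))
  structure(list(
    layers = c("conv", "pool", "conv", "pool", "conv", "fc"),
    input_size = input_size, filters = filters,
    kernel_size = as.integer(kernel_size),
    pool_size = as.integer(pool_size), seed = as.integer(seed)
  ), class = "cnn_spec")
}

#' Number of trainable parameters of a spec
#'
#' @param spec A [cnn_spec].
#' @return Integer parameter count (weights + biases of all six layers).
#' @export
n_params <- function(spec) {
  k2 <- spec$kernel_size^2
  f <- spec$filters
  s3 <- spec$input_size / spec$pool_size^2
  f[1] * 3 * k2 + f[1] +
    f[2] * f[1] * k2 + f[2] +
    f[3] * f[2] * k2 + f[3] +
    f[3] * s3 * s3 + 1
}

#' Build an untrained CNN
#'
#' Initializes the six-layer network of `spec` with He-scaled Gaussian
#' weights and zero biases, reproducibly from `spec$seed`.
#'
#' @param spec A [cnn_spec].
#' @return A list of class `cnn_model` with fields `spec`, `weights`
#'   and `trained = FALSE`.
#' @export
build_cnn <- function(spec) {
  if (!inherits(spec, "cnn_spec")) abort_spec("'spec' must be a cnn_spec")
  k2 <- spec$kernel_size^2
  f <- spec$filters
  s3 <- spec$input_size / spec$pool_size^2
  he <- function(nout, nin) {
    matrix(rnorm(nout * nin, sd = sqrt(2 / nin)), nout, nin)
  }
  weights <- withr_seed(spec$seed, list(
    W1 = he(f[1], 3 * k2),      b1 = numeric(f[1]),
    W2 = he(f[2], f[1] * k2),   b2 = numeric(f[2]),
    W3 = he(f[3], f[2] * k2),   b3 = numeric(f[3]),
    W4 = he(1, f[3] * s3 * s3), b4 = 0
  ))
  structure(list(spec = spec, weights = weights, trained = FALSE),
            class = "cnn_model")
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Training configuration for a cascade stage
#'
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param val_fraction Fraction of examples held out internally for the
#'   per-epoch validation history (0 disables).
#' @param class_weights If `TRUE`, weight the binary cross-entropy by
#'   inverse class frequency.
#' @param seed Integer seed controlling shuffling and the validation
#'   split.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 15L, batch_size = 32L,
                         learning_rate = 1e-3, val_fraction = 0.1,
                         class_weights = FALSE, seed = 1L) {
  if (epochs < 1L) abort_config("'epochs' must be >= 1")
  if (batch_size < 1L) abort_config("'batch_size' must be >= 1")
  if (val_fraction < 0 || val_fraction >= 1)
    abort_config("'val_fraction' must be in [0, 1)")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 val_fraction = val_fraction,
                 class_weights = isTRUE(class_weights),
                 seed = as.integer(seed)),
            class = "train_config")
}

# Stack ear crops into the n x (s*s*3) design matrix the C++ core
# consumes, scaled to [0, 1].
crops_to_matrix <- function(crops, input_size) {
  d <- input_size * input_size * 3L
  X <- matrix(0, length(crops), d)
  for (i in seq_along(crops)) {
    px <- if (inherits(crops[[i]], "ear_crop")) crops[[i]]$pixels else crops[[i]]
    if (!identical(dim(px)[1:2], c(input_size, input_size)))
      abort_shape(sprintf(
        "crop %d is %d x %d but the model expects %d x %d", i,
        dim(px)[1], dim(px)[2], input_size, input_size))
    X[i, ] <- as.numeric(px) / 255
  }
  X
}

#' Train one binary stage of the cascade
#'
#' Seeded, single-threaded training with Adam on binary cross-entropy.
#' The shuffling order, internal validation split and initial weights
#' are all derived from the configured seeds, so two runs with identical
#' data and configuration produce identical weights.
#'
#' @param model An untrained or trained `cnn_model` (from [build_cnn]).
#' @param crops List of `ear_crop`s (or bare pixel arrays) of the
#'   model's input size.
#' @param targets Binary vector (0/1), one per crop. Stage 1 uses
#'   `1 = defect`; stage 2 uses `1 = artefact`.
#' @param config A [train_config].
#' @return List with `model` (trained `cnn_model`) and `history` (data
#'   frame with per-epoch `loss`, `accuracy`, `val_loss`,
#'   `val_accuracy`).
#' @export
train_stage <- function(model, crops, targets, config = train_config()) {
  if (!inherits(model, "cnn_model")) abort_spec("'model' must be a cnn_model")
  targets <- as.numeric(targets)
  if (length(crops) != length(targets))
    abort_training("'crops' and 'targets' lengths differ")
  if (anyNA(targets) || !all(targets %in% c(0, 1)))
    abort_training("'targets' must be binary (0/1)")
  if (min(table(factor(targets, levels = c(0, 1)))) < 2L)
    abort_training("need at least 2 examples of each binary class")
  spec <- model$spec
  X <- crops_to_matrix(crops, spec$input_size)
  n <- nrow(X)
  rng <- withr_seed(config$seed, {
    n_val <- floor(n * config$val_fraction)
    val_idx <- if (n_val > 0) sort(sample.int(n, n_val)) else integer()
    tr_idx <- setdiff(seq_len(n), val_idx)
    perms <- matrix(vapply(seq_len(config$epochs),
                           function(e) sample(tr_idx),
                           integer(length(tr_idx))),
                    nrow = length(tr_idx))
    list(val_idx = val_idx, perms = perms)
  })
  if (length(rng$perms) == 0L)
    abort_training("no training examples left after the validation split")
  wts <- rep(1, n)
  if (config$class_weights) {
    tab <- table(factor(targets, levels = c(0, 1)))
    wts <- as.numeric(n / (2 * tab[as.character(targets)]))
  }
  fit <- cnn_train_cpp(X, targets, model$weights, spec$input_size,
                       spec$kernel_size, spec$pool_size, spec$filters,
                       config$epochs, config$batch_size,
                       config$learning_rate,
                       matrix(as.numeric(rng$perms) - 1,
                              nrow = nrow(rng$perms)),
                       as.numeric(rng$val_idx) - 1, wts)
  trained <- structure(list(spec = spec, weights = fit$weights,
                            trained = TRUE), class = "cnn_model")
  history <- data.frame(epoch = seq_len(config$epochs),
                        loss = fit$loss, accuracy = fit$accuracy,
                        val_loss = fit$val_loss,
                        val_accuracy = fit$val_accuracy)
  list(model = trained, history = history)
}

# Forward pass returning one probability per crop.
cnn_scores <- function(model, crops) {
  X <- crops_to_matrix(crops, model$spec$input_size)
  as.numeric(cnn_forward_cpp(X, model$weights, model$spec$input_size,
                             model$spec$kernel_size, model$spec$pool_size,
                             model$spec$filters))
}

#' Train the full two-stage cascade
#'
#' Stage 1 learns healthy (label 0) vs defect (labels 1 and 2) on all
#' ears; stage 2 learns lesion (1) vs artefact (2) on the defect ears
#' only. The two stages share the architecture but not the weights;
#' stage 2 is initialized and shuffled from `seed + 1`.
#'
#' @param crops List of `ear_crop`s.
#' @param labels Integer labels in `{0, 1, 2}`, one per crop (0 healthy,
#'   1 lesion, 2 artefact).
#' @param spec A [cnn_spec] shared by both stages.
#' @param config A [train_config].
#' @return A list of class `cascade_model`: `stage1`, `stage2`
#'   (trained `cnn_model`s), `spec`, `thresholds` (length 2, default
#'   0.5/0.5), `history` (per stage) and `meta` (seeds, epochs, counts,
#'   dataset fingerprint).
#' @export
train_cascade <- function(crops, labels, spec = cnn_spec(),
                          config = train_config()) {
  labels <- as.integer(labels)
  if (length(labels) != length(crops))
    abort_training("'crops' and 'labels' lengths differ")
  if (!all(labels %in% 0:2))
    abort_input("labels must be 0 (healthy), 1 (lesion) or 2 (artefact)")
  spec1 <- spec; spec1$seed <- spec$seed
  spec2 <- spec; spec2$seed <- spec$seed + 1L
  cfg1 <- config
  cfg2 <- config; cfg2$seed <- config$seed + 1L
  s1 <- train_stage(build_cnn(spec1), crops, as.numeric(labels > 0L), cfg1)
  defect <- labels %in% c(1L, 2L)
  s2 <- train_stage(build_cnn(spec2), crops[defect],
                    as.numeric(labels[defect] == 2L), cfg2)
  counts <- as.integer(table(factor(labels, levels = 0:2)))
  structure(list(
    stage1 = s1$model, stage2 = s2$model, spec = spec,
    thresholds = c(stage1 = 0.5, stage2 = 0.5),
    history = list(stage1 = s1$history, stage2 = s2$history),
    meta = list(n_train = length(labels), class_counts = counts,
                n_stage2 = sum(defect),
                seed = config$seed, epochs = config$epochs,
                fingerprint = dataset_fingerprint(crops, labels))
  ), class = "cascade_model")
}

# Cheap order-independent fingerprint of a training set.
dataset_fingerprint <- function(crops, labels) {
  means <- vapply(crops, function(cr) {
    px <- if (inherits(cr, "ear_crop")) cr$pixels else cr
    mean(px)
  }, 0)
  sprintf("n%d_c%s_m%.6f", length(labels),
          paste(as.integer(table(factor(labels, levels = 0:2))),
                collapse = "-"),
          sum(means) / max(1, length(means)))
}

#' Predict labels for a batch of ear crops
#'
#' Stage 1 scores every crop with its probability of being a defect;
#' crops scoring below the stage-1 threshold are labelled 0 and stage 2
#' is never evaluated for them. The remainder get a stage-2 artefact
#' probability: below the stage-2 threshold means lesion (1), at or
#' above means artefact (2). Scores exactly at a threshold take the
#' positive class.
#'
#' @param model A trained [train_cascade] model.
#' @param crops List of `ear_crop`s (may be empty).
#' @return Data frame with one row per crop: `source_id`, `side`,
#'   `label`, `stage1_score`, `stage2_score` (`NA` whenever the label
#'   is 0).
#' @export
predict_batch <- function(model, crops) {
  if (!inherits(model, "cascade_model"))
    abort_spec("'model' must be a cascade_model")
  if (length(crops) == 0L)
    return(data.frame(source_id = character(), side = character(),
                      label = integer(), stage1_score = numeric(),
                      stage2_score = numeric(), stringsAsFactors = FALSE))
  s1 <- cnn_scores(model$stage1, crops)
  defect <- s1 >= model$thresholds[["stage1"]]
  s2 <- rep(NA_real_, length(crops))
  if (any(defect))
    s2[defect] <- cnn_scores(model$stage2, crops[defect])
  label <- integer(length(crops))
  label[defect] <- ifelse(s2[defect] < model$thresholds[["stage2"]], 1L, 2L)
  get_field <- function(field, default) vapply(crops, function(cr) {
    if (inherits(cr, "ear_crop")) cr[[field]] else default
  }, "")
  data.frame(
    source_id = get_field("source_id", "crop"),
    side = get_field("side", NA_character_),
    label = label, stage1_score = s1, stage2_score = s2,
    stringsAsFactors = FALSE)
}

#' Predict the label of a single ear crop
#'
#' @param model A trained [train_cascade] model.
#' @param crop One `ear_crop`.
#' @return One-row data frame, as in [predict_batch].
#' @export
cascade_predict <- function(model, crop) {
  predict_batch(model, list(crop))
}

#' Save / load a cascade model directory
#'
#' A model directory holds one weight file per stage plus a JSON sidecar
#' with the architecture, thresholds, seeds and training-set
#' fingerprint.
#'
#' @param model A `cascade_model`.
#' @param dir Directory to create/populate.
#' @return `dir` (for `save_cascade`) or the restored `cascade_model`
#'   (for `load_cascade`).
#' @export
save_cascade <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  saveRDS(model$stage1$weights, file.path(dir, "stage1_weights.rds"))
  saveRDS(model$stage2$weights, file.path(dir, "stage2_weights.rds"))
  sidecar <- list(
    spec = unclass(model$spec), thresholds = as.list(model$thresholds),
    meta = model$meta)
  jsonlite::write_json(sidecar, file.path(dir, "cascade.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_cascade
#' @export
load_cascade <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "cascade.json"),
                                 simplifyVector = TRUE)
  spec <- do.call(cnn_spec, sidecar$spec[c("input_size", "filters",
                                           "kernel_size", "pool_size",
                                           "seed")])
  restore <- function(file) {
    w <- readRDS(file.path(dir, file))
    structure(list(spec = spec, weights = w, trained = TRUE),
              class = "cnn_model")
  }
  structure(list(
    stage1 = restore("stage1_weights.rds"),
    stage2 = restore("stage2_weights.rds"),
    spec = spec,
    thresholds = unlist(sidecar$thresholds),
    history = NULL,
    meta = sidecar$meta
  ), class = "cascade_model")
}

#' Write predictions to CSV
#'
#' @param predictions Data frame from [predict_batch].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  write.csv(predictions, path, row.names = FALSE)
  invisible(path)
}
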