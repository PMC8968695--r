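# Training orchestration: Adam optimization of the coarse (binary) and fine
# (3-class) models with seeded shuffled batching. Published settings are the
# defaults (Adam, learning rate 0.001, batch size 8, 500 steps per epoch,
# 100 epochs); the desk profile scales the counts down for CPU-scale runs.

#' Training configuration
#'
#' @param learning_rate Adam step size (> 0).
#' @param batch_size Images per optimizer step.
#' @param steps_per_epoch Optimizer steps per epoch.
#' @param epochs Number of epochs.
#' @param loss `"soft_dice"`, `"cross_entropy"`, or `"sum_of_both"` (default:
#'   their sum, consistent with Dice-based evaluation and stable for small
#'   structures).
#' @param seed Integer seed controlling shuffling, dropout and weight
#'   initialization.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 8,
                         steps_per_epoch = 500, epochs = 100,
                         loss = c("sum_of_both", "soft_dice", "cross_entropy"),
                         seed = 1) {
  loss <- match.arg(loss)
  if (!(learning_rate > 0)) stopf("learning_rate must be > 0")
  if (!is_count(batch_size) || batch_size < 1) stopf("batch_size must be >= 1")
  if (!is_count(steps_per_epoch) || steps_per_epoch < 1)
    stopf("steps_per_epoch must be >= 1")
  if (!is_count(epochs) || epochs < 1) stopf("epochs must be >= 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 steps_per_epoch = as.integer(steps_per_epoch),
                 epochs = as.integer(epochs), loss = loss,
                 seed = as.integer(seed)),
            class = "train_config")
}

onehot_labels <- function(labels, n_classes) {
  d <- dim(labels)
  out <- array(0, c(d[1], d[2], n_classes, d[3]))
  for (c in seq_len(n_classes)) out[, , c, ] <- labels == (c - 1L)
  out
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - b1^st$t; c2 <- 1 - b2^st$t
  for (n in names(params)) {
    g <- grads[[n]]
    if (is.null(g)) next
    st$m[[n]] <- b1 * st$m[[n]] + (1 - b1) * g
    st$v[[n]] <- b2 * st$v[[n]] + (1 - b2) * g * g
    params[[n]] <- params[[n]] -
      lr * (st$m[[n]] / c1) / (sqrt(st$v[[n]] / c2) + eps)
  }
  list(params = params, state = st)
}

loss_node <- function(graph, onehot, kind) {
  switch(kind,
    soft_dice = loss_soft_dice(graph$probs, onehot),
    cross_entropy = loss_cross_entropy(graph$probs, onehot),
    sum_of_both = op_scalar_add(loss_soft_dice(graph$probs, onehot),
                                loss_cross_entropy(graph$probs, onehot)))
}

#' Train a segmentation model
#'
#' Runs `epochs * steps_per_epoch` Adam steps over seeded shuffled batches
#' (the dataset is re-shuffled whenever exhausted) and records the loss at
#' every step. Fully reproducible given the seed on a fixed platform.
#'
#' @param model A `nephroseg_model` from [build_network()].
#' @param dataset Non-empty list of [slice_sample()]-like records whose
#'   `image` is at the model input size and whose `label` values are below
#'   `n_classes`.
#' @param cfg A [train_config()].
#' @return A list with `model` (trained) and `history` (per-step loss).
#' @export
train_model <- function(model, dataset, cfg) {
  if (length(dataset) == 0) stopf("dataset must be non-empty")
  s <- model$config$input_size
  ncl <- model$config$n_classes
  for (d in dataset) {
    if (!all(dim(d$image) == c(s, s))) stopf("all images must be %dx%d", s, s)
    if (any(d$label >= ncl)) stopf("label values must be below n_classes")
  }
  n_steps <- cfg$epochs * cfg$steps_per_epoch
  history <- numeric(n_steps)
  with_seed(cfg$seed, {
    opt <- adam_init(model$params)
    queue <- integer(0)
    for (step in seq_len(n_steps)) {
      while (length(queue) < cfg$batch_size)
        queue <- c(queue, sample.int(length(dataset)))
      idx <- queue[seq_len(cfg$batch_size)]
      queue <- queue[-seq_len(cfg$batch_size)]
      xb <- array(0, c(s, s, 1, cfg$batch_size))
      yb <- array(0L, c(s, s, cfg$batch_size))
      for (i in seq_along(idx)) {
        xb[, , 1, i] <- dataset[[idx[i]]]$image
        yb[, , i] <- dataset[[idx[i]]]$label
      }
      oh <- onehot_labels(yb, ncl)
      graph <- forward_graph(model, xb, training = TRUE)
      ln <- loss_node(graph, oh, cfg$loss)
      history[step] <- ln$value
      if (!is.finite(ln$value)) {
        stop(structure(class = c("nephroseg_divergence", "error", "condition"),
                       message = sprintf("non-finite loss at step %d", step),
                       call = NULL, history = history[seq_len(step)]))
      }
      tape_backward(ln)
      grads <- lapply(graph$pnodes, function(nd) nd$grad)
      upd <- adam_step(model$params, grads, opt, cfg$learning_rate)
      model$params <- upd$params
      opt <- upd$state
    }
  })
  list(model = model, history = history)
}

#' Desk-scale pipeline profile
#'
#' A named configuration bundle sized for single-CPU runs: 96-pixel slices, a
#' depth-3 / 8-filter coarse model on full slices, a depth-3 / 8-filter fine
#' model on 48-pixel ROI patches with the proportionally scaled ROI ladder
#' `c(48, 96)`, single-kernel (3x3) blocks with one recurrence step, and
#' short training schedules (5 epochs).
#'
#' @param seed Integer seed used for data generation, initialization and
#'   training.
#' @return A list of configuration objects (`phantom`, `coarse_network`,
#'   `fine_network`, `train_coarse`, `train_fine`, `roi_sizes`,
#'   `balance_bin_width`).
#' @export
desk_profile <- function(seed = 1) {
  blk <- r2p_block_config(kernel_sizes = 3, t = 1, dropout_rate = 0.1)
  list(
    phantom = phantom_config(image_size = 96, seed = seed),
    coarse_network = network_config(input_size = 96, depth = 3,
                                    base_filters = 8, n_classes = 2,
                                    block = blk),
    fine_network = network_config(input_size = 48, depth = 3,
                                  base_filters = 8, n_classes = 3,
                                  block = blk),
    train_coarse = train_config(steps_per_epoch = 12, epochs = 5, seed = seed),
    train_fine = train_config(steps_per_epoch = 64, epochs = 5, seed = seed + 1),
    roi_sizes = c(48, 96),
    balance_bin_width = 50,
    seed = seed
  )
}

# Build the fine-stage training set from ground-truth ROIs: crop, fuzzy
# enhance through the fixed z-score window, rescale to the fine input grid.
build_fine_dataset <- function(samples, roi_sizes, fine_input) {
  out <- list()
  for (s in samples) {
    boxes <- mask_to_rois(s$label > 0L)
    for (b in boxes) {
      roi <- expand_roi(b, dim(s$label), sizes = roi_sizes)
      img <- enhance_windowed(crop_patch(s$image, roi)) / 255
      lab <- crop_patch(s$label, roi)
      out[[length(out) + 1L]] <- slice_sample(
        to_fine_input(img, fine_input, "image"),
        to_fine_input(lab, fine_input, "label"),
        case_id = s$case_id, slice_index = s$slice_index)
    }
  }
  out
}

#' Train the coarse-to-fine cascade
#'
#' The coarse model is trained on full slices with binary labels (kidney and
#' tumor merged into one foreground class). The fine training set is built by
#' cropping ground-truth-derived ROIs, fuzzy-enhancing the patches, balancing
#' by tumor-size bin, and training the 3-class fine model on the resulting
#' patches.
#'
#' @param dataset List of preprocessed [slice_sample()] objects.
#' @param coarse_cfg,fine_cfg [network_config()] objects with `n_classes` 2
#'   and 3.
#' @param train_coarse,train_fine [train_config()] objects for the two
#'   stages.
#' @param roi_sizes ROI window ladder (default `c(128, 256)`).
#' @param balance Balance the fine set by tumor-size bin (default TRUE).
#' @param balance_bin_width Histogram bin width in pixels.
#' @return A list with `coarse`, `fine` (trained models), `histories`, and
#'   `fine_dataset_size`.
#' @export
train_cascade <- function(dataset, coarse_cfg, fine_cfg,
                          train_coarse = train_config(),
                          train_fine = train_coarse,
                          roi_sizes = c(128, 256),
                          balance = TRUE, balance_bin_width = 500) {
  if (coarse_cfg$n_classes != 2 || fine_cfg$n_classes != 3)
    stopf("coarse model must have 2 classes and fine model 3")
  coarse_set <- lapply(dataset, function(s) {
    s$label <- matrix(as.integer(s$label > 0L), nrow(s$label))
    s
  })
  coarse_model <- build_network(coarse_cfg, seed = train_coarse$seed)
  ct <- train_model(coarse_model, coarse_set, train_coarse)

  fine_set <- build_fine_dataset(dataset, roi_sizes, fine_cfg$input_size)
  if (balance) {
    areas <- tumor_areas(fine_set)
    if (length(areas) > 0) {
      hist <- build_tumor_histogram(areas, bin_width = balance_bin_width)
      fine_set <- balance_dataset(fine_set, hist, rng_seed = train_fine$seed)
    }
  }
  fine_model <- build_network(fine_cfg, seed = train_fine$seed)
  ft <- train_model(fine_model, fine_set, train_fine)

  list(coarse = ct$model, fine = ft$model,
       histories = list(coarse = ct$history, fine = ft$history),
       fine_dataset_size = length(fine_set))
}
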