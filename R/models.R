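#' Model specification
#'
#' Describes a 3D-CNN residue classifier. Three architecture families
#' are registered:
#' \describe{
#'   \item{`timed`}{convolutional blocks (ELU activations) with spatial
#'     dropout after each block and a global-average-pooling head -- the
#'     pooling preserves spatial structure and the channel-wise dropout
#'     enforces it. Default blocks: 32/64/128 filters, two 3x3x3
#'     convolutions each, spatial dropout 0.1.}
#'   \item{`prodconn_like`}{convolutional blocks followed by a
#'     flatten + dense hidden-layer head.}
#'   \item{`densenet3d`}{densely connected blocks (same-padded 3x3x3
#'     convolutions whose outputs are concatenated onto the channel
#'     stack, growth rate 8) with 1x1x1 transition convolutions and a
#'     global-average-pooling head.}
#' }
#' All architectures end in a 20-way softmax. New architectures can be
#' registered with [register_architecture()].
#'
#' @param architecture One of `"timed"`, `"prodconn_like"`,
#'   `"densenet3d"` (or a registered name).
#' @param input_shape Length-4 integer vector `c(V, V, V, C)` matching
#'   the voxel configuration the model will consume.
#' @param conv_blocks List of integer vectors, one per block, giving the
#'   filter count of each convolution in the block (architecture default
#'   when `NULL`).
#' @param spatial_dropout_rate Channel-dropout fraction (timed only;
#'   must be > 0 for timed).
#' @param head `"global_average_pooling"` or `"flatten_dense"`
#'   (architecture default when `NULL`).
#' @param dense_units Hidden units of the flatten_dense head.
#' @param n_classes Number of output classes (20).
#' @return A `model_spec` object.
#' @export
model_spec <- function(architecture = c("timed", "prodconn_like",
                                        "densenet3d"),
                       input_shape,
                       conv_blocks = NULL,
                       spatial_dropout_rate = NULL,
                       head = NULL,
                       dense_units = NULL,
                       n_classes = 20L) {
  architecture <- if (length(architecture) > 1) match.arg(architecture)
                  else architecture
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 4) {
    stop("input_shape must be c(V, V, V, C)")
  }
  defaults <- switch(architecture,
    timed = list(conv_blocks = list(c(32, 32), c(64, 64), c(128, 128)),
                 spatial_dropout_rate = 0.1,
                 head = "global_average_pooling", dense_units = integer()),
    prodconn_like = list(conv_blocks = list(16, 32),
                         spatial_dropout_rate = 0,
                         head = "flatten_dense", dense_units = 64L),
    densenet3d = list(conv_blocks = list(c(8, 8), c(8, 8), c(8, 8)),
                      spatial_dropout_rate = 0,
                      head = "global_average_pooling",
                      dense_units = integer()),
    stop("unknown architecture: ", architecture))
  if (is.null(conv_blocks)) conv_blocks <- defaults$conv_blocks
  if (is.null(spatial_dropout_rate)) {
    spatial_dropout_rate <- defaults$spatial_dropout_rate
  }
  if (is.null(head)) head <- defaults$head
  if (is.null(dense_units)) dense_units <- defaults$dense_units

  if (architecture == "timed") {
    if (head != "global_average_pooling") {
      stop("timed requires head = global_average_pooling")
    }
    if (spatial_dropout_rate <= 0) {
      stop("timed requires spatial_dropout_rate > 0")
    }
  }
  if (architecture == "prodconn_like" && head != "flatten_dense") {
    stop("prodconn_like requires head = flatten_dense")
  }
  structure(
    list(architecture = architecture, input_shape = input_shape,
         conv_blocks = conv_blocks,
         spatial_dropout_rate = spatial_dropout_rate,
         head = head, dense_units = as.integer(dense_units),
         n_classes = as.integer(n_classes)),
    class = "model_spec")
}

.arch_registry <- new.env(parent = emptyenv())

#' Register a model architecture builder
#'
#' @param name Architecture name.
#' @param builder Function `(spec) -> list of layers` (see the engine in
#'   this package for layer constructors).
#' @return `name`, invisibly.
#' @export
register_architecture <- function(name, builder) {
  assign(name, builder, envir = .arch_registry)
  invisible(name)
}

build_timed_layers <- function(spec) {
  V <- spec$input_shape[1]; c_in <- spec$input_shape[4]
  layers <- list()
  for (blk in spec$conv_blocks) {
    for (f in blk) {
      layers <- c(layers, list(layer_conv3d(c_in, f, 3L, "valid"),
                               layer_elu()))
      c_in <- f
      V <- V - 2L
      if (V < 1) stop("input too small for the configured conv blocks")
    }
    layers <- c(layers,
                list(layer_spatial_dropout(spec$spatial_dropout_rate)))
  }
  c(layers, list(layer_gap(), layer_dense(c_in, spec$n_classes)))
}

build_prodconn_layers <- function(spec) {
  V <- spec$input_shape[1]; c_in <- spec$input_shape[4]
  layers <- list()
  for (blk in spec$conv_blocks) {
    for (f in blk) {
      layers <- c(layers, list(layer_conv3d(c_in, f, 3L, "valid"),
                               layer_elu()))
      c_in <- f
      V <- V - 2L
      if (V < 1) stop("input too small for the configured conv blocks")
    }
  }
  n_flat <- V^3 * c_in
  layers <- c(layers, list(layer_flatten()))
  for (u in spec$dense_units) {
    layers <- c(layers, list(layer_dense(n_flat, u, activation = "elu")))
    n_flat <- u
  }
  c(layers, list(layer_dense(n_flat, spec$n_classes)))
}

build_densenet_layers <- function(spec) {
  c_in <- spec$input_shape[4]
  growth <- 8L
  layers <- list()
  for (b in seq_along(spec$conv_blocks)) {
    n_layers <- length(spec$conv_blocks[[b]])
    layers <- c(layers, list(layer_dense_block(c_in, growth, n_layers)))
    c_in <- c_in + n_layers * growth
    if (b < length(spec$conv_blocks)) {
      trans <- max(growth, c_in %/% 2L)
      layers <- c(layers, list(layer_conv3d(c_in, trans, 1L, "valid"),
                               layer_elu()))
      c_in <- trans
    }
  }
  c(layers, list(layer_gap(), layer_dense(c_in, spec$n_classes)))
}

register_architecture("timed", build_timed_layers)
register_architecture("prodconn_like", build_prodconn_layers)
register_architecture("densenet3d", build_densenet_layers)

#' Build an untrained model
#'
#' Instantiates the layers of a [model_spec()] with seeded He-normal
#' initial weights; the same spec and seed always produce identical
#' initial predictions.
#'
#' @param spec A `model_spec`.
#' @param seed Integer seed for weight initialisation.
#' @return A `vox_model`: list with `spec`, `layers`, `class_order`,
#'   `n_parameters` and (after training) `history`.
#' @export
build_model <- function(spec, seed = 1L) {
  if (!exists(spec$architecture, envir = .arch_registry)) {
    stop("unknown architecture: ", spec$architecture)
  }
  builder <- get(spec$architecture, envir = .arch_registry)
  layers <- withr::with_seed(as.integer(seed), builder(spec))
  structure(
    list(spec = spec, layers = layers, class_order = AA_ALPHABET,
         n_parameters = n_parameters(layers), history = NULL),
    class = "vox_model")
}

#' @export
print.vox_model <- function(x, ...) {
  cat("<vox_model> ", x$spec$architecture, " (",
      paste(x$spec$input_shape, collapse = "x"), " -> ",
      x$spec$n_classes, " classes, ",
      format(x$n_parameters, big.mark = ","), " parameters",
      if (!is.null(x$history)) paste0(", trained ", nrow(x$history),
                                      " epochs"),
      ")\n", sep = "")
  invisible(x)
}

#' Training configuration
#'
#' @param epochs Number of epochs (default 50).
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam learning rate.
#' @param optimizer Optimiser name (only `"adam"` is implemented).
#' @param seed Integer seed controlling balancing draws, shuffling and
#'   dropout.
#' @param balance Use balanced per-epoch undersampling
#'   ([balanced_epoch_indices()]) for the training split (default TRUE).
#' @param clip_norm Global gradient-norm clip (default 5; `Inf` disables),
#'   a standard stabiliser for small-batch training.
#' @return A `training_config` object.
#' @export
training_config <- function(epochs = 50L, batch_size = 64L,
                            learning_rate = 1e-3, optimizer = "adam",
                            seed = 1L, balance = TRUE, clip_norm = 5) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (optimizer != "adam") stop("unsupported optimizer: ", optimizer)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 seed = as.integer(seed), balance = isTRUE(balance),
                 clip_norm = clip_norm),
            class = "training_config")
}

#' Train a model on a frame dataset
#'
#' Minimises 20-class softmax cross-entropy with Adam. With
#' `balance = TRUE` each epoch consumes a balanced index plan from
#' [balanced_epoch_indices()] (fresh per-epoch redraw of the
#' over-represented classes); otherwise each epoch is a plain shuffle of
#' the full training split. The returned model carries a `history`
#' data.frame (per-epoch loss and, when a validation split exists,
#' validation macro-recall) and a `consumed` matrix of per-epoch label
#' counts actually seen by the network.
#'
#' @param model A `vox_model`.
#' @param dataset A `frame_dataset` with a `train` split (and optionally
#'   `validation`).
#' @param config A [training_config()].
#' @param verbose Print per-epoch progress.
#' @return The trained `vox_model`.
#' @export
train_model <- function(model, dataset, config = training_config(),
                        verbose = FALSE) {
  if (!"train" %in% names(dataset$splits)) {
    stop("dataset has no train split; call split_dataset() first")
  }
  train_idx <- dataset$splits$train
  if (length(train_idx) == 0) stop("train split is empty")
  val_idx <- dataset$splits$validation
  layers <- model$layers
  state <- adam_init(layers)
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     val_macro_recall = numeric())
  consumed <- matrix(0L, config$epochs, 20,
                     dimnames = list(NULL, AA_ALPHABET))
  t_global <- 0L

  withr::with_seed(derive_seed(config$seed, 0L), {
    for (epoch in seq_len(config$epochs)) {
      idx <- if (config$balance) {
        balanced_epoch_indices(dataset, "train", epoch, config$seed)$indices
      } else {
        sample(train_idx)
      }
      consumed[epoch, ] <- tabulate(dataset$labels[idx], nbins = 20L)
      losses <- numeric()
      starts <- seq(1, length(idx), by = config$batch_size)
      for (s in starts) {
        bi <- idx[s:min(s + config$batch_size - 1, length(idx))]
        X <- dataset$tensors[bi, , , , , drop = FALSE]
        fw <- nn_forward(layers, X, training = TRUE)
        ce <- softmax_xent(fw$logits, dataset$labels[bi])
        grads <- nn_backward(layers, fw$caches, ce$dlogits)
        grads <- clip_gradients(grads, config$clip_norm)
        t_global <- t_global + 1L
        upd <- adam_update(layers, grads, state, config$learning_rate,
                           t_global)
        layers <- upd$layers; state <- upd$state
        losses <- c(losses, ce$loss)
      }
      val_mr <- NA_real_
      if (length(val_idx) > 0) {
        P <- predict_tensor_batch(layers, dataset$tensors, val_idx)
        pred <- max.col(P, ties.method = "first")
        val_mr <- macro_recall_from_indices(dataset$labels[val_idx], pred)
      }
      hist <- rbind(hist, data.frame(epoch = epoch, loss = mean(losses),
                                     val_macro_recall = val_mr))
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f val macro-recall %s",
                        epoch, mean(losses),
                        ifelse(is.na(val_mr), "-", sprintf("%.3f", val_mr))))
      }
    }
  })
  model$layers <- layers
  model$history <- hist
  model$consumed <- consumed[seq_len(config$epochs), , drop = FALSE]
  model
}

# forward pass over dataset rows in chunks; returns (n, 20) probabilities
predict_tensor_batch <- function(layers, tensors, idx, chunk = 256L) {
  out <- matrix(0, length(idx), 20)
  starts <- seq(1, length(idx), by = chunk)
  for (s in starts) {
    bi <- idx[s:min(s + chunk - 1, length(idx))]
    X <- tensors[bi, , , , , drop = FALSE]
    fw <- nn_forward(layers, X, training = FALSE)
    out[s:(s + length(bi) - 1), ] <- softmax_rows(fw$logits)
  }
  out
}

macro_recall_from_indices <- function(true_idx, pred_idx) {
  classes <- sort(unique(true_idx))
  mean(vapply(classes, function(cl) {
    mean(pred_idx[true_idx == cl] == cl)
  }, numeric(1)))
}

#' Predict per-residue amino-acid probabilities for a structure
#'
#' Voxelises every residue with the supplied configuration and runs the
#' model on each frame independently, returning one row of class
#' probabilities per residue in chain/sequence order.
#'
#' @param model A `vox_model`.
#' @param structure A `backbone` object.
#' @param config The `voxel_config` the model was trained with (its
#'   shape must match the model's `input_shape`).
#' @param constraints Optional per-residue property override vector
#'   (design-time site fixing); requires a property channel.
#' @return A `probability_matrix`: n x 20 row-stochastic matrix with
#'   columns in [AA_ALPHABET] order; attributes `skipped` (data.frame)
#'   and `structure_id`.
#' @export
predict_structure <- function(model, structure, config,
                              constraints = NULL) {
  V <- config$voxels_per_side
  C <- length(config_channels(config))
  if (!all(model$spec$input_shape == c(V, V, V, C))) {
    stop("model input shape (",
         paste(model$spec$input_shape, collapse = "x"),
         ") does not match config frame shape (",
         paste(c(V, V, V, C), collapse = "x"), ")")
  }
  if (!is.null(constraints) && config$property_channel == "none") {
    stop("constraints require a property channel in the voxel config")
  }
  vx <- voxelise_structure(structure, config, constraints)
  n <- length(vx$frames)
  if (n == 0) stop("no voxelisable residues in structure")
  tensors <- array(0, dim = c(n, V, V, V, C))
  for (i in seq_len(n)) tensors[i, , , , ] <- vx$frames[[i]]$tensor
  P <- predict_tensor_batch(model$layers, tensors, seq_len(n))
  colnames(P) <- AA_ALPHABET
  rownames(P) <- vapply(vx$frames, function(f) {
    paste0(f$meta$chain, f$meta$resno)
  }, character(1))
  structure(P, class = c("probability_matrix", "matrix"),
            skipped = vx$skipped, structure_id = structure$structure_id)
}

#' Save / load a trained model
#'
#' `write_model` stores the model plus a human-readable JSON sidecar
#' (`<path>.json`) describing the architecture, class order and voxel
#' configuration.
#'
#' @param model A `vox_model`.
#' @param path Output path (conventionally `.rds`).
#' @param config Optional `voxel_config` recorded in the sidecar.
#' @return `path` invisibly (`read_model` returns the model).
#' @export
write_model <- function(model, path, config = NULL) {
  saveRDS(model, path)
  sidecar <- list(
    architecture = model$spec$architecture,
    input_shape = model$spec$input_shape,
    n_parameters = model$n_parameters,
    class_order = model$class_order,
    voxel_config = if (!is.null(config)) unclass(config))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "vox_model")) stop("not a vox_model file: ", path)
  m
}
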