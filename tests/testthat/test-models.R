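test_that("forward pass returns row-stochastic 20-class output", {
  spec <- tiny_timed_spec()
  m <- build_model(spec, seed = 1)
  X <- array(stats::runif(2 * 9^3 * 5), dim = c(2, 9, 9, 9, 5))
  fw <- voxdesign:::nn_forward(m$layers, X, training = FALSE)
  P <- voxdesign:::softmax_rows(fw$logits)
  expect_equal(dim(P), c(2, 20))
  expect_equal(rowSums(P), c(1, 1), tolerance = 1e-5)
  expect_true(all(P >= 0))
  expect_gt(m$n_parameters, 0)
})

test_that("spec invariants distinguish the architecture families", {
  expect_error(model_spec("timed", c(9, 9, 9, 5), spatial_dropout_rate = 0),
               "spatial_dropout_rate")
  expect_error(model_spec("timed", c(9, 9, 9, 5), head = "flatten_dense"),
               "global_average_pooling")
  expect_error(model_spec("prodconn_like", c(9, 9, 9, 5),
                          head = "global_average_pooling"),
               "flatten_dense")
  pc <- model_spec("prodconn_like", c(9, 9, 9, 5), conv_blocks = list(8))
  expect_equal(pc$head, "flatten_dense")
  m <- build_model(pc, seed = 1)
  # no global-pooling stage in the prodconn-style head
  types <- vapply(m$layers, function(l) l$type, character(1))
  expect_false("gap" %in% types)
  expect_true("flatten" %in% types)
  expect_error(build_model(structure(list(architecture = "nope"),
                                     class = "model_spec")),
               "unknown architecture")
})

test_that("densenet3d builds and produces valid distributions", {
  spec <- model_spec("densenet3d", c(9, 9, 9, 5),
                     conv_blocks = list(c(8), c(8)))
  m <- build_model(spec, seed = 2)
  X <- array(stats::runif(3 * 9^3 * 5), dim = c(3, 9, 9, 9, 5))
  fw <- voxdesign:::nn_forward(m$layers, X, training = FALSE)
  P <- voxdesign:::softmax_rows(fw$logits)
  expect_equal(dim(P), c(3, 20))
  expect_equal(rowSums(P), rep(1, 3), tolerance = 1e-6)
})

test_that("model construction is deterministic under the seed", {
  spec <- tiny_timed_spec()
  X <- array(stats::runif(2 * 9^3 * 5), dim = c(2, 9, 9, 9, 5))
  p1 <- voxdesign:::nn_forward(build_model(spec, seed = 7)$layers, X)$logits
  p2 <- voxdesign:::nn_forward(build_model(spec, seed = 7)$layers, X)$logits
  p3 <- voxdesign:::nn_forward(build_model(spec, seed = 8)$layers, X)$logits
  expect_identical(p1, p2)
  expect_false(identical(p1, p3))
})

test_that("convolution gradients match finite differences", {
  # tiny net, numeric gradient check on a few weights
  set.seed(3)
  layers <- list(voxdesign:::layer_conv3d(2, 3, 3L, "valid"),
                 voxdesign:::layer_elu(),
                 voxdesign:::layer_gap(),
                 voxdesign:::layer_dense(3, 4))
  X <- array(stats::rnorm(2 * 5^3 * 2), dim = c(2, 5, 5, 5, 2))
  labels <- c(1L, 3L)
  loss_of <- function(ls) {
    fw <- voxdesign:::nn_forward(ls, X, training = FALSE)
    voxdesign:::softmax_xent(fw$logits, labels)$loss
  }
  fw <- voxdesign:::nn_forward(layers, X, training = FALSE)
  ce <- voxdesign:::softmax_xent(fw$logits, labels)
  grads <- voxdesign:::nn_backward(layers, fw$caches, ce$dlogits)
  eps <- 1e-5
  for (probe in list(c(1, 5, 2), c(1, 20, 1), c(4, 2, 3))) {
    li <- probe[1]; i <- probe[2]; j <- probe[3]
    lp <- layers; lp[[li]]$W[i, j] <- lp[[li]]$W[i, j] + eps
    lm <- layers; lm[[li]]$W[i, j] <- lm[[li]]$W[i, j] - eps
    numeric_grad <- (loss_of(lp) - loss_of(lm)) / (2 * eps)
    expect_equal(grads[[li]]$W[i, j], numeric_grad, tolerance = 1e-4)
  }
})

test_that("training reduces loss and honours the balancing contract", {
  ds <- small_dataset()
  m <- build_model(tiny_timed_spec(), seed = 4)
  tc <- training_config(epochs = 3, batch_size = 16, learning_rate = 5e-3,
                        seed = 5, balance = TRUE)
  m <- train_model(m, ds, tc)
  expect_equal(nrow(m$history), 3)
  expect_lt(m$history$loss[3], m$history$loss[1])
  # per-epoch consumed label histogram is uniform over present classes
  for (ep in 1:3) {
    consumed <- m$consumed[ep, ]
    present <- consumed[consumed > 0]
    expect_true(all(present == present[1]))
  }
  # unbalanced training consumes the skewed histogram instead
  mu <- train_model(build_model(tiny_timed_spec(), seed = 4), ds,
                    training_config(epochs = 1, batch_size = 16,
                                    learning_rate = 5e-3, seed = 5,
                                    balance = FALSE))
  expect_equal(unname(mu$consumed[1, ]),
               unname(class_counts(ds, "train")))
  expect_error(train_model(build_model(tiny_timed_spec(), seed = 1),
                           build_dataset(make_helix(5), small_config())),
               "train split")
})

test_that("predict_structure returns one stochastic row per residue", {
  h <- make_helix(12)
  cfg <- small_config()
  m <- build_model(tiny_timed_spec(), seed = 6)
  P <- predict_structure(m, h, cfg)
  expect_equal(dim(P), c(12, 20))
  expect_equal(unname(rowSums(P)), rep(1, 12), tolerance = 1e-5)
  expect_equal(colnames(P), AA_ALPHABET)
  # mismatched config errors out
  expect_error(predict_structure(m, h, voxel_config(voxels_per_side = 11)),
               "input shape")
  expect_error(predict_structure(m, h, cfg, constraints = rep(1, 12)),
               "property channel")
})

test_that("predictions are invariant to rigid motions of the input", {
  h <- make_helix(10)
  cfg <- small_config()
  m <- build_model(tiny_timed_spec(), seed = 9)
  P1 <- predict_structure(m, h, cfg)
  h2 <- transform_backbone(ensure_virtual_cbeta(h),
                           random_rigid_transform(31))
  P2 <- predict_structure(m, h2, cfg)
  expect_equal(unclass(P2), unclass(P1), tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("models round-trip through disk with their sidecar", {
  m <- build_model(tiny_timed_spec(), seed = 2)
  tf <- withr::local_tempfile(fileext = ".rds")
  write_model(m, tf, config = small_config())
  m2 <- read_model(tf)
  expect_identical(m2$layers, m$layers)
  sidecar <- jsonlite::read_json(paste0(tf, ".json"))
  expect_equal(sidecar$architecture, "timed")
  expect_equal(unlist(sidecar$input_shape), c(9, 9, 9, 5))
})
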