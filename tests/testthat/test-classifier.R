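# small input shapes keep these structural tests fast; the full-scale
# (timesteps = 900) path differs only in loop length

test_that("model configuration validates its invariants", {
  expect_error(model_config(num_classes = 5), "4, 8 or 16")
  expect_error(model_config(recurrent_units = 0), "recurrent_units")
  cfg <- model_config(num_classes = 16)
  expect_equal(cfg$learning_rate, 5e-4)
  expect_equal(cfg$recurrent_units, 128L)
  expect_equal(cfg$fc_units, 64L)
  expect_equal(cfg$recurrent_layers, 2L)
})

test_that("softmax head outputs probability vectors of the right width", {
  set.seed(1)
  X <- array(rnorm(4 * 12 * 12), c(4, 12, 12))
  for (variant in c("GRU", "LSTM", "RNN", "CNN")) {
    for (K in c(4L, 16L)) {
      cfg <- model_config(variant = variant, recurrent_units = 8L,
                          fc_units = 6L, num_classes = K,
                          input_shape = c(12L, 12L))
      m <- build_model(cfg, seed = 2)
      pr <- predict(m, X)$probabilities
      expect_equal(dim(pr), c(4L, K))
      expect_true(all(pr >= 0))
      expect_equal(rowSums(pr), rep(1, 4), tolerance = 1e-6)
    }
  }
})

test_that("GRU parameter count matches the closed-form hand count", {
  cfg <- model_config(variant = "GRU", num_classes = 16,
                      input_shape = c(900L, 12L))
  m <- build_model(cfg)
  H <- 128; d <- 12; K <- 16
  expected <- 3 * (d * H + H * H + H) +   # layer 1: z, r, candidate gates
    3 * (H * H + H * H + H) +             # layer 2
    (H * 64 + 64) +                       # fully connected
    (64 * K + K)                          # softmax head
  expect_equal(count_parameters(m), expected)
  # LSTM has 4 gates in place of the GRU's 3
  ml <- build_model(model_config(variant = "LSTM", num_classes = 16,
                                 input_shape = c(900L, 12L)))
  expect_equal(count_parameters(ml),
               4 * (d * H + H * H + H) + 4 * (2 * H * H + H) +
                 (H * 64 + 64) + (64 * K + K))
})

test_that("argmax prediction breaks ties toward the lowest class index", {
  cfg <- model_config(variant = "GRU", recurrent_units = 4L, fc_units = 3L,
                      num_classes = 4L, input_shape = c(5L, 12L))
  m <- build_model(cfg, seed = 1)
  # zero the head: logits identically 0, so probabilities are uniform
  m$params[["out.W"]][] <- 0
  m$params[["out.b"]][] <- 0
  set.seed(2)
  pred <- predict(m, array(rnorm(3 * 5 * 12), c(3, 5, 12)))
  expect_true(all(pred$probabilities == 0.25))
  expect_equal(pred$labels, rep(0L, 3L))
})

test_that("training validates labels and refuses empty sets", {
  cfg <- model_config(variant = "GRU", recurrent_units = 4L, fc_units = 3L,
                      num_classes = 4L, input_shape = c(5L, 6L))
  m <- build_model(cfg)
  X <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
  expect_error(train_model(m, X, c(0L, 1L, 2L, 7L)), "labels must lie")
  expect_error(train_model(m, array(0, c(0, 5, 6)), integer(0)), "empty")
})

test_that("a GRU memorizes a small separable set and training is
           deterministic", {
  set.seed(5)
  n <- 16L
  X <- array(rnorm(n * 10 * 6), c(n, 10, 6))
  y <- rep(0:1, each = n / 2L)
  X[y == 1L, , 1L] <- X[y == 1L, , 1L] + 2    # shift one channel
  cfg <- model_config(variant = "GRU", recurrent_units = 16L,
                      fc_units = 8L, num_classes = 4L,
                      input_shape = c(10L, 6L))
  tc <- training_config(epochs = 150L, batch_size = 8L,
                        validation_fraction = 0,
                        early_stopping_patience = 1000L, seed = 3L)
  m1 <- train_model(build_model(cfg, seed = 9), X, y, tc)
  expect_equal(training_accuracy(m1, X, y), 1)
  m2 <- train_model(build_model(cfg, seed = 9), X, y, tc)
  expect_lt(abs(tail(m1$history$train_loss, 1) -
                  tail(m2$history$train_loss, 1)), 1e-6)
  expect_identical(m1$history, m2$history)
})

test_that("zero learning rate freezes the loss", {
  set.seed(6)
  X <- array(rnorm(8 * 6 * 4), c(8, 6, 4))
  y <- rep(0:1, 4L)
  cfg <- model_config(variant = "RNN", recurrent_units = 5L, fc_units = 4L,
                      num_classes = 4L, input_shape = c(6L, 4L),
                      learning_rate = 0)
  m <- train_model(build_model(cfg, seed = 1), X, y,
                   training_config(epochs = 5L, batch_size = 4L,
                                   validation_fraction = 0,
                                   early_stopping_patience = 100L,
                                   seed = 2L))
  expect_lt(diff(range(m$history$train_loss)), 1e-9)
})

test_that("predict agrees with evaluate's per-sample assignments", {
  set.seed(8)
  X <- array(rnorm(10 * 8 * 12), c(10, 8, 12))
  y <- sample(0:3, 10, replace = TRUE)
  cfg <- model_config(variant = "GRU", recurrent_units = 6L, fc_units = 5L,
                      num_classes = 4L, input_shape = c(8L, 12L))
  m <- build_model(cfg, seed = 4)
  pred <- predict(m, X)
  rep_ <- evaluate_model(m, X, y)
  o <- brute_force_metrics(as.character(y), as.character(pred$labels),
                           as.character(0:3))
  expect_equal(rep_$accuracy, o$accuracy)
  expect_identical(unname(rep_$confusion), unname(o$confusion + 0L))
})

test_that("analytic gradients match numerical differentiation (GRU)", {
  ns <- asNamespace("odontomesh")
  cfg <- model_config(variant = "GRU", recurrent_layers = 2L,
                      recurrent_units = 4L, fc_units = 3L,
                      num_classes = 4L, input_shape = c(6L, 3L))
  m <- build_model(cfg, seed = 12)
  set.seed(13)
  X <- array(rnorm(3 * 6 * 3), c(3, 6, 3))
  y <- c(1L, 2L, 3L)
  xs <- ns$slice_timesteps(X, 1:3)
  fw <- ns$nn_forward(m$params, cfg, xs)
  sx <- ns$softmax_xent(fw$logits, y + 1L)
  grads <- ns$nn_backward(m$params, cfg, fw, sx$dlogits)
  for (nm in names(m$params)) {
    n <- length(m$params[[nm]])
    for (k in unique(c(1L, n))) {
      eps <- 1e-5
      pp <- m$params
      pp[[nm]][k] <- pp[[nm]][k] + eps
      l1 <- ns$softmax_xent(ns$nn_forward(pp, cfg, xs)$logits, y + 1L)$loss
      pp[[nm]][k] <- pp[[nm]][k] - 2 * eps
      l2 <- ns$softmax_xent(ns$nn_forward(pp, cfg, xs)$logits, y + 1L)$loss
      expect_lt(abs((l1 - l2) / (2 * eps) - grads[[nm]][k]), 1e-5)
    }
  }
})

test_that("the ablation grid trains each cell and is seed-reproducible", {
  set.seed(20)
  # tiny synthetic two-class mesh set: incisors vs molars
  specs <- tooth_class_specs()
  meshes <- list(); labels <- integer(0)
  for (s in 1:6) {
    for (nm in c("Central Incisor (L)", "1st Molar (L)")) {
      meshes[[length(meshes) + 1L]] <-
        decimate_mesh(generate_tooth(specs[[nm]], seed = s * 31 +
                                       (nm == "1st Molar (L)"),
                                     dense_faces = 800), 16L)
      labels <- c(labels, as.integer(nm == "1st Molar (L)"))
    }
  }
  ds <- list(meshes = meshes, labels = labels)
  tc <- training_config(epochs = 3L, batch_size = 4L,
                        validation_fraction = 0,
                        early_stopping_patience = 100L)
  tab <- run_ablation(ds, variants = c("GRU", "CNN"), subsets = "both",
                      seeds = 1L, num_classes = 4L, train_cfg = tc,
                      model_args = list(recurrent_units = 6L, fc_units = 4L))
  expect_equal(nrow(tab), 2L)
  expect_true(all(is.finite(tab$mean_accuracy)))
  tab2 <- run_ablation(ds, variants = "GRU", subsets = "both",
                       seeds = 1L, num_classes = 4L, train_cfg = tc,
                       model_args = list(recurrent_units = 6L,
                                         fc_units = 4L))
  expect_equal(tab2$mean_accuracy,
               tab$mean_accuracy[tab$variant == "GRU"])
})
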