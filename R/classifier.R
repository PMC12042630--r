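#' Classifier architecture configuration
#'
#' The reference architecture is a stack of two recurrent layers of 128
#' gated recurrent units each — the first returning its full output
#' sequence, the second only its final state — followed by a 64-neuron
#' fully connected ReLU layer and a softmax head with 4, 8 or 16 outputs
#' (one per tooth category). Training uses sparse categorical
#' cross-entropy with Adam at learning rate 0.0005. Each feature-image row
#' is one timestep, so a 900-triangle mesh is a 900-step sequence of
#' 12-dimensional observations.
#'
#' Baseline variants for ablation share the recurrent topology (LSTM,
#' vanilla RNN with identical layer/unit counts) or replace it with a small
#' CNN: two blocks of 3x3 convolution (32 then 64 filters, ReLU, 2x2
#' max-pool) over the 1-channel feature image, then the same FC(64) head.
#'
#' @param variant one of `"GRU"`, `"LSTM"`, `"RNN"`, `"CNN"`.
#' @param recurrent_layers integer, default 2.
#' @param recurrent_units integer, default 128.
#' @param fc_units integer, default 64.
#' @param num_classes 4, 8 or 16.
#' @param input_shape integer length-2 `(timesteps, features)`, e.g.
#'   `c(900, 12)`.
#' @param learning_rate Adam learning rate, default 0.0005.
#' @param dropout dropout probability on the pre-FC representation
#'   (default 0, as in the reference architecture).
#' @return an object of class `model_config`.
#' @export
model_config <- function(variant = c("GRU", "LSTM", "RNN", "CNN"),
                         recurrent_layers = 2L, recurrent_units = 128L,
                         fc_units = 64L, num_classes = 16L,
                         input_shape = c(900L, 12L),
                         learning_rate = 5e-4, dropout = 0) {
  variant <- match.arg(variant)
  num_classes <- as.integer(num_classes)
  if (!num_classes %in% c(4L, 8L, 16L))
    stop("num_classes must be 4, 8 or 16")
  if (recurrent_units < 1L) stop("recurrent_units must be >= 1")
  if (learning_rate < 0) stop("learning_rate must be >= 0")
  structure(list(variant = variant,
                 recurrent_layers = as.integer(recurrent_layers),
                 recurrent_units = as.integer(recurrent_units),
                 fc_units = as.integer(fc_units),
                 num_classes = num_classes,
                 input_shape = as.integer(input_shape),
                 learning_rate = as.numeric(learning_rate),
                 dropout = as.numeric(dropout),
                 loss = "sparse_categorical_crossentropy"),
            class = "model_config")
}

#' Training configuration
#'
#' @param epochs maximum epochs (default 100).
#' @param batch_size minibatch size (default 32).
#' @param early_stopping_patience epochs without validation-loss
#'   improvement before stopping (default 10); the best-validation-loss
#'   checkpoint is returned.
#' @param seed integer seed controlling shuffling, the validation
#'   carve-out and dropout.
#' @param validation_fraction fraction of the training set held out for
#'   early stopping (default 0.1; 0 disables the carve-out and early
#'   stopping then monitors training loss).
#' @param clip_norm global gradient-norm clipping threshold (default 5;
#'   `Inf` disables clipping). Standard stabilizer for recurrent nets.
#' @return an object of class `training_config`.
#' @export
training_config <- function(epochs = 100L, batch_size = 32L,
                            early_stopping_patience = 10L, seed = 1L,
                            validation_fraction = 0.1, clip_norm = 5) {
  if (epochs < 1L) stop("epochs must be >= 1")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 seed = as.integer(seed),
                 validation_fraction = as.numeric(validation_fraction),
                 clip_norm = as.numeric(clip_norm)),
            class = "training_config")
}

#' Build an untrained classifier
#'
#' Initializes the network parameters (Glorot-uniform weights, zero biases,
#' LSTM forget-gate bias 1) from a seed, so identical seeds give identical
#' untrained models.
#'
#' @param cfg a [model_config()].
#' @param seed integer initialization seed.
#' @return an object of class `mesh_classifier`.
#' @export
build_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  params <- with_seed(seed, {
    p <- if (cfg$variant == "CNN") {
      init_cnn_params(cfg$input_shape)
    } else {
      init_recurrent_params(cfg$variant, cfg$input_shape[2L],
                            cfg$recurrent_layers, cfg$recurrent_units)
    }
    pre_fc <- if (cfg$variant == "CNN") {
      pool2 <- function(n) ceiling(ceiling(n / 2) / 2)   # two 2x2 pools
      pool2(cfg$input_shape[1L]) * pool2(cfg$input_shape[2L]) * 64L
    } else {
      cfg$recurrent_units
    }
    p[["fc.W"]] <- glorot(pre_fc, cfg$fc_units)
    p[["fc.b"]] <- numeric(cfg$fc_units)
    p[["out.W"]] <- glorot(cfg$fc_units, cfg$num_classes)
    p[["out.b"]] <- numeric(cfg$num_classes)
    p
  })
  structure(list(cfg = cfg, params = params, trained = FALSE,
                 history = NULL, class_names = NULL),
            class = "mesh_classifier")
}

#' Total trainable parameter count
#' @param model a `mesh_classifier`.
#' @return integer.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# coerce assorted inputs (N x T x F array, list of feature images or
# matrices) into an N x T x F array
as_input_array <- function(x, input_shape) {
  if (is.list(x)) {
    mats <- lapply(x, function(el) {
      if (inherits(el, "feature_image")) el$pixels else as.matrix(el)
    })
    arr <- array(0, c(length(mats), nrow(mats[[1L]]), ncol(mats[[1L]])))
    for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
    x <- arr
  }
  if (length(dim(x)) == 2L) x <- array(x, c(1L, dim(x)))
  if (length(dim(x)) != 3L)
    stop("input must be an N x timesteps x features array")
  if (!is.null(input_shape) &&
      !all(dim(x)[2:3] == input_shape))
    stop(sprintf("input shape %d x %d does not match the model's %d x %d",
                 dim(x)[2L], dim(x)[3L], input_shape[1L], input_shape[2L]))
  x
}

# slice an N x T x F array into a list of T (B x F) matrices for rows `idx`
slice_timesteps <- function(X, idx) {
  sub <- X[idx, , , drop = FALSE]
  Tn <- dim(sub)[2L]
  lapply(seq_len(Tn), function(t)
    matrix(sub[, t, , drop = FALSE], dim(sub)[1L], dim(sub)[3L]))
}

#' Train a classifier
#'
#' Minibatch Adam on sparse categorical cross-entropy. A validation
#' fraction is carved out of the training set for early stopping; the
#' parameters with the best monitored loss are restored at the end. The
#' run is deterministic given the training seed (and the model's
#' initialization seed).
#'
#' @param model an untrained (or previously trained) `mesh_classifier`.
#' @param x training inputs: `N x timesteps x features` array, or a list of
#'   `feature_image`s / matrices.
#' @param y integer class labels in `0..(num_classes-1)`.
#' @param cfg a [training_config()].
#' @param verbose print per-epoch losses.
#' @return the trained `mesh_classifier`, with a `history` data.frame
#'   (epoch, train_loss, val_loss).
#' @export
train_model <- function(model, x, y, cfg = training_config(),
                        verbose = FALSE) {
  stopifnot(inherits(model, "mesh_classifier"),
            inherits(cfg, "training_config"))
  X <- as_input_array(x, model$cfg$input_shape)
  N <- dim(X)[1L]
  if (N == 0L) stop("training set is empty")
  y <- as.integer(y)
  if (length(y) != N) stop("x and y lengths differ")
  K <- model$cfg$num_classes
  if (any(y < 0L | y >= K))
    stop(sprintf("labels must lie in [0, %d); found %d", K,
                 y[which(y < 0L | y >= K)[1L]]))
  yy <- y + 1L

  params <- model$params
  lr <- model$cfg$learning_rate
  hist_epoch <- integer(0); hist_train <- numeric(0); hist_val <- numeric(0)

  with_seed(cfg$seed, {
    n_val <- floor(cfg$validation_fraction * N)
    val_idx <- if (n_val >= 1L) sort(sample.int(N, n_val)) else integer(0)
    tr_idx <- setdiff(seq_len(N), val_idx)
    if (length(tr_idx) == 0L) stop("validation carve-out leaves no training data")

    state <- adam_init(params)
    best_loss <- Inf
    best_params <- params
    patience_left <- cfg$early_stopping_patience

    xs_val <- if (length(val_idx)) slice_timesteps(X, val_idx) else NULL

    for (epoch in seq_len(cfg$epochs)) {
      ord <- tr_idx[sample.int(length(tr_idx))]
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      tot_loss <- 0
      for (bi in batches) {
        xs <- slice_timesteps(X, bi)
        fw <- nn_forward(params, model$cfg, xs, train = TRUE)
        sx <- softmax_xent(fw$logits, yy[bi])
        tot_loss <- tot_loss + sx$loss * length(bi)
        grads <- nn_backward(params, model$cfg, fw, sx$dlogits)
        if (is.finite(cfg$clip_norm)) {
          gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
          if (gn > cfg$clip_norm)
            grads <- lapply(grads, function(g) g * (cfg$clip_norm / gn))
        }
        upd <- adam_step(params, grads, state, lr)
        params <- upd$params
        state <- upd$state
      }
      train_loss <- tot_loss / length(tr_idx)
      val_loss <- if (!is.null(xs_val)) {
        fwv <- nn_forward(params, model$cfg, xs_val, train = FALSE)
        softmax_xent(fwv$logits, yy[val_idx])$loss
      } else NA_real_
      monitored <- if (is.na(val_loss)) train_loss else val_loss
      hist_epoch <- c(hist_epoch, epoch)
      hist_train <- c(hist_train, train_loss)
      hist_val <- c(hist_val, val_loss)
      if (verbose)
        message(sprintf("epoch %3d  train %.5f  val %s", epoch, train_loss,
                        if (is.na(val_loss)) "-" else sprintf("%.5f", val_loss)))
      if (!is.finite(train_loss))
        stop("training diverged: non-finite loss at epoch ", epoch)
      if (monitored < best_loss - 1e-12) {
        best_loss <- monitored
        best_params <- params
        patience_left <- cfg$early_stopping_patience
      } else {
        patience_left <- patience_left - 1L
        if (patience_left <= 0L) break
      }
    }
    params <- best_params
  })

  model$params <- params
  model$trained <- TRUE
  model$history <- data.frame(epoch = hist_epoch, train_loss = hist_train,
                              val_loss = hist_val)
  model
}

#' Predict tooth classes
#'
#' Returns the argmax class (ties broken toward the lowest class index,
#' which is what `which.max` does) and the softmax probability vector for
#' each input.
#'
#' @param object a `mesh_classifier`.
#' @param newdata a single `feature_image`/matrix or an
#'   `N x timesteps x features` array / list.
#' @param ... unused.
#' @return a list with `labels` (integer codes `0..K-1`), `probabilities`
#'   (N x K matrix, rows summing to 1) and, if the model carries
#'   `class_names`, `class` (character).
#' @export
predict.mesh_classifier <- function(object, newdata, ...) {
  single <- inherits(newdata, "feature_image") ||
    (is.matrix(newdata) && length(dim(newdata)) == 2L)
  X <- as_input_array(if (single) list(newdata) else newdata,
                      object$cfg$input_shape)
  probs <- predict_probs(object, X)
  labels <- max.col(probs, ties.method = "first") - 1L
  out <- list(labels = labels, probabilities = probs)
  if (!is.null(object$class_names))
    out$class <- object$class_names[labels + 1L]
  out
}

# forward pass in chunks to bound memory
predict_probs <- function(model, X, chunk = 256L) {
  N <- dim(X)[1L]
  K <- model$cfg$num_classes
  probs <- matrix(NA_real_, N, K)
  for (start in seq(1L, N, chunk)) {
    idx <- start:min(N, start + chunk - 1L)
    xs <- slice_timesteps(X, idx)
    fw <- nn_forward(model$params, model$cfg, xs, train = FALSE)
    probs[idx, ] <- softmax_rows(fw$logits)
  }
  probs
}

#' Evaluate a classifier on a test set
#'
#' @param model a trained `mesh_classifier`.
#' @param x test inputs (see [train_model()]).
#' @param y integer labels in `0..(num_classes-1)`.
#' @return an `evaluation_report` (see [compute_metrics()]).
#' @export
evaluate_model <- function(model, x, y) {
  X <- as_input_array(x, model$cfg$input_shape)
  if (dim(X)[1L] == 0L || length(y) == 0L) stop("test set is empty")
  y <- as.integer(y)
  pred <- predict(model, X)
  lv <- as.character(seq_len(model$cfg$num_classes) - 1L)
  if (!is.null(model$class_names)) {
    compute_metrics(model$class_names[y + 1L],
                    model$class_names[pred$labels + 1L],
                    labels = model$class_names)
  } else {
    compute_metrics(as.character(y), as.character(pred$labels), labels = lv)
  }
}

#' Train-accuracy convenience used by learning-sanity checks
#' @param model trained model
#' @param x,y training data
#' @return fraction in \[0, 1\]
#' @export
training_accuracy <- function(model, x, y) {
  X <- as_input_array(x, model$cfg$input_shape)
  pred <- predict(model, X)
  mean(pred$labels == as.integer(y))
}

#' Run an architecture / feature-subset ablation grid
#'
#' Trains one model per (variant, feature subset, seed) cell on identical
#' train/test splits of an encoded dataset and reports mean and standard
#' deviation of the test accuracy over seeds. This mirrors the two ablation
#' axes of the study: network type (CNN / vanilla RNN / LSTM / GRU) and
#' feature content (vertices only / centroids only / both).
#'
#' @param dataset a list with elements `meshes` (budget-conforming
#'   [tri_mesh()]s) and `labels` (integer codes `0..K-1`), e.g. from
#'   [encode_dataset_split()] inputs.
#' @param variants character subset of `c("GRU","LSTM","RNN","CNN")`.
#' @param subsets character subset of `c("both","vertices","centers")`.
#' @param seeds integer vector (>= 1 seed).
#' @param num_classes number of label categories.
#' @param split_cfg a [dataset_split_config()] for the shared split.
#' @param train_cfg a [training_config()] template; its seed is replaced by
#'   each ablation seed.
#' @param model_args named list of overrides passed to [model_config()]
#'   (e.g. smaller unit counts for quick experiments).
#' @param out_csv optional path; the table is also written as CSV.
#' @param verbose print progress.
#' @return a data.frame with one row per (variant, subset): mean and sd of
#'   accuracy (percent) over seeds.
#' @export
run_ablation <- function(dataset, variants = c("GRU", "LSTM", "RNN", "CNN"),
                         subsets = c("both", "vertices", "centers"),
                         seeds = 1L, num_classes = 4L,
                         split_cfg = dataset_split_config(seed = 1L),
                         train_cfg = training_config(),
                         model_args = list(), out_csv = NULL,
                         verbose = FALSE) {
  stopifnot(length(seeds) >= 1L)
  meshes <- dataset$meshes
  labels <- as.integer(dataset$labels)
  split <- split_dataset(data.frame(id = seq_along(meshes),
                                    label = as.character(labels)),
                         split_cfg)
  rows <- list()
  for (variant in variants) for (subset in subsets) {
    fdim <- c(both = 12L, vertices = 9L, centers = 3L)[[subset]]
    budget <- n_faces(meshes[[1L]])
    accs <- numeric(length(seeds))
    X <- lapply(meshes, function(m)
      to_feature_image(extract_features(m, subset = subset,
                                        budget = budget))$pixels)
    X <- as_input_array(X, NULL)
    for (si in seq_along(seeds)) {
      cfg <- do.call(model_config, c(
        list(variant = variant, num_classes = num_classes,
             input_shape = c(budget, fdim)),
        model_args))
      model <- build_model(cfg, seed = seeds[si])
      tc <- train_cfg
      tc$seed <- seeds[si]
      model <- train_model(model,
                           X[split$train_ids, , , drop = FALSE],
                           labels[split$train_ids], tc)
      rep <- evaluate_model(model, X[split$test_ids, , , drop = FALSE],
                            labels[split$test_ids])
      accs[si] <- rep$accuracy
      if (verbose)
        message(sprintf("%s / %s / seed %d: %.2f%%", variant, subset,
                        seeds[si], rep$accuracy))
    }
    rows[[length(rows) + 1L]] <-
      data.frame(variant = variant, subset = subset,
                 mean_accuracy = mean(accs),
                 sd_accuracy = if (length(accs) > 1L) stats::sd(accs) else 0,
                 n_seeds = length(seeds))
  }
  tab <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(tab, out_csv, row.names = FALSE)
  tab
}
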