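# Two-branch CCS network: configuration, training with checkpoint selection
# on validation MAE, prediction, ensembling, persistence.

#' Configure the two-branch CCS network
#'
#' The convolutional branch applies six valid 1D convolutions (kernel 6,
#' stride 1) to the `L x 323` spatial encoding; the first five have 150
#' output channels and the last has 50, with a subsampling layer (kernel and
#' stride 2) between the third and fourth convolutions, followed by a flatten.
#' In the full variant a dense branch of two 250-node layers processes the
#' global feature vector and is concatenated with the flatten output; in the
#' reduced variant the six global scalars are merged directly with the
#' flatten output. The merge feeds a 600-node layer and a single linear
#' output node. All hidden activations are ReLU and weights use He
#' (ReLU-oriented) initialization.
#'
#' @param L Spatial encoding length (must be at least 47 so the convolution
#'   stack leaves at least one position).
#' @param global_length Length of the global feature vector (6 for the
#'   reduced variant).
#' @param variant `"full"` or `"reduced"`.
#' @param conv_channels Output channels of the six convolutional layers.
#' @param kernel Convolution kernel size.
#' @param pool_after Convolution layer after which the subsampling layer sits.
#' @param pool_type `"max"` (default) or `"avg"`; the subsampling layer type
#'   is a documented implementation choice.
#' @param dense_branch Node counts of the dense branch (full variant only).
#' @param head Node count of the merged hidden layer.
#' @param input_scaling Divide every input channel by a fixed constant from
#'   [static_input_scales()] before the first layer. The constants derive
#'   from the chemistry table and `L` alone, never from data; they condition
#'   the optimization without touching the encodings.
#' @param seed Optional seed for the initial weights (training re-initializes
#'   from its own seed so runs are reproducible end to end).
#' @return A `ccs_network` object with initialized parameters.
#' @export
ccs_network <- function(L = 96L, global_length = NULL,
                        variant = c("full", "reduced"),
                        conv_channels = c(150L, 150L, 150L, 150L, 150L, 50L),
                        kernel = 6L, pool_after = 3L,
                        pool_type = c("max", "avg"),
                        dense_branch = c(250L, 250L), head = 600L,
                        input_scaling = TRUE, seed = NULL) {
  variant <- match.arg(variant)
  pool_type <- match.arg(pool_type)
  if (is.null(global_length))
    global_length <- if (variant == "reduced") 6L
                     else 6L + 45L * n_layout_windows(subsequence_layout())
  if (variant == "reduced" && global_length != 6L)
    stop("configuration: reduced variant requires global_length = 6")
  shapes <- conv_stack_shapes(L, kernel, length(conv_channels), pool_after)
  if (shapes$positions[length(shapes$positions)] < 1L)
    stop("configuration: L = ", L, " too short for the convolution stack")
  flatten <- shapes$flatten_per_channel * conv_channels[length(conv_channels)]
  merge_length <- flatten +
    if (variant == "full") dense_branch[length(dense_branch)] else global_length
  cfg <- list(L = as.integer(L), in_channels = 323L,
              global_length = as.integer(global_length), variant = variant,
              conv_channels = as.integer(conv_channels),
              kernel = as.integer(kernel), pool_after = as.integer(pool_after),
              pool_type = pool_type, dense_branch = as.integer(dense_branch),
              head = as.integer(head), flatten_length = as.integer(flatten),
              merge_length = as.integer(merge_length))
  if (isTRUE(input_scaling)) {
    sc <- static_input_scales(L, global_length)
    cfg$inv_spatial_scale <- 1 / sc$spatial
    cfg$inv_global_scale <- 1 / sc$global
  }
  if (!is.null(seed)) set.seed(seed)
  structure(list(config = cfg, params = .init_params(cfg)),
            class = "ccs_network")
}

#' Position counts through the convolution stack
#'
#' Shape arithmetic for valid convolutions with the given kernel, stride 1,
#' and one kernel-2/stride-2 subsampling layer: the number of positions after
#' each layer and the flatten length per channel.
#'
#' @param L Input length.
#' @param kernel Convolution kernel size.
#' @param n_conv Number of convolution layers.
#' @param pool_after Index of the convolution layer followed by subsampling.
#' @return List with `positions` (after each of the `n_conv` layers, pooling
#'   applied where it sits) and `flatten_per_channel`.
#' @export
conv_stack_shapes <- function(L, kernel = 6L, n_conv = 6L, pool_after = 3L) {
  pos <- integer(n_conv)
  p <- as.integer(L)
  for (l in seq_len(n_conv)) {
    p <- p - kernel + 1L
    if (l == pool_after) p <- p %/% 2L
    pos[l] <- p
  }
  list(positions = pos, flatten_per_channel = pos[n_conv])
}

#' Training configuration
#'
#' Defaults follow the published training protocol: Adam with learning rate
#' 0.0003, batch size 256, mean absolute error loss, CCS divided by 1000
#' before fitting, validation every 1000 iterations and at every epoch end.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param target_divisor CCS values are divided by this before training and
#'   predictions multiplied by it.
#' @param max_epochs Maximum number of epochs.
#' @param max_iterations Optional hard cap on training iterations.
#' @param validate_every Validation interval in iterations.
#' @param stop_mae Optional early-stopping threshold: training stops once the
#'   validation MAE (in squared angstroms) falls below this value.
#' @param validate_at_epoch_end Also validate at every epoch end (the
#'   published protocol). Worth disabling for very small training sets where
#'   epochs are only a few iterations long.
#' @param seed Random seed covering weight initialization, shuffling and
#'   batch order.
#' @return A `ccs_training_config` list.
#' @export
training_config <- function(learning_rate = 3e-4, batch_size = 256L,
                            target_divisor = 1000, max_epochs = 50L,
                            max_iterations = NULL, validate_every = 1000L,
                            stop_mae = NULL, validate_at_epoch_end = TRUE,
                            seed = 1L) {
  stopifnot(learning_rate > 0, target_divisor > 0, batch_size >= 1L)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 target_divisor = target_divisor,
                 max_epochs = as.integer(max_epochs),
                 max_iterations = if (is.null(max_iterations)) NULL
                                  else as.integer(max_iterations),
                 validate_every = as.integer(validate_every),
                 stop_mae = stop_mae,
                 validate_at_epoch_end = isTRUE(validate_at_epoch_end),
                 seed = as.integer(seed)),
            class = "ccs_training_config")
}

.forward_in_chunks <- function(params, cfg, enc, chunk = 128L) {
  n <- dim(enc$spatial)[1L]
  pred <- numeric(n)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    pred[lo:hi] <- .net_forward(params, cfg,
                                enc$spatial[lo:hi, , , drop = FALSE],
                                enc$global[lo:hi, , drop = FALSE])$pred
  }
  pred
}

#' Train the CCS network
#'
#' Trains with Adam on mean absolute error, targets divided by
#' `target_divisor`, validating every `validate_every` iterations and at
#' every epoch end. The returned model carries the parameters of the
#' checkpoint with the lowest recorded validation MAE and the full history.
#' Training is fully reproducible given the configuration seed, which
#' re-initializes the weights and drives shuffling and batch order.
#'
#' @param network A [ccs_network()].
#' @param train,validation `ccs_encoding` objects (see [encode_dataset()])
#'   with non-`NULL` `ccs`; both must be produced with the same encoding
#'   configuration.
#' @param config A [training_config()].
#' @param verbose Print validation progress?
#' @return A `ccs_model`: list with `params` (best checkpoint), `config`,
#'   `encoding_config`, `history` (iteration, train loss in scaled units,
#'   validation MAE in squared angstroms), `best_iteration`, and
#'   `training_config`.
#' @export
train_ccs_model <- function(network, train, validation,
                            config = training_config(), verbose = FALSE) {
  stopifnot(inherits(network, "ccs_network"),
            inherits(train, "ccs_encoding"),
            inherits(validation, "ccs_encoding"))
  if (!identical(train$config, validation$config))
    stop("incompatible-encoding: train and validation encodings differ")
  if (is.null(train$ccs) || is.null(validation$ccs))
    stop("train and validation sets need reference CCS values")
  n <- dim(train$spatial)[1L]
  if (n < 1L) stop("empty training set")
  cfg <- network$config
  if (cfg$global_length != ncol(train$global))
    stop("configuration: encoding global length ", ncol(train$global),
         " does not match network global length ", cfg$global_length)
  set.seed(config$seed)
  params <- .init_params(cfg)
  state <- list(t = 0L,
                m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  y <- train$ccs / config$target_divisor
  hist_iter <- integer(0); hist_loss <- numeric(0); hist_val <- numeric(0)
  best_val <- Inf; best_params <- params; best_iter <- 0L
  iter <- 0L
  stop_now <- FALSE
  validate <- function(last_loss) {
    pred <- .forward_in_chunks(params, cfg, validation) * config$target_divisor
    val_mae <- mean(abs(pred - validation$ccs))
    hist_iter <<- c(hist_iter, iter)
    hist_loss <<- c(hist_loss, last_loss)
    hist_val <<- c(hist_val, val_mae)
    if (val_mae < best_val) {
      best_val <<- val_mae; best_params <<- params; best_iter <<- iter
    }
    if (verbose)
      message(sprintf("iter %d: train loss %.5f, validation MAE %.2f A^2",
                      iter, last_loss, val_mae))
    if (!is.null(config$stop_mae) && val_mae < config$stop_mae)
      stop_now <<- TRUE
    invisible(val_mae)
  }
  last_loss <- NA_real_
  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample.int(n)
    for (lo in seq(1L, n, by = config$batch_size)) {
      idx <- perm[lo:min(lo + config$batch_size - 1L, n)]
      X <- train$spatial[idx, , , drop = FALSE]
      G <- train$global[idx, , drop = FALSE]
      fw <- .net_forward(params, cfg, X, G, training = TRUE)
      err <- fw$pred - y[idx]
      last_loss <- mean(abs(err))
      if (!is.finite(last_loss)) stop("training-diverged: non-finite loss")
      dpred <- sign(err) / length(err)
      grads <- .net_backward(params, cfg, fw$caches, dpred)
      upd <- .adam_step(params, grads, state, config$learning_rate)
      params <- upd$params; state <- upd$state
      iter <- iter + 1L
      if (iter %% config$validate_every == 0L) validate(last_loss)
      if (stop_now) break
      if (!is.null(config$max_iterations) && iter >= config$max_iterations) break
    }
    if (config$validate_at_epoch_end && !stop_now &&
        (is.null(config$max_iterations) || iter < config$max_iterations) &&
        iter %% config$validate_every != 0L)
      validate(last_loss)   # epoch-end validation
    if (stop_now) break
    if (!is.null(config$max_iterations) && iter >= config$max_iterations) {
      if (iter %% config$validate_every != 0L) validate(last_loss)
      break
    }
  }
  if (length(hist_iter) == 0L) validate(last_loss)
  structure(list(params = best_params, config = cfg,
                 encoding_config = train$config,
                 history = data.frame(iteration = hist_iter,
                                      train_loss = hist_loss,
                                      val_mae = hist_val),
                 best_iteration = best_iter,
                 best_val_mae = best_val,
                 training_config = config),
            class = "ccs_model")
}

#' @export
print.ccs_model <- function(x, ...) {
  cat(sprintf("<ccs_model> %s variant, best checkpoint at iteration %d (validation MAE %.2f A^2)\n",
              x$config$variant, x$best_iteration, x$best_val_mae))
  invisible(x)
}

#' Predict CCS values
#'
#' Runs the network on new peptides (or a ready-made encoding) and rescales
#' the output to squared angstroms. The encoding configuration must match the
#' one the model was trained with.
#'
#' @param object A `ccs_model`.
#' @param newdata A `ccs_encoding`, or a list of `peptide` objects to encode
#'   with the model's stored configuration.
#' @param ... Unused.
#' @return Numeric vector of predicted CCS values in squared angstroms, one
#'   per peptide, in input order.
#' @export
predict.ccs_model <- function(object, newdata, ...) {
  enc <- .as_encoding(newdata, object$encoding_config)
  if (!identical(enc$config, object$encoding_config))
    stop("incompatible-encoding: encoding configuration does not match the model")
  .forward_in_chunks(object$params, object$config, enc) *
    object$training_config$target_divisor
}

.as_encoding <- function(newdata, config) {
  if (inherits(newdata, "ccs_encoding")) return(newdata)
  if (inherits(newdata, "peptide")) newdata <- list(newdata)
  if (is.list(newdata) && all(vapply(newdata, inherits, logical(1), "peptide")))
    return(encode_dataset(newdata, L = config$L, layout = config$layout,
                          reduced = config$reduced))
  stop("newdata must be a ccs_encoding or a list of peptide objects")
}

#' Ensemble of independently trained CCS models
#'
#' Averaging the predictions of several networks of the same architecture,
#' trained independently (different seeds), improves accuracy because each
#' member's errors are partly random.
#'
#' @param models List of `ccs_model` objects with identical encoding
#'   configurations.
#' @return A `ccs_ensemble` object.
#' @export
ccs_ensemble <- function(models) {
  if (length(models) < 1L) stop("ensemble needs at least one model")
  stopifnot(all(vapply(models, inherits, logical(1), "ccs_model")))
  enc0 <- models[[1L]]$encoding_config
  for (m in models)
    if (!identical(m$encoding_config, enc0))
      stop("incompatible-encoding: ensemble members use different encodings")
  structure(list(models = models), class = "ccs_ensemble")
}

#' @rdname ccs_ensemble
#' @param object A `ccs_ensemble`.
#' @param newdata Peptides or a `ccs_encoding`.
#' @param ... Unused.
#' @export
predict.ccs_ensemble <- function(object, newdata, ...) {
  enc <- .as_encoding(newdata, object$models[[1L]]$encoding_config)
  preds <- vapply(object$models, function(m) predict(m, enc),
                  numeric(dim(enc$spatial)[1L]))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1L)
  rowMeans(preds)
}

#' Save / load a trained model
#'
#' Persists the parameters together with the network and encoding
#' configurations so a reloaded model predicts bit-identically.
#'
#' @param model A `ccs_model` or `ccs_ensemble`.
#' @param path File path.
#' @export
save_ccs_model <- function(model, path) {
  stopifnot(inherits(model, "ccs_model") || inherits(model, "ccs_ensemble"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_ccs_model
#' @export
load_ccs_model <- function(path) {
  model <- readRDS(path)
  if (!(inherits(model, "ccs_model") || inherits(model, "ccs_ensemble")))
    stop("file does not contain a pepccs model")
  model
}

#' Charge-stratified mean baseline
#'
#' Predicts, for each test record, the mean training CCS of its charge state
#' (falling back to the overall training mean for unseen charges). Used as
#' the reference point when judging whether the network has learned anything
#' beyond the charge-state offsets.
#'
#' @param train_ccs,train_charge Training CCS values and charge states.
#' @param test_charge Charge states to predict for.
#' @return Numeric vector of baseline predictions.
#' @export
charge_mean_baseline <- function(train_ccs, train_charge, test_charge) {
  means <- tapply(train_ccs, train_charge, mean)
  out <- means[as.character(test_charge)]
  out[is.na(out)] <- mean(train_ccs)
  as.numeric(out)
}
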