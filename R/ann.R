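# A small fully connected network trained with Adam, implemented from
# primitive matrix operations so runs are self-contained and seedable.

#' Network architecture
#'
#' The feed-forward architecture used for both classification and
#' regression: 35 input units, three hidden layers of 20, 10 and 5 rectifier
#' units, and an output head matching the task (`sigmoid` single unit for
#' binary classification, `softmax` for three classes, `linear` single unit
#' for regression).
#'
#' @param input_units Number of input features (default 35).
#' @param hidden Hidden layer sizes (default `c(20, 10, 5)`).
#' @param output Output head: `"sigmoid"`, `"softmax"` or `"linear"`.
#' @param n_classes Number of classes for the softmax head (default 3).
#' @return An object of class `ann_architecture`.
#' @export
ann_architecture <- function(input_units = 35, hidden = c(20, 10, 5),
                             output = c("sigmoid", "softmax", "linear"),
                             n_classes = 3) {
  output <- match.arg(output)
  if (any(hidden <= 0) || any(diff(c(input_units, hidden)) >= 0)) {
    abort("hidden layer sizes must be positive and decreasing from the input.")
  }
  out_units <- switch(output, sigmoid = 1L, linear = 1L,
                      softmax = as.integer(n_classes))
  structure(list(input_units = as.integer(input_units),
                 hidden = as.integer(hidden),
                 output = output, out_units = out_units),
            class = "ann_architecture")
}

#' Training configuration
#'
#' Loss follows the head (cross-entropy for classification heads, mean
#' squared error for the linear head); optimization is Adam. The defaults
#' (200 epochs, learning rate 1e-3, batch size 32, no early stopping) are
#' fixed package choices.
#'
#' @param epochs Number of passes over the training data.
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param seed Integer seed controlling initialization and shuffling.
#' @return An object of class `training_config`.
#' @export
training_config <- function(epochs = 200, learning_rate = 1e-3,
                            batch_size = 32, seed = 1) {
  check_count(epochs, "epochs")
  check_number(learning_rate, "learning_rate", lower = 1e-12)
  check_count(batch_size, "batch_size")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "training_config")
}

mlp_init <- function(arch) {
  sizes <- c(arch$input_units, arch$hidden, arch$out_units)
  layers <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    fan_in <- sizes[l]; fan_out <- sizes[l + 1L]
    lim <- sqrt(6 / (fan_in + fan_out))
    layers[[l]] <- list(
      W = matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out),
      b = rep(0, fan_out)
    )
  }
  layers
}

mlp_forward <- function(layers, X, output) {
  acts <- list(X)
  L <- length(layers)
  for (l in seq_len(L)) {
    Z <- acts[[l]] %*% layers[[l]]$W
    Z <- sweep(Z, 2, layers[[l]]$b, "+")
    acts[[l + 1L]] <- if (l < L) pmax(Z, 0) else Z
  }
  out <- acts[[L + 1L]]
  out <- switch(output,
    sigmoid = 1 / (1 + exp(-out)),
    softmax = {
      m <- apply(out, 1, max)
      e <- exp(out - m)
      e / rowSums(e)
    },
    linear = out
  )
  list(acts = acts, out = out)
}

# Gradient of the loss wrt pre-activation of the output layer. For all three
# head/loss pairings the (scaled) gradient is (prediction - target) / m.
mlp_backward <- function(layers, fw, Y, output) {
  L <- length(layers)
  m <- nrow(Y)
  delta <- (fw$out - Y) / m
  if (output == "linear") delta <- 2 * delta
  grads <- vector("list", L)
  for (l in L:1) {
    A_prev <- fw$acts[[l]]
    grads[[l]] <- list(W = t(A_prev) %*% delta, b = colSums(delta))
    if (l > 1) {
      delta <- (delta %*% t(layers[[l]]$W)) * (fw$acts[[l]] > 0)
    }
  }
  grads
}

mlp_train <- function(X, Y, arch, cfg) {
  with_seed(cfg$seed, {
    layers <- mlp_init(arch)
    mom <- map(layers, function(ly) list(
      mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0))
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0
    n <- nrow(X)
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        fw <- mlp_forward(layers, X[idx, , drop = FALSE], arch$output)
        grads <- mlp_backward(layers, fw, Y[idx, , drop = FALSE], arch$output)
        step <- step + 1
        corr1 <- 1 - beta1^step; corr2 <- 1 - beta2^step
        for (l in seq_along(layers)) {
          g <- grads[[l]]
          mom[[l]]$mW <- beta1 * mom[[l]]$mW + (1 - beta1) * g$W
          mom[[l]]$vW <- beta2 * mom[[l]]$vW + (1 - beta2) * g$W^2
          mom[[l]]$mb <- beta1 * mom[[l]]$mb + (1 - beta1) * g$b
          mom[[l]]$vb <- beta2 * mom[[l]]$vb + (1 - beta2) * g$b^2
          layers[[l]]$W <- layers[[l]]$W - cfg$learning_rate *
            (mom[[l]]$mW / corr1) / (sqrt(mom[[l]]$vW / corr2) + eps)
          layers[[l]]$b <- layers[[l]]$b - cfg$learning_rate *
            (mom[[l]]$mb / corr1) / (sqrt(mom[[l]]$vb / corr2) + eps)
        }
      }
    }
    layers
  })
}

#' Save an ANN model checkpoint as portable JSON
#'
#' Stores weights, architecture, standardization constants, feature keys and
#' class levels; [read_model()] restores an equivalent predictor.
#'
#' @param model An `eeg_model` of kind `"ann"` from [train_model()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "eeg_model"))
  if (model$kind != "ann") abort("JSON checkpoints are supported for the ANN only.")
  payload <- list(
    kind = "ann",
    arch = list(input_units = model$arch$input_units, hidden = model$arch$hidden,
                output = model$arch$output, out_units = model$arch$out_units),
    layers = map(model$fit, function(ly) list(W = ly$W, b = ly$b)),
    center = model$center, scale = model$scale,
    feature_keys = model$feature_keys, levels = model$levels,
    target = model$target
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Restore an ANN model from a JSON checkpoint
#'
#' @param path JSON path written by [write_model()].
#' @return An `eeg_model` object.
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  arch <- structure(list(input_units = p$arch$input_units,
                         hidden = p$arch$hidden, output = p$arch$output,
                         out_units = p$arch$out_units),
                    class = "ann_architecture")
  layers <- map(seq_along(p$layers[["W"]] %||% p$layers), function(i) {
    ly <- if (is.null(p$layers[["W"]])) p$layers[[i]] else
      list(W = p$layers[["W"]][[i]], b = p$layers[["b"]][[i]])
    list(W = as.matrix(ly$W), b = as.numeric(ly$b))
  })
  structure(list(kind = "ann", arch = arch, fit = layers,
                 center = as.numeric(p$center), scale = as.numeric(p$scale),
                 feature_keys = p$feature_keys, levels = p$levels,
                 target = p$target %||% "label"),
            class = "eeg_model")
}
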