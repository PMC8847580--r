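#' Configuration of the convolutional identification model
#'
#' The identification model is a stack of convolution blocks (3x3 kernels,
#' stride (1,1), ReLU, 2x2 max pooling) followed by an identification head of
#' exactly two fully connected layers: a ReLU hidden layer and a SoftMax
#' output layer over the `n_classes` training subjects. After training, the
#' head is discarded and the flattened output of the last conv/pool block
#' becomes the EEG fingerprint (see [split_fingerprint()]).
#'
#' Defaults mirror the tuned training recipe: RMSprop, learning rate 1e-4,
#' dropout 0.25, 30 epochs, batch size 64. The default feature stack is
#' three blocks of 16/32/64 filters with a 128-unit hidden layer (8
#' weight-bearing layers in total).
#'
#' @param n_classes number of training subjects (>= 2).
#' @param conv_filters integer vector, filters per conv block.
#' @param kernel length-2 kernel shape (odd sizes; "same" padding).
#' @param pool pooling factor (p x p, stride p).
#' @param dense_hidden hidden width of the identification head.
#' @param dropout_rate dropout on the flattened features, in `[0, 1)`.
#' @param learning_rate,epochs,batch_size,optimizer training hyperparameters
#'   (only `"rmsprop"` is implemented).
#' @param seed master seed; fans out to weight init, shuffling and dropout.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(n_classes,
                              conv_filters = c(16L, 32L, 64L),
                              kernel = c(3L, 3L),
                              pool = 2L,
                              dense_hidden = 128L,
                              dropout_rate = 0.25,
                              learning_rate = 1e-4,
                              epochs = 30L,
                              batch_size = 64L,
                              optimizer = "rmsprop",
                              seed = 1L) {
  n_classes <- as.integer(n_classes)
  if (is.na(n_classes) || n_classes < 2L) {
    stop("n_classes must be >= 2", call. = FALSE)
  }
  conv_filters <- as.integer(conv_filters)
  if (length(conv_filters) < 1L || any(conv_filters < 1L)) {
    stop("conv_filters must be a vector of positive filter counts", call. = FALSE)
  }
  kernel <- as.integer(kernel)
  if (length(kernel) != 2L || any(kernel < 1L) || any(kernel %% 2L == 0L)) {
    stop("kernel must be two odd positive integers", call. = FALSE)
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must be in [0, 1)", call. = FALSE)
  }
  optimizer <- match.arg(optimizer, "rmsprop")
  structure(list(n_classes = n_classes, conv_filters = conv_filters,
                 kernel = kernel, pool = as.integer(pool),
                 dense_hidden = as.integer(dense_hidden),
                 dropout_rate = dropout_rate,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), optimizer = optimizer,
                 stride = c(1L, 1L), seed = as.integer(seed)),
            class = "classifier_config")
}

# run code under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Flattened feature (fingerprint) length implied by a configuration
#'
#' Propagates the `eta x T` plane through the conv/pool stack ("same"
#' padding, floor-divided pooling) and returns the length `m` of the
#' flattened final feature map.
#'
#' @param config a [classifier_config()].
#' @param input_shape integer `c(eta, T, n_channels)`.
#' @return integer feature length `m`.
#' @export
fingerprint_length <- function(config, input_shape) {
  h <- as.integer(input_shape[1]); w <- as.integer(input_shape[2])
  # "same" padding keeps deeper planes computable for any kernel, but a
  # kernel exceeding the configured input plane is a configuration error
  if (config$kernel[1] > h || config$kernel[2] > w) {
    stop("configuration error: kernel larger than input plane", call. = FALSE)
  }
  for (f in config$conv_filters) {
    h <- h %/% config$pool
    w <- w %/% config$pool
    if (h < 1L || w < 1L) {
      stop("configuration error: pooling collapses the feature plane",
           call. = FALSE)
    }
  }
  h * w * config$conv_filters[length(config$conv_filters)]
}

#' Build an (untrained) convolutional identification model
#'
#' Initializes weights (He-normal, driven by `config$seed`) for the conv
#' stack and the two-layer identification head.
#'
#' @param config a [classifier_config()].
#' @param input_shape integer `c(eta, T, n_channels)`.
#' @return An object of class `cnn_model`.
#' @export
build_classifier <- function(config, input_shape) {
  stopifnot(inherits(config, "classifier_config"))
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 3L || any(input_shape < 1L)) {
    stop("input_shape must be c(eta, T, n_channels)", call. = FALSE)
  }
  m <- fingerprint_length(config, input_shape)
  kh <- config$kernel[1]; kw <- config$kernel[2]

  weights <- with_local_seed(config$seed, {
    w <- list()
    cin <- input_shape[3]
    for (f in config$conv_filters) {
      k <- cin * kh * kw
      w[[length(w) + 1L]] <- matrix(stats::rnorm(f * k, sd = sqrt(2 / k)),
                                    nrow = f, ncol = k)
      w[[length(w) + 1L]] <- numeric(f)
      cin <- f
    }
    w[[length(w) + 1L]] <- matrix(
      stats::rnorm(config$dense_hidden * m, sd = sqrt(2 / m)),
      nrow = config$dense_hidden, ncol = m)
    w[[length(w) + 1L]] <- numeric(config$dense_hidden)
    w[[length(w) + 1L]] <- matrix(
      stats::rnorm(config$n_classes * config$dense_hidden,
                   sd = sqrt(2 / config$dense_hidden)),
      nrow = config$n_classes, ncol = config$dense_hidden)
    w[[length(w) + 1L]] <- numeric(config$n_classes)
    w
  })

  structure(list(config = config, input_shape = input_shape,
                 fingerprint_len = m, weights = weights,
                 trained = FALSE, history = NULL),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf(
    "<cnn_model> input %s | conv %s | dense %d -> %d | m=%d | %s\n",
    paste(x$input_shape, collapse = "x"),
    paste(x$config$conv_filters, collapse = "/"),
    x$config$dense_hidden, x$config$n_classes, x$fingerprint_len,
    if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# coerce a list of model inputs (or a 4D array) to a 4D batch array and
# validate its shape against the model
as_batch <- function(x, input_shape) {
  if (is.list(x)) x <- stack_model_inputs(x)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 4L ||
      !identical(as.integer(dim(x)[1:3]), as.integer(input_shape))) {
    stop(sprintf("shape error: batch is %s, model expects %s x B",
                 paste(dim(x), collapse = "x"),
                 paste(input_shape, collapse = "x")), call. = FALSE)
  }
  x
}

#' Class probabilities for a batch of model inputs
#'
#' @param object a `cnn_model`.
#' @param inputs list of model inputs or a 4-D batch array.
#' @param ... unused.
#' @return matrix `n_classes x B` of SoftMax probabilities.
#' @export
predict.cnn_model <- function(object, inputs, ...) {
  x <- as_batch(inputs, object$input_shape)
  cfg <- object$config
  cpp_cnn_forward(object$weights, x, as.integer(dim(x)),
                  length(cfg$conv_filters), cfg$kernel[1], cfg$kernel[2],
                  cfg$pool, FALSE)
}

#' Train the identification model end-to-end
#'
#' Mini-batch RMSprop with per-epoch reshuffling and inverted dropout on the
#' flattened features. All randomness (shuffling, dropout masks) is derived
#' from `config$seed`, so identical seeds give identical runs.
#'
#' @param model an untrained (or previously trained) `cnn_model`.
#' @param inputs list of model inputs or a 4-D batch array.
#' @param labels integer class labels in `0 .. n_classes - 1`, one per input.
#' @param epochs optional override of `config$epochs`.
#' @param verbose print per-epoch loss/accuracy.
#' @return the trained `cnn_model` with a `history` data frame.
#' @export
train_classifier <- function(model, inputs, labels, epochs = NULL,
                             verbose = FALSE) {
  stopifnot(inherits(model, "cnn_model"))
  cfg <- model$config
  x <- as_batch(inputs, model$input_shape)
  n <- dim(x)[4]
  labels <- as.integer(labels)
  if (length(labels) != n) {
    stop("labels length must equal the number of inputs", call. = FALSE)
  }
  if (any(is.na(labels)) || any(labels < 0L) || any(labels >= cfg$n_classes)) {
    stop(sprintf("training error: labels must lie in [0, %d)", cfg$n_classes),
         call. = FALSE)
  }
  if (length(unique(labels)) < cfg$n_classes) {
    stop("training error: at least one class has zero samples", call. = FALSE)
  }
  epochs <- if (is.null(epochs)) cfg$epochs else as.integer(epochs)

  nb <- length(cfg$conv_filters)
  lr <- cfg$learning_rate
  rho <- 0.9; eps <- 1e-7
  cache <- lapply(model$weights, function(w) w * 0)
  weights <- model$weights

  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  with_local_seed(cfg$seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      ep_loss <- 0; ep_correct <- 0L
      for (s in starts) {
        bi <- ord[s:min(s + cfg$batch_size - 1L, n)]
        xb <- x[, , , bi, drop = FALSE]
        step <- cpp_cnn_train_step(
          weights, xb, as.integer(dim(xb)), labels[bi], nb,
          cfg$kernel[1], cfg$kernel[2], cfg$pool, cfg$dropout_rate,
          sample.int(.Machine$integer.max, 1L))
        for (j in seq_along(weights)) {
          g <- step$grads[[j]]
          cache[[j]] <- rho * cache[[j]] + (1 - rho) * g^2
          weights[[j]] <- weights[[j]] - lr * g / (sqrt(cache[[j]]) + eps)
        }
        ep_loss <- ep_loss + step$loss * length(bi)
        ep_correct <- ep_correct + step$correct
      }
      history[ep, ] <- list(ep, ep_loss / n, ep_correct / n)
      if (verbose) {
        message(sprintf("epoch %d/%d  loss %.4f  acc %.3f",
                        ep, epochs, ep_loss / n, ep_correct / n))
      }
    }
  })

  model$weights <- weights
  model$trained <- TRUE
  model$history <- history
  model
}

#' Extract the fingerprinting function from a trained model
#'
#' Removes the two fully connected identification layers and keeps only the
#' convolutional feature stack: the returned object maps a model input to the
#' flattened output of the last conv/pool block — the EEG fingerprint
#' ("EEG hash"): a fixed-length, non-invertible feature vector. The
#' identification head is not retained in (or reachable through) the
#' returned object.
#'
#' @param model a `cnn_model` (trained; extracting from an untrained model is
#'   permitted but flagged with a message, since such fingerprints are valid
#'   vectors yet useless for authentication).
#' @return An object of class `eeg_fingerprinter`.
#' @export
split_fingerprint <- function(model) {
  stopifnot(inherits(model, "cnn_model"))
  if (!isTRUE(model$trained)) {
    message("note: extracting fingerprinter from an untrained model")
  }
  nb <- length(model$config$conv_filters)
  conv_w <- model$weights[seq_len(2L * nb)]
  core <- list(conv_weights = conv_w,
               conv_filters = model$config$conv_filters,
               kernel = model$config$kernel, pool = model$config$pool,
               input_shape = model$input_shape)
  structure(c(core,
              list(fingerprint_len = model$fingerprint_len,
                   model_version = cpp_fnv1a(serialize(core, NULL)))),
            class = "eeg_fingerprinter")
}

#' @export
print.eeg_fingerprinter <- function(x, ...) {
  cat(sprintf("<eeg_fingerprinter> input %s -> m=%d  (model_version %s)\n",
              paste(x$input_shape, collapse = "x"), x$fingerprint_len,
              x$model_version))
  invisible(x)
}

#' Fingerprints of a batch of model inputs
#'
#' @param f an [split_fingerprint()] result.
#' @param inputs list of model inputs or 4-D batch array.
#' @return matrix `m x B`; entries are non-negative (post-ReLU/pool).
#' @export
fingerprint_inputs <- function(f, inputs) {
  stopifnot(inherits(f, "eeg_fingerprinter"))
  x <- as_batch(inputs, f$input_shape)
  cpp_cnn_forward(f$conv_weights, x, as.integer(dim(x)),
                  length(f$conv_filters), f$kernel[1], f$kernel[2], f$pool,
                  TRUE)
}

#' Fingerprint a whole recording
#'
#' Runs the full chain — normalize, orthogonalize, augment, fingerprint —
#' and aggregates the per-window fingerprints into the single stored vector
#' `s = f(a)`. Default aggregation is the element-wise mean.
#'
#' @param f an `eeg_fingerprinter`.
#' @param rec an [eeg_recording()].
#' @param channels ordered channel set C used at training time.
#' @param params a [window_params()].
#' @param aggregation `"mean"` (element-wise mean vector) or `"none"`
#'   (matrix of per-window fingerprints, for score-level fusion).
#' @param orthogonalize,max_inputs passed to [build_inputs()].
#' @return numeric vector of length `m` with attribute `model_version`
#'   (or an `m x k` matrix for `aggregation = "none"`).
#' @export
fingerprint_sample <- function(f, rec, channels, params = window_params(),
                               aggregation = c("mean", "none"),
                               orthogonalize = TRUE, max_inputs = NULL) {
  aggregation <- match.arg(aggregation)
  inputs <- build_inputs(rec, channels, params, orthogonalize = orthogonalize,
                         max_inputs = max_inputs)
  fp <- fingerprint_inputs(f, inputs)
  if (aggregation == "none") {
    attr(fp, "model_version") <- f$model_version
    return(fp)
  }
  out <- rowMeans(fp)
  attr(out, "model_version") <- f$model_version
  class(out) <- "fingerprint_vector"
  out
}
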