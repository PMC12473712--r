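#' Classifier architectures and training loop
#'
#' Three small 1-D convolutional architectures for fixed-length
#' multichannel gesture windows:
#'
#' * `vanilla_cnn` - three convolution blocks (64/128/128 filters, kernels
#'   7/5/3, each ReLU + max-pool 2), global average pooling, softmax.
#' * `attention_cnn` - the same trunk with the global pool replaced by
#'   additive temporal attention pooling (scores from a 1-unit projection
#'   over time, softmax-weighted sum).
#' * `multi_input_cnn` - two branches with identical trunks (32/64/64
#'   filters, kernels 7/5/3, each ReLU + max-pool 2, global average pool),
#'   concatenated and passed through a dense-128 ReLU head to softmax.
#'   Equal kernel counts per branch give the two modalities equal weight in
#'   feature extraction.
#'
#' Training uses Adam (default learning rate 0.01), categorical
#' cross-entropy, and a fixed epoch budget with no early stopping.
#'
#' @name models
NULL

#' Model specification
#'
#' @param family one of `"vanilla_cnn"`, `"attention_cnn"`,
#'   `"multi_input_cnn"`.
#' @param input_shape for the single-input families, `c(length, channels)`;
#'   for `multi_input_cnn`, a list of exactly two `c(length, channels)`
#'   branch shapes.
#' @param n_classes number of identities (>= 2).
#' @param kernels_per_branch filter counts of the three per-branch
#'   convolution blocks (multi-input only); both branches always share them.
#' @param seed integer seed for weight initialization.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(family = c("vanilla_cnn", "attention_cnn",
                                  "multi_input_cnn"),
                       input_shape, n_classes,
                       kernels_per_branch = c(32, 64, 64), seed = 1) {
  family <- match.arg(family)
  stopifnot(n_classes >= 2)
  if (family == "multi_input_cnn") {
    if (!is.list(input_shape) || length(input_shape) != 2L) {
      stop("multi_input_cnn requires exactly 2 branch input shapes")
    }
  } else {
    stopifnot(is.numeric(input_shape), length(input_shape) == 2L)
  }
  structure(list(family = family, input_shape = input_shape,
                 n_classes = n_classes,
                 kernels_per_branch = kernels_per_branch, seed = seed),
            class = "model_spec")
}

conv_trunk <- function(in_channels, filters, kernels = c(7L, 5L, 3L)) {
  layers <- list()
  ch <- in_channels
  for (i in seq_along(filters)) {
    layers <- c(layers, list(layer_conv(filters[i], kernels[i], ch),
                             layer_relu(), layer_pool()))
    ch <- filters[i]
  }
  layers
}

trunk_out_length <- function(len, kernels = c(7L, 5L, 3L)) {
  for (k in kernels) len <- (len - k + 1L) %/% 2L
  len
}

#' Build an untrained classifier
#'
#' Weights are Glorot-uniform initialized from `spec$seed`, so two builds
#' of the same spec are identical.
#'
#' @param spec a [model_spec()].
#' @return object of class `cnn_model`.
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  with_seed(derive_seed(spec$seed, 401L), {
    model <- switch(spec$family,
      vanilla_cnn = {
        layers <- c(conv_trunk(spec$input_shape[2L], c(64L, 128L, 128L)),
                    list(layer_gap(),
                         layer_dense(spec$n_classes, 128L)))
        list(layers = layers)
      },
      attention_cnn = {
        layers <- c(conv_trunk(spec$input_shape[2L], c(64L, 128L, 128L)),
                    list(layer_attn(128L),
                         layer_dense(spec$n_classes, 128L)))
        list(layers = layers)
      },
      multi_input_cnn = {
        f <- spec$kernels_per_branch
        branches <- lapply(spec$input_shape, function(sh) {
          c(conv_trunk(sh[2L], f), list(layer_gap()))
        })
        head <- list(layer_dense(128L, 2L * f[length(f)]),
                     layer_relu(),
                     layer_dense(spec$n_classes, 128L))
        list(branches = branches, head = head)
      }
    )
    structure(c(model, list(spec = spec)), class = "cnn_model")
  })
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> %s, %d classes, %d parameters\n",
              x$spec$family, x$spec$n_classes, n_params(x)))
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param model a `cnn_model` or `trained_cnn`.
#' @param branch for multi-input models, restrict the count to one branch
#'   (1 or 2); `NULL` counts everything.
#' @return integer parameter count.
#' @export
n_params <- function(model, branch = NULL) {
  if (inherits(model, "trained_cnn")) model <- model$model
  if (!is.null(model$layers)) return(n_params_layers(model$layers))
  if (!is.null(branch)) return(n_params_layers(model$branches[[branch]]))
  n_params_layers(model$branches[[1L]]) +
    n_params_layers(model$branches[[2L]]) + n_params_layers(model$head)
}

model_forward <- function(model, x) {
  if (!is.null(model$layers)) {
    r <- forward_layers(model$layers, x)
    list(logits = r$out, caches = list(main = r$caches))
  } else {
    stopifnot(is.list(x), length(x) == 2L)
    r1 <- forward_layers(model$branches[[1L]], x[[1L]])
    r2 <- forward_layers(model$branches[[2L]], x[[2L]])
    rh <- forward_layers(model$head, cbind(r1$out, r2$out))
    list(logits = rh$out,
         caches = list(b1 = r1$caches, b2 = r2$caches, head = rh$caches,
                       split = ncol(r1$out)))
  }
}

model_backward <- function(model, caches, dlogits) {
  if (!is.null(model$layers)) {
    r <- backward_layers(model$layers, caches$main, dlogits)
    list(main = r$grads)
  } else {
    rh <- backward_layers(model$head, caches$head, dlogits)
    s <- caches$split
    r1 <- backward_layers(model$branches[[1L]], caches$b1,
                          rh$dX[, seq_len(s), drop = FALSE])
    r2 <- backward_layers(model$branches[[2L]], caches$b2,
                          rh$dX[, -seq_len(s), drop = FALSE])
    list(b1 = r1$grads, b2 = r2$grads, head = rh$grads)
  }
}

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with learning rate 0.01,
#' 300 epochs, categorical cross-entropy, and 20 repetitions per
#' experimental cell (repetitions are consumed by
#' [run_experiment_grid()], not by a single [train()] call).
#'
#' @param learning_rate Adam step size.
#' @param epochs fixed epoch budget (no early stopping).
#' @param batch_size minibatch size.
#' @param repetitions number of independently seeded training repetitions
#'   per experiment cell.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, epochs = 300,
                         batch_size = 32, repetitions = 20) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1,
            repetitions >= 1)
  structure(list(learning_rate = learning_rate, epochs = epochs,
                 batch_size = batch_size, repetitions = repetitions),
            class = "train_config")
}

feature_arrays <- function(features) {
  if (inherits(features, "feature_set")) {
    x <- if (!is.null(features$x)) features$x else unname(features$branches)
    list(x = x, labels = features$labels)
  } else {
    list(x = features, labels = NULL)
  }
}

slice_x <- function(x, idx) {
  if (is.list(x)) lapply(x, function(a) a[idx, , , drop = FALSE])
  else x[idx, , , drop = FALSE]
}

#' Train a classifier
#'
#' Runs the full epoch budget of minibatch Adam on cross-entropy.  All
#' randomness (epoch shuffling) derives from `seed`; with a fixed seed the
#' run is deterministic and invariant to the initial row order of the
#' training set.
#'
#' @param model an untrained `cnn_model` from [build_model()].
#' @param features a `feature_set` (training rows only) or a feature array
#'   `(n, length, channels)` / list of two branch arrays.
#' @param labels factor of identities (taken from `features` when it is a
#'   `feature_set`).
#' @param cfg a [train_config()].
#' @param seed integer seed for minibatch shuffling.
#' @return object of class `trained_cnn`: the fitted model, the per-epoch
#'   loss `history`, the class `levels`, and provenance (`cfg`, `seed`).
#' @export
train <- function(model, features, labels = NULL, cfg = train_config(),
                  seed = 1) {
  stopifnot(inherits(model, "cnn_model"), inherits(cfg, "train_config"))
  fa <- feature_arrays(features)
  x <- fa$x
  if (is.null(labels)) labels <- fa$labels
  if (is.null(labels)) stop("labels are required")
  labels <- droplevels(factor(labels))
  n <- if (is.list(x)) dim(x[[1L]])[1L] else dim(x)[1L]
  if (length(labels) != n) stop("labels must match feature rows")
  if (nlevels(labels) < 2L) stop("need at least 2 classes")
  if (nlevels(labels) != model$spec$n_classes) {
    stop(sprintf("model expects %d classes but labels have %d",
                 model$spec$n_classes, nlevels(labels)))
  }
  y <- as.integer(labels)

  # order-invariance: fix a canonical row order before seeded shuffling
  ord <- order(y, sample_key(x))
  x <- slice_x(x, ord)
  y <- y[ord]

  is_multi <- is.null(model$layers)
  state <- if (is_multi) {
    list(b1 = adam_init(model$branches[[1L]]),
         b2 = adam_init(model$branches[[2L]]),
         head = adam_init(model$head))
  } else {
    list(main = adam_init(model$layers))
  }
  history <- numeric(cfg$epochs)
  step <- 0L
  with_seed(derive_seed(seed, 503L), {
    for (epoch in seq_len(cfg$epochs)) {
      idx <- sample.int(n)
      total <- 0
      for (start in seq(1L, n, by = cfg$batch_size)) {
        bi <- idx[start:min(start + cfg$batch_size - 1L, n)]
        xb <- slice_x(x, bi)
        fwd <- model_forward(model, xb)
        lr <- softmax_ce(fwd$logits, y[bi])
        if (!is.finite(lr$loss)) {
          stop(sprintf("training diverged: non-finite loss at epoch %d",
                       epoch))
        }
        grads <- model_backward(model, fwd$caches, lr$dlogits)
        step <- step + 1L
        if (is_multi) {
          u1 <- adam_step(model$branches[[1L]], grads$b1, state$b1,
                          cfg$learning_rate, step)
          u2 <- adam_step(model$branches[[2L]], grads$b2, state$b2,
                          cfg$learning_rate, step)
          uh <- adam_step(model$head, grads$head, state$head,
                          cfg$learning_rate, step)
          model$branches[[1L]] <- u1$layers; state$b1 <- u1$state
          model$branches[[2L]] <- u2$layers; state$b2 <- u2$state
          model$head <- uh$layers; state$head <- uh$state
        } else {
          u <- adam_step(model$layers, grads$main, state$main,
                         cfg$learning_rate, step)
          model$layers <- u$layers; state$main <- u$state
        }
        total <- total + lr$loss * length(bi)
      }
      history[epoch] <- total / n
    }
  })
  structure(list(model = model, history = history,
                 levels = levels(labels), cfg = cfg, seed = seed),
            class = "trained_cnn")
}

# deterministic per-row sort key so training ignores input row order
sample_key <- function(x) {
  a <- if (is.list(x)) x[[1L]] else x
  apply(a, 1L, function(r) sum(r * seq_along(r)) + sum(r^2))
}

#' @export
print.trained_cnn <- function(x, ...) {
  cat(sprintf("<trained_cnn> %s, %d epochs, final loss %.4f\n",
              x$model$spec$family, length(x$history),
              x$history[length(x$history)]))
  invisible(x)
}

#' Class-probability scores for new trials
#'
#' @param trained a `trained_cnn` from [train()].
#' @param features a `feature_set` or feature array(s) matching the model's
#'   input layout.
#' @return n x K matrix of softmax probabilities (rows sum to 1), columns
#'   named by class.
#' @export
predict_scores <- function(trained, features) {
  stopifnot(inherits(trained, "trained_cnn"))
  x <- feature_arrays(features)$x
  check_shape <- function(arr, shape) {
    if (!identical(as.integer(dim(arr)[2:3]), as.integer(shape))) {
      stop(sprintf("feature shape (%s) does not match model input (%s)",
                   paste(dim(arr)[2:3], collapse = " x "),
                   paste(shape, collapse = " x ")))
    }
  }
  spec <- trained$model$spec
  if (spec$family == "multi_input_cnn") {
    if (!is.list(x) || length(x) != 2L) {
      stop("multi-input model needs a list of two branch arrays")
    }
    check_shape(x[[1L]], spec$input_shape[[1L]])
    check_shape(x[[2L]], spec$input_shape[[2L]])
  } else {
    if (is.list(x)) stop("single-input model got branched features")
    check_shape(x, spec$input_shape)
  }
  P <- softmax_rows(model_forward(trained$model, x)$logits)
  colnames(P) <- trained$levels
  P
}
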