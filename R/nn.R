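# Feed-forward classifier: fingerprint input, ReLU hidden layers, sigmoid
# output, binary cross-entropy, Adam, inverted dropout, early stopping on
# the monitored training loss. Written on base-R matrix operations; the
# same core carries the transfer-learning mechanism (layer-wise parameter
# copy between source and target networks).

#' DNN configuration
#'
#' Defaults follow the reference architecture: 1,024-bit input, hidden
#' layers of 1,000 and 500 units, dropout 0.25 per layer, Adam with learning
#' rate 0.001, batch size 64, up to 2,000 epochs with early-stopping
#' patience 50.
#'
#' @param input_width input dimension (fingerprint length).
#' @param hidden_widths integer vector of hidden-layer widths.
#' @param dropout_rate dropout probability applied to each hidden layer
#'   during training, in \[0, 1).
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param max_epochs training epoch cap.
#' @param early_stop_patience epochs without loss improvement before halting.
#' @param seed RNG seed controlling initialization, shuffling and dropout.
#' @export
dnn_config <- function(input_width = 1024L, hidden_widths = c(1000L, 500L),
                       dropout_rate = 0.25, learning_rate = 0.001,
                       batch_size = 64L, max_epochs = 2000L,
                       early_stop_patience = 50L, seed = 1L) {
  stopifnot(dropout_rate >= 0, dropout_rate < 1, all(hidden_widths > 0),
            input_width > 0, batch_size > 0, max_epochs >= 0)
  structure(list(input_width = as.integer(input_width),
                 hidden_widths = as.integer(hidden_widths),
                 dropout_rate = dropout_rate, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "dnn_config")
}

mlp_init <- function(cfg) {
  widths <- c(cfg$input_width, cfg$hidden_widths, 1L)
  layers <- vector("list", length(widths) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- widths[l]
    layers[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * widths[l + 1L], sd = sqrt(2 / fan_in)),
                 fan_in, widths[l + 1L]),
      b = rep(0, widths[l + 1L])
    )
  }
  layers
}

mlp_forward <- function(layers, X, dropout_rate = 0, train = FALSE) {
  nl <- length(layers)
  acts <- vector("list", nl + 1L)
  masks <- vector("list", nl)
  acts[[1L]] <- X
  for (l in seq_len(nl)) {
    z <- sweep(acts[[l]] %*% layers[[l]]$W, 2L, layers[[l]]$b, "+")
    if (l < nl) {
      a <- pmax(z, 0)
      if (train && dropout_rate > 0) {
        m <- matrix(stats::runif(length(a)) >= dropout_rate, nrow(a), ncol(a))
        a <- a * m / (1 - dropout_rate)
        masks[[l]] <- m
      }
      acts[[l + 1L]] <- a
    } else {
      acts[[l + 1L]] <- 1 / (1 + exp(-z))
    }
  }
  list(acts = acts, masks = masks)
}

# gradient of mean binary cross-entropy wrt all parameters
mlp_backward <- function(layers, fwd, y, dropout_rate = 0) {
  nl <- length(layers)
  n <- length(y)
  grads <- vector("list", nl)
  # sigmoid + BCE: delta at output pre-activation = (p - y) / n
  delta <- (fwd$acts[[nl + 1L]] - y) / n
  for (l in rev(seq_len(nl))) {
    a_prev <- fwd$acts[[l]]
    grads[[l]] <- list(W = crossprod(a_prev, delta), b = colSums(delta))
    if (l > 1L) {
      delta <- delta %*% t(layers[[l]]$W)
      if (!is.null(fwd$masks[[l - 1L]])) {
        delta <- delta * fwd$masks[[l - 1L]] / (1 - dropout_rate)
      }
      delta <- delta * (fwd$acts[[l]] > 0)
    }
  }
  grads
}

adam_state_init <- function(layers) {
  lapply(layers, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                  mb = l$b * 0, vb = l$b * 0))
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(layers)) {
    s <- state[[l]]; g <- grads[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
    layers[[l]]$W <- layers[[l]]$W - lr * (s$mW / corr1) / (sqrt(s$vW / corr2) + eps)
    layers[[l]]$b <- layers[[l]]$b - lr * (s$mb / corr1) / (sqrt(s$vb / corr2) + eps)
    state[[l]] <- s
  }
  list(layers = layers, state = state)
}

bce_loss <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train the feed-forward DNN classifier
#'
#' @param fps a `fingerprint_matrix` of the training compounds.
#' @param labels character vector in `{"active","inactive"}` aligned with
#'   `fps$ids` (actives are the positive class).
#' @param cfg a [dnn_config()]; `cfg$input_width` must equal the
#'   fingerprint length.
#' @param init optional pre-initialized layer list (used by the transfer
#'   mechanism); layers not supplied are freshly initialized.
#' @return a `classifier_model` of kind `"dnn"` with the training-loss
#'   curve in `$history`.
#' @export
train_dnn <- function(fps, labels, cfg = dnn_config(), init = NULL) {
  X <- fps$bits * 1
  stopifnot(ncol(X) == cfg$input_width, nrow(X) == length(labels))
  y <- as.numeric(labels == "active")
  if (cfg$max_epochs > 0 && length(unique(y)) < 2L) {
    stop("training requires at least one compound per class")
  }
  with_seed(cfg$seed, {
    layers <- if (is.null(init)) mlp_init(cfg) else init
    state <- adam_state_init(layers)
    t_step <- 0L
    best <- Inf; wait <- 0L
    history <- numeric(0)
    n <- nrow(X)
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
        fwd <- mlp_forward(layers, X[idx, , drop = FALSE],
                           cfg$dropout_rate, train = TRUE)
        p <- fwd$acts[[length(layers) + 1L]]
        epoch_loss <- epoch_loss + bce_loss(p, y[idx]) * length(idx)
        grads <- mlp_backward(layers, fwd, y[idx], cfg$dropout_rate)
        t_step <- t_step + 1L
        upd <- adam_step(layers, grads, state, cfg$learning_rate, t_step)
        layers <- upd$layers; state <- upd$state
      }
      epoch_loss <- epoch_loss / n
      history <- c(history, epoch_loss)
      if (epoch_loss < best - 1e-7) { best <- epoch_loss; wait <- 0L }
      else {
        wait <- wait + 1L
        if (wait >= cfg$early_stop_patience) break
      }
    }
    structure(list(kind = "dnn", layers = layers, config = cfg,
                   fp_config = fps$config, history = history),
              class = "classifier_model")
  })
}

#' Predict class probabilities
#'
#' @param model a `classifier_model`.
#' @param fps a `fingerprint_matrix` with the same configuration as used in
#'   training.
#' @return numeric vector of active-class probabilities in \[0, 1\]; the
#'   hard label is active iff the probability is `>= threshold` (0.5 by
#'   convention, see [predict_label()]).
#' @export
predict_proba <- function(model, fps) {
  stopifnot(inherits(model, "classifier_model"))
  if (!identical(unclass(model$fp_config), unclass(fps$config))) {
    stop("fingerprint configuration does not match the training configuration")
  }
  X <- fps$bits * 1
  switch(model$kind,
    dnn = {
      fwd <- mlp_forward(model$layers, X)
      as.numeric(fwd$acts[[length(model$layers) + 1L]])
    },
    naive_bayes = {
      df <- as.data.frame(lapply(seq_len(ncol(X)), function(j) {
        factor(X[, j], levels = c(0, 1))
      }))
      names(df) <- paste0("b", seq_len(ncol(X)))
      as.numeric(stats::predict(model$fit, df, type = "raw")[, "active"])
    },
    random_forest = {
      colnames(X) <- paste0("b", seq_len(ncol(X)))
      as.numeric(stats::predict(model$fit, data.frame(X))$predictions[, "active"])
    },
    gradient_boosting = {
      as.numeric(stats::predict(model$fit, xgboost::xgb.DMatrix(X)))
    },
    stop("unknown model kind: ", model$kind)
  )
}

#' Hard labels from probabilities
#'
#' @param proba probabilities from [predict_proba()].
#' @param threshold decision threshold; ties (exactly at the threshold) are
#'   labeled active.
#' @return character vector in `{"active","inactive"}`.
#' @export
predict_label <- function(proba, threshold = 0.5) {
  ifelse(proba >= threshold, "active", "inactive")
}

#' Train a baseline classifier
#'
#' Wraps established implementations (Bernoulli-style naive Bayes from
#' e1071 with Laplace smoothing, random forest from ranger, gradient
#' boosting from xgboost) behind the same probability contract as the DNN.
#'
#' @param kind one of `"naive_bayes"`, `"random_forest"`,
#'   `"gradient_boosting"`.
#' @param fps training `fingerprint_matrix`.
#' @param labels class labels aligned with `fps$ids`.
#' @param seed RNG seed.
#' @param ... passed to the underlying implementation.
#' @return a `classifier_model`.
#' @export
train_baseline <- function(kind, fps, labels, seed = 1L, ...) {
  kind <- match.arg(kind, c("naive_bayes", "random_forest", "gradient_boosting"))
  X <- fps$bits * 1
  y <- factor(labels, levels = c("inactive", "active"))
  fit <- with_seed(seed, switch(kind,
    naive_bayes = {
      df <- as.data.frame(lapply(seq_len(ncol(X)), function(j) {
        factor(X[, j], levels = c(0, 1))
      }))
      names(df) <- paste0("b", seq_len(ncol(X)))
      e1071::naiveBayes(df, y, laplace = 1, ...)
    },
    random_forest = {
      colnames(X) <- paste0("b", seq_len(ncol(X)))
      ranger::ranger(x = data.frame(X), y = y, probability = TRUE,
                     seed = seed, num.threads = 1L, ...)
    },
    gradient_boosting = {
      args <- list(...)
      nrounds <- if (is.null(args$nrounds)) 100L else args$nrounds
      args$nrounds <- NULL
      xgboost::xgb.train(
        params = c(list(objective = "binary:logistic", nthread = 1L,
                        seed = seed), args),
        data = xgboost::xgb.DMatrix(X, label = as.numeric(y == "active")),
        nrounds = nrounds, verbose = 0)
    }
  ))
  structure(list(kind = kind, fit = fit, fp_config = fps$config,
                 hyperparameters = list(seed = seed, ...)),
            class = "classifier_model")
}

#' Pre-train a source-domain DNN
#'
#' Trains a DNN on a larger related-target dataset (the source domain) with
#' the standard protocol, for later parameter transfer into a target model.
#' The source set must use the same fingerprint configuration and label
#' semantics as the target.
#'
#' @inheritParams train_dnn
#' @return a `classifier_model` of kind `"dnn"`.
#' @export
pretrain_source <- function(fps, labels, cfg = dnn_config()) {
  train_dnn(fps, labels, cfg)
}

#' Transfer hidden-layer parameters into a fresh target network
#'
#' Copies the weights and biases of the selected hidden layers from a
#' trained source DNN into a newly initialized network with the target
#' configuration; all other layers are freshly initialized under the target
#' seed, and no other component (optimizer, loss, hyperparameters) is
#' modified. The returned initialization is then trained (fine-tuned,
#' including the transferred layers) with [train_dnn()].
#'
#' @param source a trained `classifier_model` of kind `"dnn"`.
#' @param target_cfg [dnn_config()] for the target network.
#' @param layers_to_transfer integer indices of hidden layers to copy
#'   (1 = first hidden layer; default transfers only the first).
#' @return an initialized (untrained) layer list suitable as the `init`
#'   argument of [train_dnn()].
#' @export
transfer_weights <- function(source, target_cfg, layers_to_transfer = 1L) {
  stopifnot(inherits(source, "classifier_model"), source$kind == "dnn")
  n_hidden <- length(target_cfg$hidden_widths)
  if (any(layers_to_transfer < 1L | layers_to_transfer > n_hidden)) {
    stop("layers_to_transfer indices out of range")
  }
  init <- with_seed(target_cfg$seed, mlp_init(target_cfg))
  for (l in layers_to_transfer) {
    src <- source$layers[[l]]
    if (!all(dim(src$W) == dim(init[[l]]$W))) {
      stop("layer ", l, " width mismatch between source and target")
    }
    init[[l]] <- src
  }
  init
}

#' Serialize / restore a classifier model
#'
#' Model state is written as a directory holding a JSON manifest
#' (kind, configs, history, hyperparameters) plus an RDS with the trained
#' parameters.
#'
#' @param model a `classifier_model`.
#' @param dir target directory (created).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(kind = model$kind,
                   fp_config = unclass(model$fp_config),
                   config = if (!is.null(model$config)) unclass(model$config),
                   history = model$history,
                   hyperparameters = model$hyperparameters)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname save_model
#' @param dir directory written by [save_model()].
#' @export
load_model <- function(dir) {
  readRDS(file.path(dir, "model.rds"))
}
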