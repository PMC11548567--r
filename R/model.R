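#' Training configuration
#'
#' @param epochs Training epochs (default 50).
#' @param batch_size Mini-batch size (default 32).
#' @param learning_rate Optimiser step size (default 0.001).
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param loss `"categorical_crossentropy"` (default) or `"focal"`.
#' @param focal_gamma Focusing exponent for the focal loss (default 2).
#' @param seed Integer seed controlling weight initialisation, batch
#'   shuffling and dropout; identical seed, data and configuration give
#'   an identical training history.
#' @param verbose Print per-epoch metrics.
#' @return A `train_config` object (named list).
#' @export
train_config <- function(epochs = 50, batch_size = 32, learning_rate = 0.001,
                         optimizer = c("adam", "sgd"),
                         loss = c("categorical_crossentropy", "focal"),
                         focal_gamma = 2, seed = 1L, verbose = FALSE) {
  optimizer <- match.arg(optimizer)
  loss <- match.arg(loss)
  stopifnot(epochs >= 0, batch_size >= 1, learning_rate > 0, focal_gamma >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 optimizer = optimizer, loss = loss,
                 focal_gamma = focal_gamma,
                 seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

ACT_CODES <- c(none = 0L, relu = 1L, softmax = 2L)
KIND_CODES <- c(conv1d = 0L, maxpool1d = 1L, dropout = 2L, flatten = 3L, dense = 4L)

# flatten an arch_spec into the parallel vectors the engine consumes
arch_to_cpp <- function(arch) {
  ls <- arch$layers
  list(
    input_len = arch$input_len,
    input_channels = arch$input_channels,
    kind = vapply(ls, function(l) KIND_CODES[[l$kind]], integer(1)),
    arg1 = vapply(ls, function(l) {
      as.integer(switch(l$kind, conv1d = l$filters, maxpool1d = l$pool,
                        dense = l$units, 0L))
    }, integer(1)),
    arg2 = vapply(ls, function(l) {
      as.integer(if (l$kind == "conv1d") l$kernel else 0L)
    }, integer(1)),
    rate = vapply(ls, function(l) {
      if (l$kind == "dropout") l$rate else 0
    }, numeric(1)),
    act = vapply(ls, function(l) {
      ACT_CODES[[l$activation %||% "none"]]
    }, integer(1))
  )
}

# He-normal init for ReLU layers, Glorot for the softmax head
init_params <- function(arch, seed) {
  summ <- summarize_arch(arch)           # validates shapes
  len <- arch$input_len
  ch <- arch$input_channels
  params <- vector("list", length(arch$layers))
  with_local_seed(seed, {
    for (li in seq_along(arch$layers)) {
      l <- arch$layers[[li]]
      if (l$kind == "conv1d") {
        fan_in <- l$kernel * ch
        sdv <- sqrt(2 / fan_in)
        params[[li]] <- list(
          W = matrix(rnorm(fan_in * l$filters, 0, sdv), fan_in, l$filters),
          b = numeric(l$filters))
        len <- conv_out_len(len, l$kernel)
        ch <- l$filters
      } else if (l$kind == "maxpool1d") {
        len <- pool_out_len(len, l$pool)
      } else if (l$kind == "flatten") {
        len <- len * ch
        ch <- 1L
      } else if (l$kind == "dense") {
        sdv <- if (identical(l$activation, "softmax")) {
          sqrt(2 / (len + l$units))
        } else {
          sqrt(2 / len)
        }
        params[[li]] <- list(
          W = matrix(rnorm(len * l$units, 0, sdv), len, l$units),
          b = numeric(l$units))
        len <- l$units
      }
    }
  })
  params
}

#' Build a trainable 1D-CNN from an architecture specification
#'
#' Allocates and initialises the network weights (He-normal for ReLU
#' layers, Glorot for the softmax head, seeded) for the package's
#' compiled training engine. The model's `param_count` is derived from
#' the allocated weight arrays themselves and therefore provides an
#' independent check of [summarize_arch()]'s arithmetic.
#'
#' @param arch An [arch_spec()] (default [default_arch()]).
#' @param cfg A [train_config()].
#' @return A `cnn_model` object.
#' @export
#' @examples
#' m <- build_cnn(default_arch())
#' m$param_count
build_cnn <- function(arch = default_arch(), cfg = train_config()) {
  stopifnot(inherits(arch, "arch_spec"))
  params <- init_params(arch, cfg$seed)
  n_classes <- arch$layers[[length(arch$layers)]]$units
  structure(list(
    arch = arch,
    cfg = cfg,
    params = params,
    param_count = sum(vapply(params, function(p) {
      if (is.null(p)) 0L else length(p$W) + length(p$b)
    }, integer(1))),
    n_classes = n_classes,
    classes = CLASS_LEVELS[seq_len(min(n_classes, 4L))],
    trained = FALSE,
    history = NULL
  ), class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("1D-CNN model: input %d samples, %d classes, %s parameters%s\n",
              x$arch$input_len, x$n_classes,
              format(x$param_count, big.mark = ","),
              if (x$trained) " (trained)" else " (untrained)"))
  invisible(x)
}

labels_to_int <- function(y, classes) {
  y <- as.character(y)
  bad <- setdiff(unique(y), classes)
  if (length(bad) > 0) abort(paste0("labels outside the model's classes: ",
                                    paste(bad, collapse = ", ")))
  match(y, classes) - 1L
}

#' Train a 1D-CNN
#'
#' Mini-batch gradient descent (Adam by default) with categorical
#' cross-entropy or focal loss, recording per-epoch training and
#' validation loss/accuracy. Fully deterministic under
#' `cfg$seed`. `epochs = 0` returns the untrained model with an empty
#' history.
#'
#' @param model A [build_cnn()] model.
#' @param train A [dataset_matrix()]; its row width must equal the
#'   architecture input length.
#' @param val Optional validation [dataset_matrix()] (disjoint from
#'   `train`).
#' @param cfg A [train_config()]; defaults to the one stored in the
#'   model.
#' @return The model with fitted `params` and a `history` tibble
#'   (`epoch`, `train_loss`, `train_acc`, `val_loss`, `val_acc`).
#' @export
train_cnn <- function(model, train, val = NULL, cfg = NULL) {
  stopifnot(inherits(model, "cnn_model"), inherits(train, "dataset_matrix"))
  cfg <- cfg %||% model$cfg
  if (ncol(train$X) != model$arch$input_len) {
    abort(sprintf("training rows have %d samples but the model expects %d",
                  ncol(train$X), model$arch$input_len))
  }
  gamma <- if (cfg$loss == "focal") cfg$focal_gamma else 0
  y <- labels_to_int(train$y, model$classes)
  if (is.null(val)) {
    Xval <- matrix(numeric(0), 0, ncol(train$X))
    yval <- integer(0)
  } else {
    Xval <- val$X
    yval <- labels_to_int(val$y, model$classes)
  }
  if (cfg$epochs == 0) {
    model$history <- tibble(epoch = integer(), train_loss = numeric(),
                            train_acc = numeric(), val_loss = numeric(),
                            val_acc = numeric())
    return(model)
  }
  fit <- cpp_cnn_train(train$X, y, Xval, yval,
                       arch_to_cpp(model$arch), model$params,
                       cfg$epochs, cfg$batch_size, cfg$learning_rate,
                       cfg$optimizer, gamma, cfg$seed, cfg$verbose)
  model$params <- fit$params
  h <- fit$history
  model$history <- tibble(
    epoch = seq_along(h$train_loss),
    train_loss = h$train_loss,
    train_acc = h$train_acc,
    val_loss = if (length(h$val_loss)) h$val_loss else NA_real_,
    val_acc = if (length(h$val_acc)) h$val_acc else NA_real_
  )
  model$trained <- TRUE
  model$cfg <- cfg
  model
}

#' Predict class probabilities or labels
#'
#' @param object A trained `cnn_model`.
#' @param newdata A [dataset_matrix()] or plain numeric matrix with one
#'   clip per row.
#' @param type `"prob"` for the softmax matrix, `"class"` for argmax
#'   labels.
#' @param ... Unused.
#' @return Probability matrix (rows sum to 1) or a factor of labels.
#' @export
predict.cnn_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "dataset_matrix")) newdata$X else as.matrix(newdata)
  if (ncol(X) != object$arch$input_len) {
    abort(sprintf("input rows have %d samples but the model expects %d",
                  ncol(X), object$arch$input_len))
  }
  P <- cpp_cnn_predict(X, arch_to_cpp(object$arch), object$params)
  colnames(P) <- object$classes
  if (type == "prob") return(P)
  factor(object$classes[max.col(P, ties.method = "first")],
         levels = object$classes)
}

#' Focal loss
#'
#' Mean over samples of `-(1 - p_true)^gamma * log(p_true)`, the
#' cross-entropy variant that down-weights confidently classified
#' samples; `gamma = 0` recovers categorical cross-entropy exactly.
#' Zero probabilities are clipped at `1e-12` with a warning.
#'
#' @param probs N x C matrix of predicted probabilities (rows sum to 1).
#' @param one_hot N x C one-hot label matrix.
#' @param gamma Focusing exponent, `>= 0`.
#' @return Scalar loss.
#' @export
#' @examples
#' focal_loss(matrix(c(0.5, 0.5), 1), matrix(c(1, 0), 1), gamma = 2)
focal_loss <- function(probs, one_hot, gamma = 2) {
  probs <- as.matrix(probs)
  one_hot <- as.matrix(one_hot)
  stopifnot(all(dim(probs) == dim(one_hot)), gamma >= 0)
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    abort("probability rows must sum to 1")
  }
  p_true <- rowSums(probs * one_hot)
  if (any(p_true <= 0)) {
    warn("zero predicted probability for a true class; clipping at 1e-12")
    p_true <- pmax(p_true, 1e-12)
  }
  mean(-(1 - p_true)^gamma * log(p_true))
}

#' @export
tidy.cnn_model <- function(x, ...) {
  if (is.null(x$history)) {
    abort("model has no training history; call train_cnn() first")
  }
  tidyr::pivot_longer(x$history, -"epoch",
                      names_to = c("split", "metric"), names_sep = "_",
                      values_to = "value")
}

#' @export
glance.cnn_model <- function(x, ...) {
  h <- x$history
  tibble(
    param_count = x$param_count,
    trained = x$trained,
    epochs = if (is.null(h)) 0L else nrow(h),
    final_train_acc = if (is.null(h) || nrow(h) == 0) NA_real_ else h$train_acc[nrow(h)],
    final_val_acc = if (is.null(h) || nrow(h) == 0) NA_real_ else h$val_acc[nrow(h)]
  )
}

#' @export
autoplot.cnn_model <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value, colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL)
}
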