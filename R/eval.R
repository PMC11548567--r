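#' Stratified k-fold partition
#'
#' Splits indices into `k` disjoint folds preserving class composition:
#' within every class the per-fold counts differ by at most one. Seeded
#' and deterministic.
#'
#' @param labels Class labels (factor or character).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return List of `k` integer index vectors that partition
#'   `seq_along(labels)`.
#' @export
kfold_split <- function(labels, k, seed = 1L) {
  stopifnot(k >= 2)
  labels <- as.character(labels)
  tab <- table(labels)
  small <- names(tab)[tab < k]
  if (length(small) > 0) {
    abort(paste0("class(es) with fewer members than k = ", k, ": ",
                 paste(small, collapse = ", ")))
  }
  folds <- vector("list", k)
  with_local_seed(seed, {
    for (cl in names(tab)) {
      idx <- sample(which(labels == cl))
      assign_to <- rep_len(seq_len(k), length(idx))
      for (f in seq_len(k)) {
        folds[[f]] <- c(folds[[f]], idx[assign_to == f])
      }
    }
  })
  lapply(folds, sort)
}

#' Classification report from truth and predictions
#'
#' Builds the 4 x 4 confusion matrix (rows = true class, columns =
#' predicted class) and derives overall accuracy, per-class precision,
#' recall, F1 and support, and macro-averaged one-vs-rest sensitivity,
#' specificity, precision and F1. A per-class precision, recall or F1
#' whose denominator is zero is reported as 0 (with a warning).
#'
#' @param truth True labels.
#' @param pred Predicted labels.
#' @param classes Label universe (default [class_levels()]).
#' @return An `eval_report` object.
#' @seealso [evaluate()]
#' @export
eval_report <- function(truth, pred, classes = class_levels()) {
  truth <- factor(as.character(truth), levels = classes)
  pred <- factor(as.character(pred), levels = classes)
  stopifnot(length(truth) == length(pred), length(truth) > 0,
            !anyNA(truth), !anyNA(pred))
  conf <- table(truth = truth, pred = pred)
  eval_report_from_confusion(unclass(conf))
}

#' @rdname eval_report
#' @param confusion Square count matrix, rows = true, columns =
#'   predicted.
#' @export
eval_report_from_confusion <- function(confusion) {
  conf <- as.matrix(confusion)
  stopifnot(nrow(conf) == ncol(conf), all(conf >= 0))
  classes <- rownames(conf) %||% paste0("class", seq_len(nrow(conf)))
  dimnames(conf) <- list(truth = classes, pred = classes)
  total <- sum(conf)
  stopifnot(total > 0)
  diag_c <- diag(conf)
  support <- rowSums(conf)
  predicted <- colSums(conf)

  safe_div <- function(num, den, what) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0)) {
      warn(paste0(what, " undefined (zero denominator) for: ",
                  paste(classes[den == 0], collapse = ", "), "; reported as 0"))
    }
    out
  }
  precision <- safe_div(diag_c, predicted, "precision")
  recall <- safe_div(diag_c, support, "recall")
  f1_den <- precision + recall
  f1 <- ifelse(f1_den > 0, 2 * precision * recall / f1_den, 0)

  # one-vs-rest specificity: TN / (TN + FP) per class
  specificity <- vapply(seq_along(classes), function(i) {
    tn <- total - support[i] - predicted[i] + diag_c[i]
    fp <- predicted[i] - diag_c[i]
    if (tn + fp > 0) tn / (tn + fp) else 0
  }, numeric(1))
  # per-class accuracy: (TP + TN) / total, one-vs-rest
  class_acc <- vapply(seq_along(classes), function(i) {
    tp <- diag_c[i]
    tn <- total - support[i] - predicted[i] + diag_c[i]
    (tp + tn) / total
  }, numeric(1))

  structure(list(
    confusion = conf,
    accuracy = sum(diag_c) / total,
    per_class = tibble(
      class = factor(classes, levels = classes),
      accuracy = unname(class_acc),
      precision = unname(precision),
      recall = unname(recall),
      f1 = unname(f1),
      specificity = unname(specificity),
      support = unname(as.integer(support))
    ),
    macro = c(sensitivity = mean(recall),
              specificity = mean(specificity),
              precision = mean(precision),
              f1 = mean(f1)),
    n = total
  ), class = "eval_report")
}

#' Evaluate a fitted model on a test partition
#'
#' Argmax predictions over the softmax output, summarised as an
#' [eval_report()].
#'
#' @param model A trained [build_cnn()] model.
#' @param test A [dataset_matrix()].
#' @return An `eval_report`.
#' @export
evaluate <- function(model, test) {
  stopifnot(inherits(test, "dataset_matrix"), nrow(test$X) > 0)
  pred <- predict(model, test, type = "class")
  eval_report(test$y, pred, classes = model$classes)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: accuracy %.4f on %d clips\n", x$accuracy, x$n))
  print(x$confusion)
  print(as.data.frame(x$per_class), row.names = FALSE, digits = 4)
  cat(sprintf("macro: sensitivity %.4f  specificity %.4f  precision %.4f  f1 %.4f\n",
              x$macro["sensitivity"], x$macro["specificity"],
              x$macro["precision"], x$macro["f1"]))
  invisible(x)
}

#' @export
tidy.eval_report <- function(x, ...) x$per_class

#' @export
glance.eval_report <- function(x, ...) {
  tibble(accuracy = x$accuracy,
         sensitivity = x$macro[["sensitivity"]],
         specificity = x$macro[["specificity"]],
         precision = x$macro[["precision"]],
         f1 = x$macro[["f1"]],
         n = x$n)
}

#' @export
autoplot.eval_report <- function(object, ...) {
  df <- as.data.frame(object$confusion)
  ggplot2::ggplot(df, ggplot2::aes(.data$pred, .data$truth, fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq)) +
    ggplot2::scale_y_discrete(limits = rev(levels(df$truth))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "true", fill = "count")
}

#' Stratified k-fold cross-validation of the full training recipe
#'
#' For each fold: oversample the fold's training split with
#' [smote_balance()] (never the held-out fold), train a fresh network,
#' and evaluate on the held-out fold. Reports per-fold
#' [eval_report()]s and the mean and standard deviation of accuracy,
#' macro sensitivity, specificity, precision and F1.
#'
#' @param data A [dataset_matrix()].
#' @param arch An [arch_spec()].
#' @param cfg A [train_config()].
#' @param k Number of folds (5 and 10 are conventional).
#' @param smote_cfg A [smote_config()], or `NULL` to skip balancing.
#' @param seed Seed for the fold partition.
#' @return A `cv_result`: list with `k`, `fold_reports` and a `summary`
#'   tibble (metric, mean, sd).
#' @export
crossval <- function(data, arch = default_arch(), cfg = train_config(),
                     k = 5, smote_cfg = smote_config(), seed = 1L) {
  stopifnot(inherits(data, "dataset_matrix"))
  folds <- kfold_split(data$y, k, seed)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    hold <- folds[[f]]
    tr <- dm_subset(data, setdiff(seq_along(data$y), hold))
    if (!is.null(smote_cfg)) tr <- smote_balance(tr, smote_cfg)
    model <- build_cnn(arch, cfg)
    model <- train_cnn(model, tr, val = NULL, cfg = cfg)
    reports[[f]] <- evaluate(model, dm_subset(data, hold))
  }
  metrics <- purrr::map_dfr(reports, glance)
  summary <- tibble(
    metric = c("accuracy", "sensitivity", "specificity", "precision", "f1"),
    mean = vapply(c("accuracy", "sensitivity", "specificity", "precision", "f1"),
                  function(m) mean(metrics[[m]]), numeric(1)),
    sd = vapply(c("accuracy", "sensitivity", "specificity", "precision", "f1"),
                function(m) sd(metrics[[m]]), numeric(1))
  )
  structure(list(k = k, fold_reports = reports, summary = summary),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation\n", x$k))
  print(as.data.frame(x$summary), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) x$summary

#' @export
glance.cv_result <- function(x, ...) {
  tibble(k = x$k,
         mean_accuracy = x$summary$mean[x$summary$metric == "accuracy"],
         sd_accuracy = x$summary$sd[x$summary$metric == "accuracy"])
}

#' @export
autoplot.cv_result <- function(object, ...) {
  df <- purrr::imap_dfr(object$fold_reports,
                        function(r, i) dplyr::mutate(glance(r), fold = i))
  df <- tidyr::pivot_longer(df, c("accuracy", "sensitivity", "specificity",
                                  "precision", "f1"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$fold))) +
    ggplot2::labs(x = NULL, y = NULL, colour = "fold")
}
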