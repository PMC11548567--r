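#' Hyperparameter grid specification
#'
#' The default grid is the tuning grid used for this network family:
#' three candidate values for each of five knobs (243 combinations).
#' `n_filters` and `kernel_size` set the first convolution block;
#' subsequent blocks follow the network's progression (filters double,
#' kernels shrink by 2 per block — see [arch_from_grid()]).
#' `num_units` sets the first dense layer, halving in the next two.
#'
#' @param n_filters Candidate first-block filter counts.
#' @param kernel_size Candidate first-block kernel widths.
#' @param dropout_rate Candidate dropout fractions.
#' @param num_units Candidate first-dense-layer widths.
#' @param learning_rate Candidate optimiser step sizes.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(n_filters = c(32, 64, 128),
                      kernel_size = c(3, 5, 7),
                      dropout_rate = c(0.2, 0.3, 0.4),
                      num_units = c(64, 128, 256),
                      learning_rate = c(0.0001, 0.001, 0.01)) {
  fields <- list(n_filters = n_filters, kernel_size = kernel_size,
                 dropout_rate = dropout_rate, num_units = num_units,
                 learning_rate = learning_rate)
  if (any(vapply(fields, length, integer(1)) == 0)) {
    abort("every grid dimension needs at least one candidate value")
  }
  structure(fields, class = "grid_spec")
}

#' Enumerate every grid combination
#'
#' @param grid A [grid_spec()].
#' @return Tibble with one row per combination (Cartesian product, in
#'   list order).
#' @export
#' @examples
#' nrow(enumerate_grid(grid_spec()))
enumerate_grid <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  tidyr::expand_grid(
    n_filters = grid$n_filters,
    kernel_size = grid$kernel_size,
    dropout_rate = grid$dropout_rate,
    num_units = grid$num_units,
    learning_rate = grid$learning_rate
  )
}

#' Build an architecture from one grid point
#'
#' Expands the single-value grid knobs into the four-block topology:
#' convolution filters `f, 2f, 4f, 8f` with kernels
#' `k, k-2, k-4, k-6` (floored at 1), pool width 3 throughout, dense
#' widths `u, u/2, u/4` (floored at the class count), then the softmax
#' head.
#'
#' @param n_filters,kernel_size,dropout_rate,num_units One grid point.
#' @param input_len Model input width in samples.
#' @param n_classes Output classes.
#' @return An [arch_spec()]; infeasible geometry raises a shape error.
#' @export
arch_from_grid <- function(n_filters, kernel_size, dropout_rate, num_units,
                           input_len = 8000, n_classes = 4) {
  layers <- list()
  for (blockk in 0:3) {
    f <- n_filters * 2^blockk
    k <- max(kernel_size - 2 * blockk, 1)
    layers <- c(layers, list(conv1d(f, k), maxpool1d(3), dropout(dropout_rate)))
  }
  layers <- c(layers, list(flatten()))
  for (d in 0:2) {
    u <- max(num_units %/% 2^d, n_classes)
    layers <- c(layers, list(dense(u), dropout(dropout_rate)))
  }
  layers <- c(layers, list(dense(n_classes, activation = "softmax")))
  arch <- arch_spec(input_len, layers)
  summarize_arch(arch)   # fail fast on shape collapse
  arch
}

#' Exhaustive grid search with k-fold cross-validation
#'
#' Evaluates every grid combination by mean k-fold validation accuracy
#' (SMOTE re-applied inside each fold's training split; the held-out
#' fold is never balanced). Combinations whose geometry collapses are
#' skipped with a warning rather than aborting. The ranking is
#' deterministic under `seed`; ties are broken by fewer parameters,
#' then by grid order.
#'
#' @param grid A [grid_spec()].
#' @param data A [dataset_matrix()] (training partition).
#' @param k Folds for the inner cross-validation.
#' @param cfg A [train_config()]; its `learning_rate` is overridden by
#'   each grid point.
#' @param smote_cfg A [smote_config()] or `NULL`.
#' @param seed Seed for the fold partition.
#' @return A `grid_search_result`: list with `results` (ranked tibble:
#'   grid point, `mean_accuracy`, `sd_accuracy`, `params`, `rank`) and
#'   `best` (top row, with its `arch`).
#' @export
grid_search <- function(grid, data, k = 5, cfg = train_config(),
                        smote_cfg = smote_config(), seed = 1L) {
  combos <- enumerate_grid(grid)
  input_len <- ncol(data$X)
  n_classes <- length(levels(data$y))

  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    g <- combos[i, ]
    arch <- tryCatch(
      arch_from_grid(g$n_filters, g$kernel_size, g$dropout_rate, g$num_units,
                     input_len = input_len, n_classes = n_classes),
      error = function(e) {
        warn(sprintf("grid point %d infeasible (%s); skipped", i, conditionMessage(e)))
        NULL
      })
    if (is.null(arch)) next
    cfg_i <- cfg
    cfg_i$learning_rate <- g$learning_rate
    cv <- tryCatch(
      crossval(data, arch, cfg_i, k = k, smote_cfg = smote_cfg, seed = seed),
      error = function(e) {
        warn(sprintf("grid point %d failed (%s); skipped", i, conditionMessage(e)))
        NULL
      })
    if (is.null(cv)) next
    acc <- cv$summary[cv$summary$metric == "accuracy", ]
    rows[[i]] <- dplyr::mutate(g, mean_accuracy = acc$mean, sd_accuracy = acc$sd,
                               params = total_params(arch), grid_index = i)
  }
  results <- dplyr::bind_rows(rows)
  if (nrow(results) == 0) abort("no feasible grid point")
  results <- dplyr::arrange(results, dplyr::desc(.data$mean_accuracy),
                            .data$params, .data$grid_index)
  results$rank <- seq_len(nrow(results))
  best <- results[1, ]
  best_arch <- arch_from_grid(best$n_filters, best$kernel_size,
                              best$dropout_rate, best$num_units,
                              input_len = input_len, n_classes = n_classes)
  structure(list(results = results, best = best, best_arch = best_arch),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("grid search over %d feasible configuration(s)\n", nrow(x$results)))
  print(as.data.frame(head(x$results, 5)), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
tidy.grid_search_result <- function(x, ...) x$results

#' @export
glance.grid_search_result <- function(x, ...) {
  dplyr::mutate(x$best, n_configurations = nrow(x$results))
}
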