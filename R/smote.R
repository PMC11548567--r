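#' SMOTE configuration
#'
#' @param k_neighbors Number of same-class nearest neighbours considered
#'   when interpolating (default 5).
#' @param target_counts Optional named vector (class -> count) of
#'   desired per-class counts; by default every class is raised to the
#'   majority-class count.
#' @param seed Integer seed.
#' @return A `smote_config` object (named list).
#' @export
smote_config <- function(k_neighbors = 5, target_counts = NULL, seed = 1L) {
  stopifnot(k_neighbors >= 1)
  structure(list(k_neighbors = as.integer(k_neighbors),
                 target_counts = target_counts,
                 seed = as.integer(seed)),
            class = "smote_config")
}

#' Same-class k-nearest neighbours of one row
#'
#' Returns the indices of the `k` rows of `X_class` closest (Euclidean)
#' to row `i`, excluding `i` itself; distance ties are broken by lower
#' row index so the result is deterministic.
#'
#' @param X_class Numeric matrix of the minority-class rows only.
#' @param i Query row index.
#' @param k Neighbour count (`k <= nrow(X_class) - 1`).
#' @return Integer vector of `k` row indices.
#' @export
knn_minority <- function(X_class, i, k) {
  X_class <- as.matrix(X_class)
  m <- nrow(X_class)
  if (m < 2) abort("cannot find neighbours in a class with fewer than 2 samples")
  stopifnot(i >= 1, i <= m, k >= 1, k <= m - 1)
  diffs <- sweep(X_class, 2, X_class[i, ])
  d <- sqrt(rowSums(diffs^2))
  d[i] <- Inf
  ord <- order(d, seq_len(m))   # ties -> lower index first
  ord[seq_len(k)]
}

#' Interpolate one synthetic sample between two neighbours
#'
#' The SMOTE interpolation rule: `x_new = x_i + r * (x_j - x_i)` with
#' `r` in `[0, 1]`, so every coordinate of the synthetic sample lies
#' between the corresponding coordinates of its two parents.
#'
#' @param xi,xj Numeric vectors of equal length.
#' @param r Interpolation scalar in `[0, 1]`.
#' @return Numeric vector, the synthetic sample.
#' @export
#' @examples
#' smote_sample(c(0, 0), c(2, 4), 0.5)
smote_sample <- function(xi, xj, r) {
  if (length(xi) != length(xj)) abort("xi and xj must have equal length")
  stopifnot(length(r) == 1, r >= 0, r <= 1)
  xi + r * (xj - xi)
}

#' Balance a training set by synthetic minority oversampling
#'
#' Raises every class of the training partition to its target count
#' (majority count by default) by interpolating between existing
#' same-class samples: base samples are visited cyclically in row
#' order, a neighbour is drawn uniformly among the base's `k_neighbors`
#' same-class nearest neighbours, and the interpolation scalar `r` is
#' drawn uniformly on `[0, 1]` per synthetic sample. Original rows are
#' preserved verbatim and synthetic rows are flagged in the provenance
#' table. Apply this to the training partition only — never to held-out
#' data.
#'
#' @param train A [dataset_matrix()] (training partition).
#' @param cfg A [smote_config()].
#' @return A [dataset_matrix()] with equalised class counts; synthetic
#'   rows carry `provenance$synthetic == TRUE`.
#' @export
smote_balance <- function(train, cfg = smote_config()) {
  stopifnot(inherits(train, "dataset_matrix"))
  counts <- table(train$y)
  present <- names(counts)[counts > 0]
  targets <- cfg$target_counts %||%
    setNames(rep(max(counts), length(present)), present)
  bad <- present[counts[present] > targets[present]]
  if (length(bad) > 0) {
    abort(paste0("target count below current count for class(es): ",
                 paste(bad, collapse = ", ")))
  }

  new_rows <- list()
  new_labels <- character(0)
  new_parents <- character(0)
  with_local_seed(cfg$seed, {
    for (cl in present) {
      need <- targets[[cl]] - counts[[cl]]
      if (need == 0) next
      idx <- which(train$y == cl)
      if (length(idx) < 2) {
        abort(paste0("class '", cl, "' has a single sample and cannot be ",
                     "oversampled by interpolation; lower its target count ",
                     "or merge classes"))
      }
      Xc <- train$X[idx, , drop = FALSE]
      k <- min(cfg$k_neighbors, nrow(Xc) - 1L)
      nn <- lapply(seq_len(nrow(Xc)), function(i) knn_minority(Xc, i, k))
      for (s in seq_len(need)) {
        i <- (s - 1L) %% nrow(Xc) + 1L        # cycle through base rows
        j <- nn[[i]][sample.int(k, 1L)]
        r <- runif(1)
        new_rows[[length(new_rows) + 1L]] <- smote_sample(Xc[i, ], Xc[j, ], r)
        new_labels <- c(new_labels, cl)
        new_parents <- c(new_parents,
                         sprintf("%s:%d+%d", cl, idx[i], idx[j]))
      }
    }
  })

  if (length(new_rows) == 0) return(train)
  X_new <- do.call(rbind, new_rows)
  prov_new <- tibble(file_stem = new_parents,
                     cycle_index = NA_integer_,
                     synthetic = TRUE)
  dataset_matrix(rbind(train$X, X_new),
                 c(as.character(train$y), new_labels),
                 dplyr::bind_rows(train$provenance, prov_new))
}
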