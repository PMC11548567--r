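#' Layer specifications for a 1D convolutional network
#'
#' Declarative layer constructors used to assemble an [arch_spec()].
#' Convolutions are valid (no padding), stride 1; max-pooling uses
#' non-overlapping windows (stride = pool width, no padding).
#'
#' @param filters,units Output channels (conv) or units (dense).
#' @param kernel Convolution kernel width in samples.
#' @param pool Pooling window width.
#' @param rate Dropout fraction in `[0, 1)`.
#' @param activation One of `"relu"`, `"softmax"`, `"none"`.
#' @return A `layer_spec` object (named list with a `kind` field).
#' @name layer_spec
NULL

new_layer <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "layer_spec")
}

#' @rdname layer_spec
#' @export
conv1d <- function(filters, kernel, activation = "relu") {
  stopifnot(filters >= 1, kernel >= 1)
  new_layer("conv1d", filters = as.integer(filters),
            kernel = as.integer(kernel), activation = activation)
}

#' @rdname layer_spec
#' @export
maxpool1d <- function(pool) {
  stopifnot(pool >= 1)
  new_layer("maxpool1d", pool = as.integer(pool))
}

#' @rdname layer_spec
#' @export
dropout <- function(rate) {
  stopifnot(rate >= 0, rate < 1)
  new_layer("dropout", rate = rate)
}

#' @rdname layer_spec
#' @export
flatten <- function() new_layer("flatten")

#' @rdname layer_spec
#' @export
dense <- function(units, activation = "relu") {
  stopifnot(units >= 1)
  new_layer("dense", units = as.integer(units), activation = activation)
}

#' Network architecture specification
#'
#' An ordered list of layers applied to a mono waveform of
#' `input_len` samples. The specification must contain exactly one
#' [flatten()] and end in a [dense()] softmax layer whose width is the
#' number of classes.
#'
#' @param input_len Input length in samples.
#' @param layers List of [layer_spec] objects.
#' @param input_channels Input channels (1 for mono audio).
#' @return An `arch_spec` object.
#' @seealso [default_arch()], [summarize_arch()]
#' @export
arch_spec <- function(input_len, layers, input_channels = 1) {
  stopifnot(input_len >= 1, input_channels >= 1)
  kinds <- vapply(layers, function(l) l$kind, character(1))
  if (sum(kinds == "flatten") != 1) {
    abort("an arch_spec must contain exactly one flatten layer")
  }
  last <- layers[[length(layers)]]
  if (last$kind != "dense" || !identical(last$activation, "softmax")) {
    abort("the final layer must be a dense softmax classifier")
  }
  structure(list(input_len = as.integer(input_len),
                 input_channels = as.integer(input_channels),
                 layers = layers),
            class = "arch_spec")
}

#' The default four-block 1D-CNN architecture
#'
#' Four convolution/pool/dropout blocks on the raw 8000-sample
#' waveform, a flatten, then a 256-128-64 dense funnel into a 4-way
#' softmax. Filter counts double block-to-block (8, 16, 32, 64) while
#' kernel widths shrink (13, 11, 9, 7); every pool is width 3.
#'
#' The kernel and pool widths are derived constants: with valid
#' convolution (out = L - k + 1) and floor-division pooling
#' (out = floor(L / p)), they are the unique integer solutions to the
#' layer-output sequence 8000 -> 7988 -> 2662 -> 2652 -> 884 -> 876 ->
#' 292 -> 286 -> 95 (e.g. the first kernel solves 8000 - k + 1 = 7988,
#' so k = 13; each pool solves floor(L / p) with p = 3).
#'
#' @param input_len Input width in samples (default 8000, i.e. 2 s at
#'   4 kHz).
#' @param n_classes Output classes (default 4).
#' @param dropout_rate Dropout fraction applied after every block and
#'   dense layer (default 0.3).
#' @return An [arch_spec()].
#' @export
#' @examples
#' summarize_arch(default_arch())
default_arch <- function(input_len = 8000, n_classes = 4, dropout_rate = 0.3) {
  arch_spec(input_len, list(
    conv1d(8, 13), maxpool1d(3), dropout(dropout_rate),
    conv1d(16, 11), maxpool1d(3), dropout(dropout_rate),
    conv1d(32, 9), maxpool1d(3), dropout(dropout_rate),
    conv1d(64, 7), maxpool1d(3), dropout(dropout_rate),
    flatten(),
    dense(256), dropout(dropout_rate),
    dense(128), dropout(dropout_rate),
    dense(64), dropout(dropout_rate),
    dense(n_classes, activation = "softmax")
  ))
}

#' Valid-convolution output length
#'
#' @param L Input length.
#' @param k Kernel width (`1 <= k <= L`).
#' @return `L - k + 1`.
#' @export
#' @examples
#' conv_out_len(8000, 13)
conv_out_len <- function(L, k) {
  stopifnot(k >= 1)
  if (k > L) abort(sprintf("kernel width %d exceeds input length %d", k, L))
  L - k + 1L
}

#' Non-overlapping max-pool output length
#'
#' @param L Input length.
#' @param p Pool width (stride = width, no padding).
#' @return `floor(L / p)`.
#' @export
#' @examples
#' pool_out_len(7988, 3)
pool_out_len <- function(L, p) {
  stopifnot(p >= 1)
  L %/% p
}

#' Trainable parameter count of one layer
#'
#' Convolution: `kernel * in_channels * filters + filters`; dense:
#' `in_units * units + units`; pooling, dropout and flatten carry no
#' parameters.
#'
#' @param layer A [layer_spec] object.
#' @param n_in Input channels (conv) or input units (dense).
#' @return Integer parameter count.
#' @export
layer_params <- function(layer, n_in) {
  switch(layer$kind,
    conv1d = layer$kernel * n_in * layer$filters + layer$filters,
    dense = n_in * layer$units + layer$units,
    0L
  )
}

#' Layer-by-layer summary of an architecture
#'
#' Propagates (length, channels) through the network by pure
#' arithmetic — [conv_out_len()], [pool_out_len()], flatten =
#' length x channels — accumulating [layer_params()] per layer. No
#' learning framework is involved; this is the package's independent
#' account of the network's shapes and size.
#'
#' @param arch An [arch_spec()].
#' @return An `arch_summary`: tibble with `name`, `kind`, `out_len`,
#'   `out_channels`, `params` (the input row first), with attribute
#'   `total_params`.
#' @export
summarize_arch <- function(arch) {
  stopifnot(inherits(arch, "arch_spec"))
  len <- arch$input_len
  ch <- arch$input_channels
  flat <- FALSE
  counts <- integer(0)

  rows <- list(tibble(name = "input", kind = "input",
                      out_len = len, out_channels = ch, params = 0))
  for (li in seq_along(arch$layers)) {
    l <- arch$layers[[li]]
    n <- sum(vapply(arch$layers[seq_len(li)], function(z) z$kind == l$kind, logical(1)))
    name <- if (n == 1) l$kind else paste0(l$kind, "_", n - 1)
    p <- 0
    if (l$kind == "conv1d") {
      if (flat) abort(sprintf("conv1d after flatten at layer %d", li))
      if (l$kernel > len) {
        abort(sprintf("shape collapse at layer %d (%s): length %d < kernel %d",
                      li, name, len, l$kernel))
      }
      p <- layer_params(l, ch)
      len <- conv_out_len(len, l$kernel)
      ch <- l$filters
    } else if (l$kind == "maxpool1d") {
      len <- pool_out_len(len, l$pool)
      if (len < 1) abort(sprintf("shape collapse at layer %d (%s): pooled to zero", li, name))
    } else if (l$kind == "flatten") {
      len <- len * ch
      ch <- 1L
      flat <- TRUE
    } else if (l$kind == "dense") {
      if (!flat) abort(sprintf("dense before flatten at layer %d", li))
      p <- layer_params(l, len)
      len <- l$units
    }
    rows[[length(rows) + 1L]] <- tibble(name = name, kind = l$kind,
                                        out_len = len, out_channels = ch,
                                        params = p)
  }
  out <- dplyr::bind_rows(rows)
  structure(out, total_params = sum(out$params),
            class = c("arch_summary", class(out)))
}

#' @export
print.arch_summary <- function(x, ...) {
  df <- as.data.frame(x)
  post_flat <- cumsum(df$kind == "flatten") > 0
  shape <- ifelse(post_flat,
                  sprintf("(None, %d)", df$out_len),
                  sprintf("(None, %d, %d)", df$out_len, df$out_channels))
  cat(sprintf("%-14s %-18s %12s\n", "Layer", "Output Shape", "Param#"))
  for (i in seq_len(nrow(df))) {
    cat(sprintf("%-14s %-18s %12s\n", df$name[i], shape[i],
                format(df$params[i], big.mark = ",")))
  }
  cat(sprintf("Total params: %s\n",
              format(attr(x, "total_params"), big.mark = ",")))
  invisible(x)
}

#' @export
glance.arch_summary <- function(x, ...) {
  tibble(n_layers = nrow(x) - 1L,
         n_weight_layers = sum(x$params > 0),
         total_params = attr(x, "total_params"),
         flatten_width = x$out_len[x$kind == "flatten"][1])
}

#' Total trainable parameters of an architecture
#'
#' @param arch An [arch_spec()].
#' @return Integer total.
#' @export
total_params <- function(arch) attr(summarize_arch(arch), "total_params")
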