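#' Preprocessing configuration
#'
#' Parameters for turning raw annotated recordings into fixed-length,
#' model-ready cycle clips: resample to a common rate, cut cycles at the
#' annotation boundaries, truncate long cycles, then crop or pad every
#' clip to the model input length.
#'
#' The two length knobs are deliberately independent: cycles longer than
#' `cycle_truncation_s` (default 2.7 s, the mean cycle duration of the
#' ICBHI corpus) keep only their initial 2.7 s, and the model consumes
#' exactly `model_input_samples` samples (default 8000 = 2.0 s at
#' 4 kHz, the network's input width). Truncation is applied first, then
#' the crop/pad to the model width.
#'
#' @param target_rate Pipeline sampling rate in Hz (default 4000; the
#'   adventitious-sound band of interest lies below 2 kHz).
#' @param cycle_truncation_s Maximum retained cycle duration in seconds.
#' @param model_input_samples Exact model input length in samples.
#' @param pad_mode `"zero"` (default) or `"wrap"` padding for short
#'   clips.
#' @param event_window_ms Length-2 range of the short event-analysis
#'   window in milliseconds (default 20--25).
#' @param screening_enabled Run [validity_screen()] on adventitious
#'   clips during [prepare_dataset()] (default `FALSE`; intended for
#'   synthetic fixture QC).
#' @param screening_threshold Evidence-score threshold for screening.
#' @param split_fraction Training fraction for [split_train_test()]
#'   (default 0.7).
#' @param seed Integer seed for the stratified split.
#' @return A `preprocess_config` object (named list).
#' @export
preprocess_config <- function(target_rate = 4000,
                              cycle_truncation_s = 2.7,
                              model_input_samples = 8000,
                              pad_mode = c("zero", "wrap"),
                              event_window_ms = c(20, 25),
                              screening_enabled = FALSE,
                              screening_threshold = 1.0,
                              split_fraction = 0.7,
                              seed = 1L) {
  pad_mode <- match.arg(pad_mode)
  stopifnot(target_rate > 0, cycle_truncation_s > 0,
            model_input_samples >= 1,
            split_fraction > 0, split_fraction < 1,
            all(event_window_ms > 0))
  if (model_input_samples > ceiling(cycle_truncation_s * target_rate)) {
    abort("model_input_samples cannot exceed the truncated cycle length")
  }
  structure(list(
    target_rate = target_rate,
    cycle_truncation_s = cycle_truncation_s,
    model_input_samples = as.integer(model_input_samples),
    pad_mode = pad_mode,
    event_window_ms = event_window_ms,
    screening_enabled = isTRUE(screening_enabled),
    screening_threshold = screening_threshold,
    split_fraction = split_fraction,
    seed = as.integer(seed)
  ), class = "preprocess_config")
}

#' Resample a waveform to a new rate
#'
#' Fourier-domain resampling: the spectrum is truncated (ideal
#' anti-aliasing low-pass) or zero-extended to the new length, so
#' content below the destination Nyquist frequency is preserved
#' exactly for band-limited signals. The output length is exactly
#' `round(n * dst_rate / src_rate)`; equal rates return the input
#' unchanged.
#'
#' @param x Numeric waveform.
#' @param src_rate,dst_rate Source and destination rates in Hz.
#' @return Numeric vector of length `round(length(x) * dst_rate / src_rate)`.
#' @export
resample_wave <- function(x, src_rate, dst_rate) {
  stopifnot(src_rate > 0, dst_rate > 0)
  if (length(x) == 0) return(numeric(0))
  if (src_rate == dst_rate) return(x)
  n <- length(x)
  n_out <- round(n * dst_rate / src_rate)
  if (n_out < 1) return(numeric(0))

  X <- stats::fft(x)
  m <- n_out
  N <- min(n, m)
  nyq <- N %/% 2 + 1                  # DC .. highest kept positive bin
  Y <- complex(m)
  Y[1:nyq] <- X[1:nyq]
  nneg <- N - nyq                     # kept negative-frequency bins
  if (nneg > 0) Y[(m - nneg + 1):m] <- X[(n - nneg + 1):n]
  if (N %% 2 == 0) {
    if (m < n) {
      Y[nyq] <- Y[nyq] + X[n - N / 2 + 1]       # fold the mirrored Nyquist bin
    } else if (m > n) {
      Y[nyq] <- Y[nyq] / 2
      Y[m - N / 2 + 1] <- Conj(Y[nyq])
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Cut a recording into annotated cycle clips
#'
#' Clip *i* takes samples in the half-open interval
#' `[round(start_i * rate), round(end_i * rate))`. Annotations running
#' marginally past the end of the audio are clamped (with a warning);
#' annotations fully outside the audio are skipped (with a warning).
#'
#' @param waveform Numeric waveform.
#' @param rate Sampling rate in Hz.
#' @param annotations Tibble from [read_annotation()] (columns
#'   `start_s`, `end_s`, `crackle`, `wheeze`).
#' @return Tibble with one row per retained cycle: `cycle_index`,
#'   `start_s`, `end_s`, `crackle`, `wheeze`, `label`, `rate`,
#'   `duration_s`, `samples` list-column.
#' @export
extract_cycles <- function(waveform, rate, annotations) {
  n <- length(waveform)
  empty <- tibble(cycle_index = integer(), start_s = numeric(), end_s = numeric(),
                  crackle = logical(), wheeze = logical(),
                  label = factor(character(), levels = CLASS_LEVELS),
                  rate = numeric(), duration_s = numeric(), samples = list())
  if (nrow(annotations) == 0) return(empty)

  rows <- lapply(seq_len(nrow(annotations)), function(i) {
    a <- annotations[i, ]
    i0 <- round(a$start_s * rate)
    i1 <- round(a$end_s * rate)
    if (i0 >= n) {
      warn(sprintf("cycle %d (%.2f-%.2f s) lies outside the audio; skipped",
                   i, a$start_s, a$end_s))
      return(NULL)
    }
    if (i1 > n) {
      warn(sprintf("cycle %d end %.2f s past audio end; clamped", i, a$end_s))
      i1 <- n
    }
    seg <- waveform[(i0 + 1L):i1]
    tibble(cycle_index = i, start_s = a$start_s, end_s = a$end_s,
           crackle = a$crackle, wheeze = a$wheeze,
           label = label_of(a$crackle, a$wheeze),
           rate = rate, duration_s = length(seg) / rate,
           samples = list(seg))
  })
  out <- dplyr::bind_rows(Filter(Negate(is.null), rows))
  if (nrow(out) == 0) empty else out
}

#' Normalise a clip to the exact model input length
#'
#' First truncates the clip to `cycle_truncation_s` if longer, then
#' crops or pads (zero or wrap, per `pad_mode`) to exactly
#' `model_input_samples`. Deterministic.
#'
#' @param samples Numeric clip at the pipeline target rate.
#' @param cfg A [preprocess_config()].
#' @return Numeric vector of length `cfg$model_input_samples`.
#' @export
fix_length <- function(samples, cfg = preprocess_config()) {
  max_n <- round(cfg$cycle_truncation_s * cfg$target_rate)
  if (length(samples) > max_n) samples <- samples[seq_len(max_n)]
  L <- cfg$model_input_samples
  if (length(samples) >= L) return(samples[seq_len(L)])
  pad_n <- L - length(samples)
  pad <- switch(cfg$pad_mode,
    zero = numeric(pad_n),
    wrap = rep_len(samples, pad_n)
  )
  c(samples, pad)
}

#' Short event-analysis windows over a clip
#'
#' Slides a non-overlapping window of `window_ms` milliseconds over the
#' clip (sample width `round(window_ms * rate / 1000)`), returning each
#' window with its excess kurtosis — the transient-evidence statistic
#' used by [validity_screen()]. A window longer than the clip is clamped
#' to the whole clip with a warning.
#'
#' @param samples Numeric clip.
#' @param rate Sampling rate in Hz.
#' @param window_ms Window width in milliseconds (default 25).
#' @return Tibble with `window_index`, `start`, `end` (sample indices,
#'   1-based inclusive), `kurtosis` and a `samples` list-column.
#' @export
segment_events <- function(samples, rate, window_ms = 25) {
  stopifnot(window_ms > 0)
  w <- round(window_ms * rate / 1000)
  if (w > length(samples)) {
    warn("event window longer than clip; using a single clamped window")
    w <- length(samples)
  }
  n_win <- length(samples) %/% w
  starts <- (seq_len(n_win) - 1L) * w + 1L
  purrr::map_dfr(seq_len(n_win), function(i) {
    seg <- samples[starts[i]:(starts[i] + w - 1L)]
    tibble(window_index = i, start = starts[i], end = starts[i] + w - 1L,
           kurtosis = window_kurtosis(seg), samples = list(seg))
  })
}

window_kurtosis <- function(x) {
  if (sd(x) < .Machine$double.eps) return(0)
  e1071::kurtosis(x, type = 2)
}

#' Short-time Fourier magnitude spectrogram
#'
#' Hann-windowed STFT magnitudes (default 256-sample window, 50%
#' overlap). Frequency rows span `[0, rate/2]`.
#'
#' @param samples Numeric clip (must be at least one window long).
#' @param rate Sampling rate in Hz.
#' @param n_fft Window/FFT length in samples.
#' @param overlap Fractional window overlap in `[0, 1)`.
#' @return A `spectrogram` object: list with `magnitude`
#'   (frequency x time matrix), `freq` (Hz) and `time` (s).
#' @export
spectrogram <- function(samples, rate, n_fft = 256, overlap = 0.5) {
  if (length(samples) == 0) abort("cannot compute a spectrogram of an empty clip")
  if (length(samples) < n_fft) {
    abort(sprintf("clip (%d samples) shorter than one STFT window (%d)",
                  length(samples), n_fft))
  }
  sp <- signal::specgram(samples, n = n_fft, Fs = rate,
                         window = signal::hanning(n_fft),
                         overlap = floor(n_fft * overlap))
  structure(list(
    magnitude = abs(sp$S),
    freq = as.numeric(sp$f),
    time = as.numeric(sp$t)
  ), class = "spectrogram")
}

#' @export
autoplot.spectrogram <- function(object, ...) {
  df <- tidyr::expand_grid(time = object$time, freq = object$freq)
  df$power_db <- 20 * log10(as.vector(object$magnitude) + 1e-12)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$freq, fill = .data$power_db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "dB") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)")
}

#' Adventitious-evidence scores for a clip
#'
#' Two unitless scores quantifying the evidence a clip carries for each
#' adventitious sound type, both normalised so that 1.0 is the default
#' screening decision boundary:
#'
#' * `wheeze_score` — spectral-ridge persistence. Each spectrogram bin's
#'   power is compared with the local (frequency-neighbourhood) median
#'   of its frame; the score is the largest fraction of frames, over
#'   bins, in which a bin exceeds 6x its local median, divided by 0.3
#'   (a tone must persist in at least 30% of frames to score 1).
#' * `crackle_score` — maximum excess kurtosis over the short event
#'   windows of [segment_events()], divided by 5.
#'
#' @param samples Numeric clip.
#' @param rate Sampling rate in Hz.
#' @param window_ms Event window width (ms) for the kurtosis score.
#' @return Named numeric vector `c(wheeze_score, crackle_score)`.
#' @export
adventitious_scores <- function(samples, rate, window_ms = 25) {
  sp <- spectrogram(samples, rate)
  mag <- sp$magnitude
  power <- mag^2
  keep <- sp$freq >= 100 & sp$freq <= min(1900, rate / 2)
  power <- power[keep, , drop = FALSE]
  nf <- nrow(power)
  half_w <- 8L
  ratio <- matrix(0, nf, ncol(power))
  for (f in seq_len(nf)) {
    lo <- max(1L, f - half_w); hi <- min(nf, f + half_w)
    local_med <- apply(power[lo:hi, , drop = FALSE], 2, stats::median)
    ratio[f, ] <- power[f, ] / (local_med + 1e-20)
  }
  persistence <- apply(ratio > 6, 1, mean)
  wheeze_score <- max(persistence) / 0.3

  kmax <- max(segment_events(samples, rate, window_ms)$kurtosis)
  crackle_score <- kmax / 5

  c(wheeze_score = wheeze_score, crackle_score = crackle_score)
}

#' Screen an adventitious clip for spectral evidence of its label
#'
#' Automated stand-in for manual spectrogram review: a clip labelled
#' `crackle`, `wheeze` or `both` passes when its evidence score (from
#' [adventitious_scores()]; the minimum of the two scores for `both`)
#' reaches `threshold`. Normal clips bypass screening and always pass.
#' Raising the threshold can only reject more clips (monotone).
#'
#' @param samples Numeric clip.
#' @param rate Sampling rate in Hz.
#' @param label Class label of the clip.
#' @param threshold Evidence-score threshold (default 1.0; 0 accepts
#'   everything).
#' @return List with `valid` (logical) and `scores` (the evidence
#'   scores).
#' @export
validity_screen <- function(samples, rate, label, threshold = 1.0) {
  label <- as.character(label)
  scores <- adventitious_scores(samples, rate)
  score <- switch(label,
    normal = Inf,
    wheeze = scores[["wheeze_score"]],
    crackle = scores[["crackle_score"]],
    both = min(scores),
    abort(paste0("unknown class label: ", label))
  )
  list(valid = score >= threshold, scores = scores, score = score)
}

#' Assemble model-ready inputs from a clip table
#'
#' Resamples every clip to the target rate, optionally screens
#' adventitious clips, length-normalises with [fix_length()],
#' peak-normalises each row to `[-1, 1]`, and stacks the result into a
#' [dataset_matrix()].
#'
#' @param clips Clip tibble ([synth_dataset()], [read_icbhi_dataset()]
#'   or [extract_cycles()] output).
#' @param cfg A [preprocess_config()].
#' @return A [dataset_matrix()] with one row per retained clip.
#' @export
prepare_dataset <- function(clips, cfg = preprocess_config()) {
  stopifnot(nrow(clips) > 0)
  keep <- rep(TRUE, nrow(clips))
  rows <- vector("list", nrow(clips))
  for (i in seq_len(nrow(clips))) {
    x <- resample_wave(clips$samples[[i]], clips$rate[i], cfg$target_rate)
    lab <- as.character(clips$label[i])
    if (cfg$screening_enabled && lab != "normal") {
      scr <- validity_screen(x, cfg$target_rate, lab, cfg$screening_threshold)
      if (!scr$valid) {
        keep[i] <- FALSE
        warn(sprintf("clip %d (%s) failed validity screening (score %.2f); discarded",
                     i, lab, scr$score))
        next
      }
    }
    x <- fix_length(x, cfg)
    peak <- max(abs(x))
    if (peak > 0) x <- x / peak
    rows[[i]] <- x
  }
  clips <- clips[keep, ]
  X <- do.call(rbind, rows[keep])
  prov <- tibble(
    file_stem = if ("file_stem" %in% names(clips)) clips$file_stem else NA_character_,
    cycle_index = if ("cycle_index" %in% names(clips)) clips$cycle_index else seq_len(nrow(clips)),
    synthetic = FALSE
  )
  dataset_matrix(X, clips$label, provenance = prov)
}

#' Model-ready dataset container
#'
#' A fixed-width sample matrix with aligned labels and provenance: `X`
#' is N x L (one length-normalised clip per row), `y` a factor over
#' [class_levels()], `provenance` a tibble with one row per clip
#' (including a `synthetic` flag set by [smote_balance()]).
#'
#' @param X Numeric matrix, one clip per row.
#' @param y Class labels (length `nrow(X)`).
#' @param provenance Optional provenance tibble (`nrow(X)` rows).
#' @return A `dataset_matrix` object.
#' @export
dataset_matrix <- function(X, y, provenance = NULL) {
  X <- as.matrix(X)
  y <- as_class_factor(y)
  stopifnot(nrow(X) == length(y))
  if (is.null(provenance)) {
    provenance <- tibble(file_stem = NA_character_,
                         cycle_index = seq_len(nrow(X)),
                         synthetic = FALSE)
    provenance <- provenance[seq_len(nrow(X)), ]
  }
  stopifnot(nrow(provenance) == nrow(X))
  structure(list(X = X, y = y, provenance = as_tibble(provenance)),
            class = "dataset_matrix")
}

#' @export
print.dataset_matrix <- function(x, ...) {
  cat(sprintf("dataset_matrix: %d clips x %d samples\n", nrow(x$X), ncol(x$X)))
  tab <- table(x$y)
  cat("  classes: ", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  if (any(x$provenance$synthetic)) {
    cat("  synthetic rows:", sum(x$provenance$synthetic), "\n")
  }
  invisible(x)
}

#' @export
dim.dataset_matrix <- function(x) dim(x$X)

# row subset preserving alignment
dm_subset <- function(dm, idx) {
  dataset_matrix(dm$X[idx, , drop = FALSE], dm$y[idx], dm$provenance[idx, ])
}

#' Stratified train/test split
#'
#' Splits a [dataset_matrix()] into disjoint training and testing
#' partitions, sampling `round(split_fraction * n)` clips per class
#' (so class proportions are preserved to within one clip). Seeded and
#' deterministic.
#'
#' @param dataset A [dataset_matrix()].
#' @param cfg A [preprocess_config()] (uses `split_fraction` and `seed`).
#' @return List with `train` and `test` [dataset_matrix()] objects.
#' @export
split_train_test <- function(dataset, cfg = preprocess_config()) {
  y <- dataset$y
  tab <- table(y)
  small <- names(tab)[tab < 2 & tab > 0]
  if (length(small) > 0) {
    abort(paste0("cannot stratify: class(es) with fewer than 2 samples: ",
                 paste(small, collapse = ", ")))
  }
  train_idx <- integer(0)
  with_local_seed(cfg$seed, {
    for (cl in names(tab)[tab > 0]) {
      idx <- which(y == cl)
      n_train <- round(cfg$split_fraction * length(idx))
      n_train <- min(max(n_train, 1L), length(idx) - 1L)
      train_idx <- c(train_idx, sort(sample(idx, n_train)))
    }
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(y), train_idx)
  list(train = dm_subset(dataset, train_idx),
       test = dm_subset(dataset, test_idx))
}

# evaluate expr under a temporary RNG seed, restoring the caller's stream
with_local_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}
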