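test_that("resampling preserves band-limited content and length arithmetic", {
  x <- rnorm(1000)
  expect_identical(resample_wave(x, 4000, 4000), x)      # identity
  expect_length(resample_wave(rnorm(44100), 44100, 4000), 4000)
  expect_length(resample_wave(numeric(0), 44100, 4000), 0)

  # 500 Hz sine survives 44.1 kHz -> 4 kHz resampling nearly unchanged
  t44 <- (0:44099) / 44100
  y <- resample_wave(sin(2 * pi * 500 * t44), 44100, 4000)
  ref <- sin(2 * pi * 500 * (0:3999) / 4000)
  core <- 101:3900                                        # ignore filter edges
  expect_gt(stats::cor(y[core], ref[core]), 0.99)
})

test_that("down-up resampling round-trips band-limited signals", {
  t <- (0:7999) / 8000
  x <- sin(2 * pi * 300 * t) + 0.5 * sin(2 * pi * 700 * t)
  back <- resample_wave(resample_wave(x, 8000, 4000), 4000, 8000)
  core <- 201:7800
  expect_gt(stats::cor(x[core], back[core]), 0.99)
})

test_that("cycle extraction follows half-open sample intervals", {
  wav <- rnorm(40000)  # 10 s at 4 kHz
  ann <- tibble::tibble(start_s = 2.0, end_s = 4.5, crackle = TRUE, wheeze = FALSE)
  clips <- extract_cycles(wav, 4000, ann)
  expect_equal(length(clips$samples[[1]]), 10000)
  expect_equal(clips$samples[[1]], wav[8001:18000])
  expect_equal(as.character(clips$label), "crackle")

  expect_equal(nrow(extract_cycles(wav, 4000, tibble::tibble(
    start_s = numeric(), end_s = numeric(), crackle = logical(), wheeze = logical()))), 0)

  # marginal overrun clamps, full overrun skips
  ann2 <- tibble::tibble(start_s = c(9.5, 11), end_s = c(10.5, 12),
                         crackle = FALSE, wheeze = FALSE)
  expect_warning(expect_warning(clips2 <- extract_cycles(wav, 4000, ann2),
                                "clamped"), "skipped")
  expect_equal(nrow(clips2), 1)
  expect_equal(length(clips2$samples[[1]]), 2000)
})

test_that("fix_length truncates then pads to the exact model width", {
  cfg <- preprocess_config()
  long <- rnorm(64000)                                    # 16 s at 4 kHz
  out <- fix_length(long, cfg)
  expect_length(out, 8000)
  expect_equal(out, long[1:8000])                         # truncation keeps the start

  exact <- rnorm(8000)
  expect_identical(fix_length(exact, cfg), exact)

  short <- rnorm(5000)
  padded <- fix_length(short, cfg)
  expect_length(padded, 8000)
  expect_equal(padded[5001:8000], numeric(3000))          # zero pad

  wrap_cfg <- preprocess_config(pad_mode = "wrap")
  wrapped <- fix_length(short, wrap_cfg)
  expect_equal(wrapped[5001:8000], short[1:3000])

  # truncation cap applies before the crop: 12 s clip at 2.7 s cap
  cap_cfg <- preprocess_config(cycle_truncation_s = 1.5, model_input_samples = 6000)
  expect_equal(fix_length(rnorm(48000) -> z, cap_cfg)[1:6000],
               fix_length(z[1:6000], cap_cfg))
})

test_that("event segmentation yields the expected window grid and statistics", {
  clip <- rnorm(8000)
  win25 <- segment_events(clip, 4000, 25)
  expect_equal(nrow(win25), 80)                           # 8000 / 100
  expect_true(all(lengths(win25$samples) == 100))
  win20 <- segment_events(clip, 4000, 20)
  expect_equal(lengths(win20$samples)[1], 80)             # 20 ms at 4 kHz

  expect_warning(one <- segment_events(rnorm(50), 4000, 25), "clamped")
  expect_equal(nrow(one), 1)

  set.seed(8)
  crackle <- synth_cycle("crackle", synth_config())
  set.seed(8)
  normal <- synth_cycle("normal", synth_config())
  expect_gt(max(segment_events(crackle$samples, 4000)$kurtosis),
            max(segment_events(normal$samples, 4000)$kurtosis))
})

test_that("spectrograms localise tones and reject degenerate input", {
  t <- (0:7999) / 4000
  sp <- spectrogram(sin(2 * pi * 500 * t), 4000)
  peak_bin <- which.max(rowMeans(sp$magnitude))
  expect_lt(abs(sp$freq[peak_bin] - 500), 4000 / 256 + 1e-9)

  spz <- spectrogram(numeric(1000), 4000)
  expect_true(all(spz$magnitude == 0))

  expect_error(spectrogram(numeric(0), 4000), "empty")
  expect_error(spectrogram(rnorm(100), 4000), "shorter than one STFT window")

  # a synthetic wheeze shows a persistent ridge at its tone frequency
  set.seed(11)
  wheeze <- synth_cycle("wheeze", synth_config(wheeze_params = list(tone_fraction = c(0.5, 0.5))))
  spw <- spectrogram(wheeze$samples, 4000)
  power <- spw$magnitude^2
  band <- spw$freq >= 100 & spw$freq <= 1900
  ridge_bin <- which.max(rowMeans(power[band, ]))
  frame_med <- apply(power[band, ], 2, stats::median)
  persist <- mean(power[band, ][ridge_bin, ] > 6 * frame_med)
  expect_gte(persist, 0.3)
})

test_that("validity screening accepts true events, rejects impostors, and is monotone", {
  set.seed(12)
  wheeze <- synth_cycle("wheeze", synth_config())
  set.seed(12)
  normal <- synth_cycle("normal", synth_config())

  expect_true(validity_screen(wheeze$samples, 4000, "wheeze")$valid)
  expect_false(validity_screen(normal$samples, 4000, "wheeze", threshold = 1)$valid)
  expect_true(validity_screen(normal$samples, 4000, "normal")$valid)    # bypass
  expect_true(validity_screen(normal$samples, 4000, "wheeze", threshold = 0)$valid)

  # monotonicity: raising the threshold never admits a rejected clip
  set.seed(13)
  clips <- replicate(6, synth_cycle(sample(class_levels()[-1], 1), synth_config()),
                     simplify = FALSE)
  for (th in list(c(0.5, 1), c(1, 2))) {
    for (cl in clips) {
      lo <- validity_screen(cl$samples, cl$rate, cl$label, th[1])$valid
      hi <- validity_screen(cl$samples, cl$rate, cl$label, th[2])$valid
      expect_true(lo || !hi)
    }
  }
})

test_that("prepared datasets have uniform width, preserved labels and unit peaks", {
  expect_equal(dim(tiny_dm), c(20L, 8000L))
  expect_equal(as.character(tiny_dm$y), as.character(tiny_clips$label))
  expect_true(all(abs(tiny_dm$X) <= 1))
  expect_true(all(apply(abs(tiny_dm$X), 1, max) > 0.99))
})

test_that("stratified split honours per-class 70% counts and partitions the data", {
  dm <- random_dm(n_per_class = 10, len = 16, seed = 2)
  # rebuild with imbalanced counts 40/30/20/10
  set.seed(2)
  X <- matrix(rnorm(100 * 16), 100)
  y <- rep(class_levels(), times = c(40, 30, 20, 10))
  dmi <- dataset_matrix(X, y)
  cfg <- preprocess_config(seed = 0)
  parts <- split_train_test(dmi, cfg)
  expect_equal(as.integer(table(parts$train$y)), c(28L, 21L, 14L, 7L))
  expect_equal(nrow(parts$train$X) + nrow(parts$test$X), 100)

  # disjoint and exhaustive on the underlying rows
  key <- function(m) apply(m, 1, function(r) paste(signif(r, 12), collapse = ","))
  expect_length(intersect(key(parts$train$X), key(parts$test$X)), 0)
  expect_setequal(c(key(parts$train$X), key(parts$test$X)), key(X))

  # determinism
  parts2 <- split_train_test(dmi, cfg)
  expect_identical(parts$train$X, parts2$train$X)

  y_bad <- c(rep("normal", 5), "crackle")
  expect_error(split_train_test(dataset_matrix(matrix(rnorm(6 * 4), 6), y_bad),
                                cfg), "crackle")
})
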