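test_that("synthesised cycles are bounded, mono, and at the configured rate", {
  cfg <- synth_config()
  set.seed(1)
  for (lab in class_levels()) {
    clip <- synth_cycle(lab, cfg)
    expect_true(all(clip$samples >= -1 & clip$samples <= 1))
    expect_equal(clip$rate, cfg$sample_rate)
    dur <- length(clip$samples) / clip$rate
    expect_gte(dur, cfg$cycle_duration_s[1] - 1e-9)
    expect_lte(dur, cfg$cycle_duration_s[2] + 1e-9)
  }
  expect_error(synth_cycle("cough", cfg), "unknown class label")
})

test_that("wheeze cycles carry a narrowband peak that normal cycles lack", {
  cfg <- synth_config()
  set.seed(1)
  wheeze <- synth_cycle("wheeze", cfg)
  set.seed(1)
  normal <- synth_cycle("normal", cfg)

  welch <- function(x, rate) {
    sp <- spectrogram(x, rate)
    rowMeans(sp$magnitude^2)
  }
  pw <- welch(wheeze$samples, cfg$sample_rate)
  pn <- welch(normal$samples, cfg$sample_rate)
  freqs <- spectrogram(wheeze$samples, cfg$sample_rate)$freq
  band <- freqs >= 100
  ratio <- function(p) max(p[band]) / stats::median(p[band])
  expect_gt(ratio(pw), ratio(pn))

  # the dominant peak sits inside the configured tone range
  peak_hz <- freqs[band][which.max(pw[band])]
  expect_gte(peak_hz, cfg$wheeze_params$tone_freq_hz[1] - 20)
  expect_lte(peak_hz, 2 * cfg$wheeze_params$tone_freq_hz[2] + 20)  # may be a harmonic
})

test_that("crackle cycles contain damped transients; zero-burst request degrades to normal statistics", {
  cfg <- synth_config()
  set.seed(2)
  crackle <- synth_cycle("crackle", cfg)
  set.seed(2)
  normal <- synth_cycle("normal", cfg)
  kmax <- function(clip) max(segment_events(clip$samples, clip$rate)$kurtosis)
  expect_gt(kmax(crackle), kmax(normal))

  cfg0 <- synth_config(crackle_params = list(bursts_per_cycle = c(0L, 0L)))
  set.seed(3)
  empty <- synth_cycle("crackle", cfg0)
  expect_lt(max(segment_events(empty$samples, empty$rate)$kurtosis), 5)
})

test_that("synth_dataset is deterministic and honours per-class counts", {
  cfg <- synth_config(n_per_class = 5, seed = 7)
  ds1 <- synth_dataset(cfg)
  ds2 <- synth_dataset(cfg)
  expect_equal(nrow(ds1), 20)
  expect_equal(as.integer(table(ds1$label)), rep(5L, 4))
  expect_identical(ds1$samples, ds2$samples)

  imb <- synth_dataset(synth_config(n_per_class = c(10, 5, 3, 2), seed = 7))
  expect_equal(as.integer(table(imb$label)), c(10L, 5L, 3L, 2L))

  empty <- synth_dataset(synth_config(n_per_class = 0, seed = 1))
  expect_equal(nrow(empty), 0)
})

test_that("fixtures round-trip through the ICBHI readers at label and sample level", {
  cfg <- synth_config(n_per_class = 1, cycle_duration_s = c(1, 2), seed = 9)
  ds <- synth_dataset(cfg)
  td <- withr::local_tempdir()
  man <- write_icbhi_fixture(ds, td)
  expect_equal(nrow(man), 4)
  expect_true(all(file.exists(man$wav)) && all(file.exists(man$txt)))

  # flag encoding: the "both" row carries 1 1
  both_stem <- ds$file_stem[ds$label == "both"]
  row <- readLines(file.path(td, paste0(both_stem, ".txt")))
  expect_match(row, "1\t1$")

  back <- read_icbhi_dataset(td)
  back <- back[match(ds$file_stem, back$file_stem), ]
  expect_equal(as.character(back$label), as.character(ds$label))
  for (i in seq_len(nrow(ds))) {
    expect_equal(length(back$samples[[i]]), length(ds$samples[[i]]))
    expect_gt(stats::cor(back$samples[[i]], ds$samples[[i]]), 0.999)
  }

  # empty dataset produces an empty manifest and no files
  td2 <- withr::local_tempdir()
  man0 <- write_icbhi_fixture(synth_dataset(synth_config(n_per_class = 0)), td2)
  expect_equal(nrow(man0), 0)
  expect_length(list.files(td2), 0)
})

test_that("multi-cycle recordings keep per-cycle annotations aligned", {
  cfg <- synth_config(n_per_class = 2, cycles_per_recording = 4,
                      cycle_duration_s = c(1, 1.5), seed = 13)
  ds <- synth_dataset(cfg)
  expect_equal(length(unique(ds$file_stem)), 2)
  td <- withr::local_tempdir()
  write_icbhi_fixture(ds, td)
  cen <- census(td)
  expect_equal(cen$n_recordings, 2)
  expect_equal(cen$n_cycles, 8)
  expect_equal(as.integer(cen$per_class), rep(2L, 4))
})

test_that("a band-energy-plus-kurtosis rule separates the four classes", {
  ds <- synth_dataset(synth_config(n_per_class = 10, seed = 42))
  scores <- t(vapply(seq_len(nrow(ds)), function(i) {
    adventitious_scores(ds$samples[[i]], ds$rate[i])
  }, numeric(2)))
  pred <- ifelse(scores[, 1] >= 1 & scores[, 2] >= 1, "both",
          ifelse(scores[, 1] >= 1, "wheeze",
          ifelse(scores[, 2] >= 1, "crackle", "normal")))
  expect_gte(mean(pred == as.character(ds$label)), 0.9)
})
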