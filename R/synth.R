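#' Configuration for the synthetic lung-sound generator
#'
#' Builds the parameter set controlling [synth_cycle()] and
#' [synth_dataset()]. The generator emulates the four respiratory-cycle
#' classes used throughout the package: `normal` is smooth band-limited
#' breath noise shaped by a raised-cosine inspiration/expiration
#' envelope; `crackle` superimposes brief exponentially damped sinusoid
#' bursts; `wheeze` superimposes a sustained narrowband tone with weak
#' frequency modulation and a small harmonic stack; `both` carries both
#' event types.
#'
#' All frequency parameters must stay below the Nyquist frequency, and
#' crackle centre frequencies are kept below 2 kHz so the events live in
#' the band a 4 kHz pipeline retains.
#'
#' @param sample_rate Sampling rate in Hz (default 4000).
#' @param cycle_duration_s Length-2 numeric, min/max cycle duration in
#'   seconds; each cycle draws its duration uniformly from this range.
#' @param n_per_class Cycles per class for [synth_dataset()]; either a
#'   single count or a length-4 vector ordered as [class_levels()] for an
#'   imbalanced set.
#' @param noise_floor_db Level of the white background noise relative to
#'   the breath-noise RMS, in dB (negative).
#' @param crackle_params List with `bursts_per_cycle` (length-2 integer
#'   range), `burst_duration_ms` (range, default 5--15 ms),
#'   `center_freq_hz` (range, default 200--1800 Hz), `damping` (number of
#'   exponential time constants spanned by one burst) and `gain` (burst
#'   amplitude relative to breath RMS).
#' @param wheeze_params List with `tone_freq_hz` (range, default
#'   150--900 Hz), `tone_fraction` (range of cycle fraction covered by
#'   the tone, minimum 0.3), `harmonics` (count), `fm_depth_hz`
#'   (frequency-modulation depth) and `gain` (tone amplitude relative to
#'   breath RMS).
#' @param breath_envelope List with `inspiration` and `expiration`
#'   fractions of the cycle (must sum to at most 1).
#' @param cycles_per_recording Cycles concatenated into one simulated
#'   recording when writing fixtures (default 1).
#' @param seed Integer seed used by [synth_dataset()].
#' @return An object of class `synth_config` (a named list).
#' @export
#' @examples
#' cfg <- synth_config(n_per_class = 5, seed = 1)
#' cfg$sample_rate
synth_config <- function(sample_rate = 4000,
                         cycle_duration_s = c(1.0, 4.0),
                         n_per_class = 10,
                         noise_floor_db = -30,
                         crackle_params = list(),
                         wheeze_params = list(),
                         breath_envelope = list(inspiration = 0.4, expiration = 0.55),
                         cycles_per_recording = 1,
                         seed = 1L) {
  crackle <- modifyList(list(
    bursts_per_cycle = c(5L, 10L),
    burst_duration_ms = c(5, 15),
    center_freq_hz = c(200, 1800),
    damping = 5,
    gain = 6
  ), crackle_params)
  wheeze <- modifyList(list(
    tone_freq_hz = c(150, 900),
    tone_fraction = c(0.45, 0.8),
    harmonics = 2L,
    fm_depth_hz = 6,
    gain = 4
  ), wheeze_params)

  stopifnot(
    sample_rate > 0,
    length(cycle_duration_s) == 2, all(cycle_duration_s > 0),
    cycle_duration_s[1] <= cycle_duration_s[2],
    all(n_per_class >= 0), length(n_per_class) %in% c(1L, 4L),
    noise_floor_db <= 0,
    cycles_per_recording >= 1
  )
  nyquist <- sample_rate / 2
  if (max(crackle$center_freq_hz) >= min(2000, nyquist)) {
    abort("crackle centre frequencies must stay below 2 kHz and below Nyquist")
  }
  if (max(wheeze$tone_freq_hz) >= nyquist) {
    abort("wheeze tone frequencies must stay below Nyquist")
  }
  if (min(wheeze$tone_fraction) < 0.3) {
    abort("wheeze tone must cover at least 0.3 of the cycle")
  }
  if (breath_envelope$inspiration + breath_envelope$expiration > 1 + 1e-9) {
    abort("inspiration + expiration fractions cannot exceed 1")
  }

  structure(list(
    sample_rate = sample_rate,
    cycle_duration_s = cycle_duration_s,
    n_per_class = n_per_class,
    noise_floor_db = noise_floor_db,
    crackle_params = crackle,
    wheeze_params = wheeze,
    breath_envelope = breath_envelope,
    cycles_per_recording = as.integer(cycles_per_recording),
    seed = as.integer(seed)
  ), class = "synth_config")
}

# raised-cosine inspiration/expiration breath envelope on [0, 1)
breath_envelope_curve <- function(n, insp, expi) {
  t <- seq(0, 1, length.out = n)
  env <- numeric(n)
  in_insp <- t < insp
  env[in_insp] <- sin(pi * t[in_insp] / insp)^2
  in_exp <- t >= insp & t < insp + expi
  env[in_exp] <- 0.8 * sin(pi * (t[in_exp] - insp) / expi)^2
  env + 0.02
}

# band-limited breath noise: white noise through a low-pass butterworth
breath_noise <- function(n, rate, cutoff_hz = 500) {
  x <- rnorm(n + 200)
  bf <- signal::butter(4, min(cutoff_hz / (rate / 2), 0.99), type = "low")
  y <- signal::filtfilt(bf, x)
  y[101:(n + 100)]
}

runif_range <- function(r) if (r[1] == r[2]) r[1] else runif(1, r[1], r[2])

# one exponentially damped sinusoid burst, length in samples
crackle_burst <- function(n, rate, fc, damping) {
  t <- seq_len(n) / rate
  tau <- (n / rate) / damping
  sin(2 * pi * fc * t + runif(1, 0, 2 * pi)) * exp(-t / tau)
}

#' Synthesise one annotated respiratory cycle
#'
#' Draws one cycle of the requested class from the current RNG stream
#' (seed it with `set.seed()` for reproducibility; [synth_dataset()]
#' does this for you). The returned waveform is mono, peak-normalised to
#' 0.9, and bounded in `[-1, 1]`.
#'
#' Setting `bursts_per_cycle` to `c(0, 0)` is permitted as a degenerate
#' boundary: a "crackle" cycle then contains no transient events and is
#' statistically indistinguishable from a normal cycle (and will fail
#' [validity_screen()]).
#'
#' @param label One of `"normal"`, `"crackle"`, `"wheeze"`, `"both"`.
#' @param cfg A [synth_config()].
#' @return A `cycle_clip`: list with `samples`, `rate`, `label`,
#'   `crackle`/`wheeze` flags and `duration_s`.
#' @export
#' @examples
#' set.seed(1)
#' clip <- synth_cycle("wheeze", synth_config())
#' range(clip$samples)
synth_cycle <- function(label, cfg = synth_config()) {
  if (!is.character(label) || length(label) != 1 || !label %in% CLASS_LEVELS) {
    abort(paste0("unknown class label: ", paste(label, collapse = ",")))
  }
  rate <- cfg$sample_rate
  dur <- runif_range(cfg$cycle_duration_s)
  n <- max(round(dur * rate), 32L)

  env <- breath_envelope_curve(n, cfg$breath_envelope$inspiration,
                               cfg$breath_envelope$expiration)
  base <- breath_noise(n, rate) * env
  rms <- sqrt(mean(base^2))
  x <- base + rnorm(n) * rms * 10^(cfg$noise_floor_db / 20)

  if (label %in% c("wheeze", "both")) {
    wp <- cfg$wheeze_params
    f0 <- runif_range(wp$tone_freq_hz)
    frac <- runif_range(wp$tone_fraction)
    len <- max(round(frac * n), 16L)
    start <- sample.int(n - len + 1L, 1L)
    t <- seq_len(len) / rate
    inst <- f0 + wp$fm_depth_hz * sin(2 * pi * 4 * t + runif(1, 0, 2 * pi))
    phase <- 2 * pi * cumsum(inst) / rate
    tone <- sin(phase)
    h <- 1L
    while (h < wp$harmonics && (h + 1) * (f0 + wp$fm_depth_hz) < 0.95 * rate / 2) {
      h <- h + 1L
      tone <- tone + sin(h * phase + runif(1, 0, 2 * pi)) / h
    }
    tone <- tone * sin(pi * seq_len(len) / (len + 1))^2   # raised-cosine onset/offset
    x[start:(start + len - 1L)] <- x[start:(start + len - 1L)] +
      tone * rms * wp$gain
  }

  if (label %in% c("crackle", "both")) {
    cp <- cfg$crackle_params
    lo <- as.integer(cp$bursts_per_cycle[1]); hi <- as.integer(cp$bursts_per_cycle[2])
    n_bursts <- if (hi <= lo) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
    if (n_bursts > 0) {
      for (b in seq_len(n_bursts)) {
        bd <- runif_range(cp$burst_duration_ms) / 1000
        bn <- max(round(bd * rate), 8L)
        if (bn >= n) bn <- n %/% 2
        fc <- runif_range(cp$center_freq_hz)
        pos <- sample.int(n - bn + 1L, 1L)
        burst <- crackle_burst(bn, rate, fc, cp$damping) *
          rms * cp$gain * runif(1, 0.7, 1.3)
        x[pos:(pos + bn - 1L)] <- x[pos:(pos + bn - 1L)] + burst
      }
    }
  }

  x <- 0.9 * x / max(abs(x))
  structure(list(
    samples = x,
    rate = rate,
    label = label,
    crackle = label %in% c("crackle", "both"),
    wheeze = label %in% c("wheeze", "both"),
    duration_s = n / rate
  ), class = "cycle_clip")
}

#' Synthesise an annotated dataset of respiratory cycles
#'
#' Generates `n_per_class` cycles for each of the four classes (or an
#' imbalanced composition when `n_per_class` has length 4), assigning
#' cycles to simulated recordings with ICBHI-style file stems. The whole
#' dataset is a deterministic function of `cfg` (including `cfg$seed`).
#'
#' @param cfg A [synth_config()].
#' @return A tibble with one row per cycle: `file_stem`, `cycle_index`,
#'   `start_s`, `end_s`, `crackle`, `wheeze`, `label`, `rate`,
#'   `duration_s` and a `samples` list-column.
#' @export
#' @examples
#' ds <- synth_dataset(synth_config(n_per_class = 2, seed = 7))
#' dplyr::count(ds, label)
synth_dataset <- function(cfg = synth_config()) {
  n_per <- cfg$n_per_class
  if (length(n_per) == 1) n_per <- rep(n_per, 4)
  n_per <- as.integer(n_per)
  labels <- rep(CLASS_LEVELS, times = n_per)
  if (length(labels) == 0) {
    return(tibble(
      file_stem = character(), cycle_index = integer(),
      start_s = numeric(), end_s = numeric(),
      crackle = logical(), wheeze = logical(),
      label = factor(character(), levels = CLASS_LEVELS),
      rate = numeric(), duration_s = numeric(), samples = list()
    ))
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  clips <- lapply(labels, synth_cycle, cfg = cfg)

  per_rec <- cfg$cycles_per_recording
  n_clip <- length(clips)
  rec_of <- (seq_len(n_clip) - 1L) %/% per_rec
  locations <- c("Al", "Ar", "Pl", "Pr", "Tc")

  rows <- vector("list", n_clip)
  t_cursor <- 0
  for (i in seq_len(n_clip)) {
    cl <- clips[[i]]
    idx_in_rec <- (i - 1L) %% per_rec + 1L
    if (idx_in_rec == 1L) t_cursor <- 0
    meta <- recording_meta(
      patient_id = sprintf("%d", 101L + rec_of[i]),
      recording_index = "1b1",
      chest_location = locations[rec_of[i] %% length(locations) + 1L],
      acquisition_mode = "sc",
      equipment = "Synth"
    )
    rows[[i]] <- tibble(
      file_stem = format_filename(meta),
      cycle_index = idx_in_rec,
      start_s = t_cursor,
      end_s = t_cursor + cl$duration_s,
      crackle = cl$crackle,
      wheeze = cl$wheeze,
      label = factor(cl$label, levels = CLASS_LEVELS),
      rate = cl$rate,
      duration_s = cl$duration_s,
      samples = list(cl$samples)
    )
    t_cursor <- t_cursor + cl$duration_s
  }
  dplyr::bind_rows(rows)
}

#' Write a synthetic dataset as ICBHI-layout fixtures
#'
#' Writes one 16-bit PCM WAV per simulated recording (cycles of a
#' recording concatenated in order) and a same-stem `.txt` annotation
#' file whose rows carry `start end crackle wheeze`. The layout
#' round-trips through [read_annotation()], [read_wav()] and [census()].
#'
#' @param dataset A tibble from [synth_dataset()].
#' @param out_dir Output directory (created if missing).
#' @return A manifest tibble with one row per recording: `file_stem`,
#'   `wav`, `txt`, `n_cycles`.
#' @export
write_icbhi_fixture <- function(dataset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(paste0("cannot create output directory: ", out_dir))
  if (nrow(dataset) == 0) {
    return(tibble(file_stem = character(), wav = character(),
                  txt = character(), n_cycles = integer()))
  }
  stems <- unique(dataset$file_stem)
  rows <- lapply(stems, function(stem) {
    d <- dataset[dataset$file_stem == stem, ]
    d <- d[order(d$cycle_index), ]
    wav_path <- file.path(out_dir, paste0(stem, ".wav"))
    txt_path <- file.path(out_dir, paste0(stem, ".txt"))
    write_wav(unlist(d$samples), d$rate[1], wav_path)
    writeLines(sprintf("%.4f\t%.4f\t%d\t%d",
                       d$start_s, d$end_s,
                       as.integer(d$crackle), as.integer(d$wheeze)),
               txt_path)
    tibble(file_stem = stem, wav = wav_path, txt = txt_path,
           n_cycles = nrow(d))
  })
  dplyr::bind_rows(rows)
}
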