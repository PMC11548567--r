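#' Recording metadata from an ICBHI-style file stem
#'
#' ICBHI 2017 file stems encode five underscore-separated fields:
#' `patientID_recordingIndex_chestLocation_acquisitionMode_equipment`
#' (for example `101_1b1_Al_sc_Meditron`). [parse_filename()] splits a
#' stem (or path; directory and extension are dropped) into those
#' fields; [format_filename()] is its inverse; [recording_meta()]
#' constructs the record directly.
#'
#' @param name File name, path or bare stem.
#' @return A `recording_meta` object: named list with `patient_id`,
#'   `recording_index`, `chest_location`, `acquisition_mode`,
#'   `equipment`.
#' @export
#' @examples
#' m <- parse_filename("101_1b1_Al_sc_Meditron.wav")
#' m$patient_id
#' format_filename(m)
parse_filename <- function(name) {
  stem <- sub("\\.[A-Za-z0-9]+$", "", basename(name))
  parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
  if (length(parts) != 5 || any(parts == "")) {
    abort(paste0("cannot parse ICBHI file stem (need 5 underscore-separated fields): ",
                 name))
  }
  recording_meta(parts[1], parts[2], parts[3], parts[4], parts[5])
}

#' @rdname parse_filename
#' @param patient_id,recording_index,chest_location,acquisition_mode,equipment
#'   Character fields of the stem, in order.
#' @export
recording_meta <- function(patient_id, recording_index, chest_location,
                           acquisition_mode, equipment) {
  structure(list(
    patient_id = as.character(patient_id),
    recording_index = as.character(recording_index),
    chest_location = as.character(chest_location),
    acquisition_mode = as.character(acquisition_mode),
    equipment = as.character(equipment)
  ), class = "recording_meta")
}

#' @rdname parse_filename
#' @param meta A `recording_meta` object.
#' @export
format_filename <- function(meta) {
  paste(meta$patient_id, meta$recording_index, meta$chest_location,
        meta$acquisition_mode, meta$equipment, sep = "_")
}

#' Read an ICBHI cycle annotation file
#'
#' Annotation files carry one respiratory cycle per row with four
#' whitespace-separated columns: start time (s), end time (s), crackle
#' flag (0/1) and wheeze flag (0/1).
#'
#' @param path Path to the `.txt` annotation file.
#' @return A tibble with columns `start_s`, `end_s`, `crackle`,
#'   `wheeze` (logicals) and `label` (factor over [class_levels()]),
#'   rows in file order. An empty file yields an empty tibble.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  empty <- tibble(start_s = numeric(), end_s = numeric(),
                  crackle = logical(), wheeze = logical(),
                  label = factor(character(), levels = CLASS_LEVELS))
  if (length(lines) == 0) return(empty)

  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 4) {
      abort(sprintf("malformed annotation row %d in %s: expected 4 columns, got %d",
                    i, path, length(f)))
    }
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v)) abort(sprintf("non-numeric annotation row %d in %s", i, path))
    if (!all(v[3:4] %in% c(0, 1))) {
      abort(sprintf("crackle/wheeze flags must be 0/1 at row %d in %s", i, path))
    }
    if (v[1] < 0 || v[2] <= v[1]) {
      abort(sprintf("invalid cycle times at row %d in %s: start %.4f, end %.4f",
                    i, path, v[1], v[2]))
    }
    tibble(start_s = v[1], end_s = v[2],
           crackle = v[3] == 1, wheeze = v[4] == 1)
  })
  out <- dplyr::bind_rows(rows)
  out$label <- label_of(out$crackle, out$wheeze)
  out
}

#' Map crackle/wheeze flags to the four-class label
#'
#' The mapping is the bijection (0,0) -> normal, (1,0) -> crackle,
#' (0,1) -> wheeze, (1,1) -> both.
#'
#' @param crackle,wheeze Logical (or 0/1) vectors of equal length.
#' @return Factor over [class_levels()].
#' @export
#' @examples
#' label_of(c(FALSE, TRUE), c(TRUE, TRUE))
label_of <- function(crackle, wheeze) {
  stopifnot(length(crackle) == length(wheeze))
  crackle <- as.logical(crackle)
  wheeze <- as.logical(wheeze)
  out <- ifelse(crackle & wheeze, "both",
         ifelse(crackle, "crackle",
         ifelse(wheeze, "wheeze", "normal")))
  factor(out, levels = CLASS_LEVELS)
}

#' Census of an ICBHI-layout directory
#'
#' Walks a directory of paired `.wav`/`.txt` files and tabulates the
#' dataset: number of recordings, number of respiratory cycles,
#' per-class cycle counts and cycle-duration statistics. Unpaired files
#' are skipped with a warning rather than aborting, so partial
#' downloads can still be summarised.
#'
#' @param root_dir Directory containing WAV/TXT pairs.
#' @return A `census` object: list with `n_recordings`, `n_cycles`,
#'   `per_class` (named integer vector over [class_levels()]),
#'   `duration_stats` (min/mean/max seconds) and `cycles` (per-cycle
#'   tibble with `file_stem` and annotation columns).
#' @export
census <- function(root_dir) {
  if (!dir.exists(root_dir)) abort(paste0("directory not found: ", root_dir))
  wavs <- list.files(root_dir, pattern = "\\.wav$", ignore.case = TRUE)
  txts <- list.files(root_dir, pattern = "\\.txt$", ignore.case = TRUE)
  wav_stems <- sub("\\.wav$", "", wavs, ignore.case = TRUE)
  txt_stems <- sub("\\.txt$", "", txts, ignore.case = TRUE)

  unpaired <- c(setdiff(wav_stems, txt_stems), setdiff(txt_stems, wav_stems))
  if (length(unpaired) > 0) {
    warn(paste0("skipping ", length(unpaired), " unpaired file(s): ",
                paste(head(unpaired, 5), collapse = ", ")))
  }
  stems <- sort(intersect(wav_stems, txt_stems))

  cycles <- purrr::map_dfr(stems, function(stem) {
    ann <- read_annotation(file.path(root_dir, paste0(stem, ".txt")))
    if (nrow(ann) > 0) ann$file_stem <- stem
    ann
  })

  per_class <- setNames(integer(4), CLASS_LEVELS)
  if (nrow(cycles) > 0) {
    tab <- table(cycles$label)
    per_class[names(tab)] <- as.integer(tab)
    dur <- cycles$end_s - cycles$start_s
    duration_stats <- c(min = min(dur), mean = mean(dur), max = max(dur))
  } else {
    duration_stats <- c(min = NA_real_, mean = NA_real_, max = NA_real_)
  }

  structure(list(
    n_recordings = length(stems),
    n_patients = length(unique(vapply(
      stems, function(s) strsplit(s, "_", fixed = TRUE)[[1]][1], character(1)))),
    n_cycles = nrow(cycles),
    per_class = per_class,
    duration_stats = duration_stats,
    cycles = cycles
  ), class = "census")
}

#' @export
print.census <- function(x, ...) {
  cat("ICBHI-layout census\n")
  cat("  recordings:", x$n_recordings, " patients:", x$n_patients,
      " cycles:", x$n_cycles, "\n")
  cat("  per class: ", paste(names(x$per_class), x$per_class,
                             sep = "=", collapse = "  "), "\n")
  if (x$n_cycles > 0) {
    cat(sprintf("  cycle duration (s): min %.2f  mean %.2f  max %.2f\n",
                x$duration_stats["min"], x$duration_stats["mean"],
                x$duration_stats["max"]))
  }
  invisible(x)
}

#' @export
tidy.census <- function(x, ...) {
  tibble(class = factor(CLASS_LEVELS, levels = CLASS_LEVELS),
         n_cycles = as.integer(x$per_class))
}

#' @export
glance.census <- function(x, ...) {
  tibble(n_recordings = x$n_recordings, n_patients = x$n_patients,
         n_cycles = x$n_cycles,
         duration_min_s = x$duration_stats[["min"]],
         duration_mean_s = x$duration_stats[["mean"]],
         duration_max_s = x$duration_stats[["max"]])
}

#' Read all cycles of an ICBHI-layout directory as a clip table
#'
#' Convenience wrapper joining [read_wav()], [read_annotation()] and
#' [extract_cycles()] over every paired recording under `root_dir`.
#'
#' @param root_dir Directory of WAV/TXT pairs.
#' @return Tibble in the same shape as [synth_dataset()] output.
#' @export
read_icbhi_dataset <- function(root_dir) {
  cen <- census(root_dir)
  stems <- unique(cen$cycles$file_stem)
  purrr::map_dfr(stems, function(stem) {
    wav <- read_wav(file.path(root_dir, paste0(stem, ".wav")))
    ann <- cen$cycles[cen$cycles$file_stem == stem, ]
    clips <- extract_cycles(wav$samples, wav$rate, ann)
    if (nrow(clips) > 0) clips$file_stem <- stem
    clips
  })
}
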