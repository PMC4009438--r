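#' Write a recording bundle to disk
#'
#' Canonical plain-text layout: `eeg.csv` (time + 8 named channels, uV),
#' `nirs.csv` (time + 24 intensity columns `chNN_760`/`chNN_830`),
#' `events.tsv` (BIDS-style onset/duration/trial_type), `meta.json` (rates,
#' wavelengths, montage, seed, config echo) and, when ground truth exists,
#' `ground_truth.csv`. Values round-trip at full double precision.
#'
#' @param recording A `bci_recording`.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(recording, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(recording$eeg, file.path(path, "eeg.csv"), progress = FALSE)
  readr::write_csv(recording$nirs, file.path(path, "nirs.csv"), progress = FALSE)
  write_events(recording$schedule, file.path(path, "events.tsv"))
  meta <- recording$meta
  meta$montage <- as.list(meta$montage)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(recording$ground_truth)) {
    readr::write_csv(recording$ground_truth,
                     file.path(path, "ground_truth.csv"), progress = FALSE)
  }
  if (!is.null(recording$taps) && nrow(recording$taps)) {
    readr::write_csv(recording$taps, file.path(path, "taps.csv"),
                     progress = FALSE)
  }
  invisible(path)
}

#' Read a recording bundle
#'
#' Validates the bundle invariants: all referenced files present, exactly the
#' 8 named EEG channels, exactly 12 NIRS channels x 2 wavelengths, positive
#' rates.
#'
#' @param path Bundle directory.
#' @return A `bci_recording`.
#' @export
read_bundle <- function(path) {
  need <- c("eeg.csv", "nirs.csv", "events.tsv", "meta.json")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing)) {
    stop("Bundle is missing file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  if (is.null(meta$eeg_rate) || is.null(meta$nirs_rate) ||
      meta$eeg_rate <= 0 || meta$nirs_rate <= 0) {
    stop("meta.json must declare positive eeg_rate and nirs_rate.",
         call. = FALSE)
  }
  eeg <- readr::read_csv(file.path(path, "eeg.csv"), show_col_types = FALSE,
                         progress = FALSE)
  if (!identical(setdiff(names(eeg), "time"), eeg_channels)) {
    stop("eeg.csv must have exactly the channels ",
         paste(eeg_channels, collapse = ", "), ".", call. = FALSE)
  }
  nirs <- readr::read_csv(file.path(path, "nirs.csv"), show_col_types = FALSE,
                          progress = FALSE)
  wl <- meta$wavelengths %||% c(760, 830)
  expected <- nirs_intensity_cols(wl)
  if (!setequal(setdiff(names(nirs), "time"), expected)) {
    stop("nirs.csv must have 12 channels x 2 wavelengths (24 columns ",
         "chNN_", wl[1], "/chNN_", wl[2], "), got ",
         length(setdiff(names(nirs), "time")), " columns.", call. = FALSE)
  }
  nirs <- nirs[c("time", expected)]
  attr(nirs, "rate") <- meta$nirs_rate
  attr(nirs, "wavelengths") <- wl
  schedule <- read_events(file.path(path, "events.tsv"))
  gt_path <- file.path(path, "ground_truth.csv")
  gt <- NULL
  if (file.exists(gt_path)) {
    g <- readr::read_csv(gt_path, show_col_types = FALSE, progress = FALSE)
    gt <- new_hemo(g$time, as.matrix(g[grep("_hbo$", names(g))]),
                   as.matrix(g[grep("_hbr$", names(g))]), meta$nirs_rate)
  }
  taps_path <- file.path(path, "taps.csv")
  taps <- if (file.exists(taps_path)) {
    readr::read_csv(taps_path, show_col_types = FALSE, progress = FALSE)
  } else NULL
  if (is.data.frame(meta$montage)) meta$montage <- tibble::as_tibble(meta$montage)
  structure(list(eeg = eeg, nirs = nirs, schedule = schedule, taps = taps,
                 ground_truth = gt, meta = meta),
            class = "bci_recording")
}

#' Write a hemoglobin series as CSV
#'
#' Columns `time`, `ch01_hbo`..`ch12_hbo`, `ch01_hbr`..`ch12_hbr` in uM.
#'
#' @param hemo A [new_hemo()] series.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hemoglobin <- function(hemo, path) {
  readr::write_csv(hemo, path, progress = FALSE)
  invisible(path)
}

#' @export
print.bci_recording <- function(x, ...) {
  cat(sprintf(
    "Hybrid NIRS-EEG recording: %.0f s, EEG %d ch @ %g Hz, NIRS %d ch x 2 wl @ %g Hz\n",
    max(x$eeg$time) + 1 / x$meta$eeg_rate, length(setdiff(names(x$eeg), "time")),
    x$meta$eeg_rate, (ncol(x$nirs) - 1) / 2, x$meta$nirs_rate))
  cat(sprintf("Schedule: %d blocks (%d samples)\n", nrow(x$schedule),
              attr(x$schedule, "n_samples") %||% NA))
  invisible(x)
}
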