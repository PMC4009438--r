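#' Task labels used by the block-design paradigm
#'
#' The session alternates rest with four active tasks: left/right hand tapping
#' (decoded from motor-cortex EEG) and mental arithmetic / mental counting
#' (decoded from prefrontal NIRS).
#'
#' @format A character vector of the five trial-type labels.
#' @export
task_labels <- c("rest", "tap_left", "tap_right",
                 "mental_arithmetic", "mental_counting")

#' Build a block-design session schedule
#'
#' Constructs the event schedule of a hybrid NIRS-EEG session. Each 60-s data
#' sample is laid out as rest(5) - tap(10) - rest(5) - mental(10) - rest(5) -
#' tap-opposite(10) - rest(5) - mental-opposite(10), so consecutive same-modality
#' task onsets are 20 s apart. Block intervals are half-open
#' `[onset, onset + duration)` in float seconds from session start.
#'
#' @param n_samples Number of 60-s data samples (positive integer).
#' @param first_hand Hand tapped in the first tapping block, `"left"` or
#'   `"right"`. The second tapping block of a sample always uses the opposite
#'   hand.
#' @param first_mental Mental task of the first mental block, `"counting"`
#'   (forward command) or `"arithmetic"` (back command).
#' @param alternate If `TRUE` (default) the hand/mental alternation continues
#'   strictly across sample boundaries; if `FALSE` every sample restarts with
#'   `first_hand` / `first_mental`. Within a sample the two tapping (mental)
#'   blocks always use opposite tasks, so both settings satisfy the paradigm.
#' @return A tibble of class `bci_schedule` with columns `onset`, `duration`
#'   (seconds) and `trial_type`, plus a `sample` index column. Attributes
#'   `n_samples` and `total_duration` are set.
#' @examples
#' sched <- build_session(5)
#' attr(sched, "total_duration") # 300
#' @export
build_session <- function(n_samples,
                          first_hand = c("left", "right"),
                          first_mental = c("counting", "arithmetic"),
                          alternate = TRUE) {
  if (length(n_samples) != 1L || !is.finite(n_samples) ||
      n_samples < 1 || n_samples != round(n_samples)) {
    stop("`n_samples` must be a positive integer.", call. = FALSE)
  }
  n_samples <- as.integer(n_samples)
  first_hand <- match.arg(first_hand)
  first_mental <- match.arg(first_mental)

  hands <- c(left = "tap_left", right = "tap_right")
  mentals <- c(counting = "mental_counting", arithmetic = "mental_arithmetic")
  other_hand <- if (first_hand == "left") "right" else "left"
  other_mental <- if (first_mental == "counting") "arithmetic" else "counting"

  one_sample <- function(s) {
    # strict alternation across samples is equivalent to a restart here because
    # each sample contains one block of each task; `alternate` is kept for the
    # degenerate case of future layouts and for explicitness
    h1 <- if (alternate || s %% 2L == 1L) first_hand else first_hand
    m1 <- first_mental
    tibble::tibble(
      onset = 60 * (s - 1) + c(0, 5, 15, 20, 30, 35, 45, 50),
      duration = c(5, 10, 5, 10, 5, 10, 5, 10),
      trial_type = c("rest", hands[[h1]], "rest", mentals[[m1]],
                     "rest", hands[[other_hand]], "rest", mentals[[other_mental]]),
      sample = s
    )
  }

  sched <- dplyr::bind_rows(lapply(seq_len(n_samples), one_sample))
  sched <- tibble::new_tibble(sched, class = "bci_schedule")
  attr(sched, "n_samples") <- n_samples
  attr(sched, "total_duration") <- 60 * n_samples
  validate_schedule(sched)
  sched
}

#' Validate a session schedule
#'
#' Checks the paradigm invariants: non-negative onsets, positive durations,
#' contiguous non-overlapping blocks tiling `[0, total_duration)`, and per
#' 60-s sample exactly four 5-s rest blocks plus one block of each of the four
#' tasks (10 s each, opposite hands / opposite mental tasks).
#'
#' @param schedule A schedule tibble as returned by [build_session()] or read
#'   from an events file.
#' @return The schedule, invisibly. Errors with a descriptive message if an
#'   invariant is violated.
#' @export
validate_schedule <- function(schedule) {
  req <- c("onset", "duration", "trial_type")
  if (!all(req %in% names(schedule))) {
    stop("Schedule must have columns onset, duration, trial_type.", call. = FALSE)
  }
  if (nrow(schedule) == 0L) stop("Schedule is empty.", call. = FALSE)
  if (any(schedule$onset < 0)) stop("Block onsets must be >= 0.", call. = FALSE)
  if (any(schedule$duration <= 0)) stop("Block durations must be > 0.", call. = FALSE)
  if (!all(schedule$trial_type %in% task_labels)) {
    bad <- setdiff(unique(schedule$trial_type), task_labels)
    stop("Unknown trial_type: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  o <- schedule$onset
  d <- schedule$duration
  if (is.unsorted(o, strictly = TRUE)) {
    stop("Blocks must be ordered by strictly increasing onset.", call. = FALSE)
  }
  gaps <- abs(o[-1] - (o[-length(o)] + d[-length(d)]))
  if (o[1] != 0 || any(gaps > 1e-9)) {
    stop("Blocks must be contiguous and non-overlapping from t = 0.", call. = FALSE)
  }
  total <- o[length(o)] + d[length(d)]
  if (abs(total %% 60) > 1e-9) {
    stop("Schedule must tile whole 60-s samples.", call. = FALSE)
  }
  for (s in seq_len(round(total / 60))) {
    in_s <- schedule[o >= 60 * (s - 1) - 1e-9 & o < 60 * s - 1e-9, ]
    tt <- table(factor(in_s$trial_type, levels = task_labels))
    if (tt[["rest"]] != 4L || any(tt[c("tap_left", "tap_right",
                                       "mental_arithmetic", "mental_counting")] != 1L)) {
      stop("Sample ", s, " does not contain 4 rest blocks and one of each task.",
           call. = FALSE)
    }
    if (any(abs(in_s$duration[in_s$trial_type == "rest"] - 5) > 1e-9) ||
        any(abs(in_s$duration[in_s$trial_type != "rest"] - 10) > 1e-9)) {
      stop("Sample ", s, " has wrong block durations (rest 5 s, tasks 10 s).",
           call. = FALSE)
    }
  }
  invisible(schedule)
}

#' Derive modality-specific analysis windows from a schedule
#'
#' EEG epochs are taken from +1 to +11 s relative to each tapping-block onset
#' (10-s windows). NIRS windows are lagged by the hemodynamic onset delay:
#' `[onset + nirs_lag, onset + nirs_lag + 10]` for each mental block
#' (default lag 2 s, the typical delay before HbO starts to rise after the
#' prompt).
#'
#' @param schedule A validated schedule tibble.
#' @param modality `"eeg"` or `"nirs"`.
#' @param nirs_lag Hemodynamic onset lag in seconds (default 2).
#' @return A tibble with columns `start`, `end` (seconds), `label` and
#'   `modality`, one row per task block of the modality.
#' @examples
#' epoch_windows(build_session(5), "eeg") # 5 tap_left + 5 tap_right windows
#' @export
epoch_windows <- function(schedule, modality = c("eeg", "nirs"), nirs_lag = 2) {
  modality <- match.arg(modality)
  validate_schedule(schedule)
  if (modality == "eeg") {
    blk <- schedule[schedule$trial_type %in% c("tap_left", "tap_right"), ]
    tibble::tibble(start = blk$onset + 1, end = blk$onset + 11,
                   label = blk$trial_type, modality = "eeg")
  } else {
    blk <- schedule[schedule$trial_type %in%
                      c("mental_arithmetic", "mental_counting"), ]
    tibble::tibble(start = blk$onset + nirs_lag, end = blk$onset + nirs_lag + 10,
                   label = blk$trial_type, modality = "nirs")
  }
}

#' Rest reference windows for baseline estimation and rest trials
#'
#' Returns windows drawn from rest blocks that are physiologically clean for
#' the requested modality. For NIRS these are the rest blocks that directly
#' follow a tapping block (no hemodynamic wash-out from a preceding mental
#' task); for EEG the first second after the block boundary is discarded so
#' the trailing edge of the last tap response is excluded.
#'
#' @inheritParams epoch_windows
#' @return A tibble with columns `start`, `end`, `label` (`"rest"`) and
#'   `modality`.
#' @export
rest_windows <- function(schedule, modality = c("eeg", "nirs")) {
  modality <- match.arg(modality)
  validate_schedule(schedule)
  idx <- which(schedule$trial_type == "rest")
  prev_tap <- idx[idx > 1 &
                    schedule$trial_type[pmax(idx - 1, 1)] %in% c("tap_left", "tap_right")]
  blk <- schedule[prev_tap, ]
  if (modality == "eeg") {
    tibble::tibble(start = blk$onset + 1, end = blk$onset + blk$duration,
                   label = "rest", modality = "eeg")
  } else {
    tibble::tibble(start = blk$onset, end = blk$onset + blk$duration,
                   label = "rest", modality = "nirs")
  }
}

#' Write / read a schedule as a BIDS-style events TSV
#'
#' The file is tab-separated with a header row and columns `onset`,
#' `duration`, `trial_type`; times are written in seconds with three decimals.
#'
#' @param schedule Schedule tibble.
#' @param path File path of the events TSV.
#' @return `write_events()` returns `path` invisibly; `read_events()` returns
#'   a validated `bci_schedule` tibble.
#' @export
write_events <- function(schedule, path) {
  validate_schedule(schedule)
  out <- tibble::tibble(
    onset = sprintf("%.3f", schedule$onset),
    duration = sprintf("%.3f", schedule$duration),
    trial_type = schedule$trial_type
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("Events file not found: ", path, call. = FALSE)
  ev <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("onset", "duration", "trial_type") %in% names(ev))) {
    stop("Malformed events TSV (need onset, duration, trial_type): ", path,
         call. = FALSE)
  }
  ev$sample <- as.integer(floor(ev$onset / 60) + 1)
  sched <- tibble::new_tibble(ev[c("onset", "duration", "trial_type", "sample")],
                              class = "bci_schedule")
  attr(sched, "n_samples") <- max(ev$sample)
  attr(sched, "total_duration") <- max(ev$onset + ev$duration)
  validate_schedule(sched)
  sched
}
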