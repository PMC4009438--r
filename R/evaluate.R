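#' Trial-level feature table of one session
#'
#' One feature row per analysis window: the tapping and rest windows of the
#' EEG modality (mean C3/C4 peak amplitudes, detection thresholds from the
#' rest-window envelope baselines) and the mental-task and rest windows of
#' the NIRS modality (window-mean HbO/HbR across the 12 channels).
#'
#' @param recording A `bci_recording`.
#' @param optics An [optics_config()].
#' @param nirs_lag Hemodynamic onset lag, s.
#' @param k Peak-detection threshold multiplier.
#' @param ... Passed to [preprocess_nirs()].
#' @return A list with tibbles `eeg` (label + `eeg_c3_meanpeak`,
#'   `eeg_c4_meanpeak`) and `nirs` (label + `nirs_mean_hbo`,
#'   `nirs_mean_hbr`).
#' @export
session_trials <- function(recording, optics = optics_config(), nirs_lag = 2,
                           k = 2, ...) {
  rate <- recording$meta$eeg_rate
  eeg_bp <- bandpass_beta(recording$eeg, rate)
  rw <- rest_windows(recording$schedule, "eeg")
  baselines <- list(
    C3 = envelope_baseline(eeg_bp, rate, rw, "C3"),
    C4 = envelope_baseline(eeg_bp, rate, rw, "C4")
  )
  eeg_windows <- dplyr::bind_rows(epoch_windows(recording$schedule, "eeg"), rw)
  epochs <- segment_epochs(eeg_bp, rate, eeg_windows)
  eeg_tab <- purrr::map_dfr(epochs, function(ep) {
    dplyr::mutate(eeg_features(ep, baselines = baselines, k = k),
                  label = ep$label, .before = 1)
  })

  hemo <- preprocess_nirs(recording, optics, ...)
  nirs_windows <- dplyr::bind_rows(
    epoch_windows(recording$schedule, "nirs", nirs_lag),
    rest_windows(recording$schedule, "nirs")
  )
  nirs_tab <- purrr::map_dfr(seq_len(nrow(nirs_windows)), function(i) {
    dplyr::mutate(nirs_features(hemo, nirs_windows[i, ]),
                  label = nirs_windows$label[i], .before = 1)
  })
  list(eeg = eeg_tab, nirs = nirs_tab)
}

problem_defs <- list(
  left_vs_stop = list(modality = "eeg", task = "tap_left",
                      features = c("eeg_c3_meanpeak", "eeg_c4_meanpeak")),
  right_vs_stop = list(modality = "eeg", task = "tap_right",
                       features = c("eeg_c3_meanpeak", "eeg_c4_meanpeak")),
  forward_vs_stop = list(modality = "nirs", task = "mental_counting",
                         features = c("nirs_mean_hbo", "nirs_mean_hbr")),
  back_vs_stop = list(modality = "nirs", task = "mental_arithmetic",
                      features = c("nirs_mean_hbo", "nirs_mean_hbr"))
)

#' Evaluate simulated sessions
#'
#' Simulates `n_sessions` independent sessions, computes the four binary
#' problems (Left/Right/Forward/Back vs Stop) as stratified k-fold
#' cross-validated accuracies on trial-level features, and (optionally)
#' trains the state models on each session and decodes it to obtain per-block
#' majority-command accuracy. Deterministic given `seed`.
#'
#' @param n_sessions Number of simulated sessions.
#' @param n_samples 60-s samples per session (default 5).
#' @param cfg A [sim_config()]; its seed field is replaced per session by a
#'   value derived from `seed`.
#' @param optics An [optics_config()].
#' @param k Cross-validation folds.
#' @param seed Master seed.
#' @param decode Also run the full fusion decoder per session.
#' @return A list of class `bci_eval`: `table` (per-session accuracy tibble),
#'   `summary` (from [aggregate_accuracies()]), `block_accuracy` (mean
#'   percent across sessions, `NA` if `decode = FALSE`), `block_accuracies`.
#' @export
evaluate_sessions <- function(n_sessions = 20, n_samples = 5,
                              cfg = sim_config(), optics = optics_config(),
                              k = 5, seed = 0, decode = TRUE) {
  rows <- vector("list", n_sessions)
  block_acc <- rep(NA_real_, n_sessions)
  for (i in seq_len(n_sessions)) {
    cfg_i <- cfg
    cfg_i$seed <- as.integer((seed * 131071 + i * 7919) %% 2000000000)
    rec <- simulate_session(n_samples, cfg_i, optics)
    trials <- session_trials(rec, optics)
    acc <- purrr::imap_dbl(problem_defs, function(p, nm) {
      tab <- trials[[p$modality]]
      keep <- tab$label %in% c(p$task, "rest")
      cross_validate(tab[keep, p$features],
                     ifelse(tab$label[keep] == "rest", "rest", p$task),
                     k = k, seed = cfg_i$seed)$accuracy
    })
    rows[[i]] <- tibble::tibble(session = i, !!!as.list(acc))
    if (decode) {
      models <- train_models(rec, optics)
      block_acc[i] <- decode_session(rec, models, optics)$block_accuracy
    }
  }
  table <- dplyr::bind_rows(rows)
  structure(list(table = table,
                 summary = aggregate_accuracies(table),
                 block_accuracy = if (decode) mean(block_acc) else NA_real_,
                 block_accuracies = block_acc,
                 seed = seed),
            class = "bci_eval")
}

#' @export
print.bci_eval <- function(x, ...) {
  cat("Per-problem cross-validated accuracy over",
      nrow(x$table), "sessions:\n")
  print(x$summary)
  if (!is.na(x$block_accuracy)) {
    cat(sprintf("Mean per-block majority-command accuracy: %.1f%%\n",
                x$block_accuracy))
  }
  invisible(x)
}

# display rounding: half-up to `digits` decimals (R's round() is half-even)
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Summarise an accuracy table
#'
#' Column means and sample standard deviations (n - 1 denominator) of a
#' per-subject or per-session accuracy table, rounded half-up to one decimal
#' for display.
#'
#' @param table A data frame whose numeric columns (other than an id column
#'   named `session` or `subject`) are accuracies in percent.
#' @param digits Display decimals (default 1).
#' @return A tibble with `problem`, `mean`, `sd`.
#' @export
aggregate_accuracies <- function(table, digits = 1) {
  cols <- setdiff(names(table), c("session", "subject"))
  cols <- cols[vapply(table[cols], is.numeric, logical(1))]
  if (nrow(table) < 2) {
    stop("Need at least 2 rows to aggregate.", call. = FALSE)
  }
  vals <- as.matrix(table[cols])
  if (any(vals < 0 | vals > 100)) {
    stop("Accuracies must lie in [0, 100].", call. = FALSE)
  }
  tibble::tibble(
    problem = cols,
    mean = as.numeric(round_half_up(colMeans(vals), digits)),
    sd = as.numeric(round_half_up(apply(vals, 2, stats::sd), digits))
  )
}

#' Reference per-subject accuracies shipped with the package
#'
#' Loads the per-subject classification accuracies (12 subjects x 4 binary
#' problems) reported by the published hybrid NIRS-EEG study that this
#' pipeline models, transcribed as a plain-text test asset. Useful for
#' exercising [aggregate_accuracies()] and the report formatting.
#'
#' @return A tibble with columns `subject`, `left_vs_stop`, `right_vs_stop`,
#'   `forward_vs_stop`, `back_vs_stop`.
#' @export
reference_accuracies <- function() {
  path <- system.file("extdata", "reference_accuracies_12subjects.csv",
                      package = "hybridbci", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
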