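#' Commands emitted by the fusion stage
#' @format Character vector of the five control commands.
#' @export
commands <- c("Left", "Right", "Forward", "Back", "Stop")

#' Per-recording EEG peak stream
#'
#' Band-passed envelope peaks over the whole recording for the feature
#' channels, with the detection threshold taken from the rest-window envelope
#' baseline (`mean + k * SD`).
#'
#' @param eeg_bp Band-passed EEG tibble (`time` + channels).
#' @param rate Sampling rate, Hz.
#' @param schedule Session schedule (for the rest baseline windows).
#' @param channels Feature channels (default C3, C4).
#' @param k Threshold multiplier.
#' @param refractory Minimum inter-peak distance, s.
#' @param smooth Envelope smoothing width, s.
#' @return A tibble with `time`, `channel`, `amplitude`.
#' @export
eeg_peak_stream <- function(eeg_bp, rate, schedule, channels = c("C3", "C4"),
                            k = 2, refractory = 0.5, smooth = 0.15) {
  rw <- rest_windows(schedule, "eeg")
  purrr::map_dfr(channels, function(ch) {
    base <- envelope_baseline(eeg_bp, rate, rw, ch, smooth)
    env <- eeg_envelope(eeg_bp[[ch]], rate, smooth)
    pk <- find_peaks(env, eeg_bp$time, base$mean + k * base$sd, refractory)
    dplyr::mutate(pk, channel = ch, .before = 1)
  })
}

#' Channel-mean NIRS feature stream
#'
#' Mean HbO and HbR across the 12 channels at each NIRS sample.
#'
#' @param hemo A [new_hemo()] series (preprocessed).
#' @return Tibble with `time`, `hbo`, `hbr`.
#' @export
nirs_frame_stream <- function(hemo) {
  tibble::tibble(time = hemo$time,
                 hbo = rowMeans(hemo_matrix(hemo, "hbo")),
                 hbr = rowMeans(hemo_matrix(hemo, "hbr")))
}

#' Synchronize EEG and NIRS feature streams to a common decision rate
#'
#' Emits one frame per decision instant `t_k = k / common_rate`,
#' `k = 1 .. floor(T * common_rate)`. EEG features are recomputed causally
#' over a trailing window `(t_k - eeg_window, t_k]` (mean amplitude of the
#' detected peaks, 0 if none); NIRS features are the latest sample at or
#' before `t_k`, plus a trailing slope of mean HbO over the last
#' `slope_samples` NIRS samples. No frame uses data after its own time, so
#' the stream is online-capable.
#'
#' The EEG argument may alternatively be an already-framed feature stream
#' (columns `time`, `eeg_c3_meanpeak`, `eeg_c4_meanpeak`), in which case it
#' is aligned without recomputation (a no-op when already on the frame grid).
#'
#' @param eeg_stream Peak stream from [eeg_peak_stream()] or a framed feature
#'   tibble (see above).
#' @param nirs_stream Feature stream from [nirs_frame_stream()].
#' @param common_rate Decision rate in Hz (default 1.81, the NIRS rate).
#' @param extent Session extent in seconds; defaults to the NIRS stream
#'   extent.
#' @param eeg_window Trailing EEG feature window, s.
#' @param slope_samples Number of trailing NIRS samples for the slope.
#' @return A tibble of frames: `time`, `eeg_c3_meanpeak`, `eeg_c4_meanpeak`,
#'   `nirs_mean_hbo`, `nirs_mean_hbr`, `nirs_slope`.
#' @export
synchronize <- function(eeg_stream, nirs_stream, common_rate = 1.81,
                        extent = NULL, eeg_window = 2, slope_samples = 3) {
  if (is.null(extent)) {
    extent <- max(nirs_stream$time) + 1 / common_rate / 2
  }
  n_frames <- floor(extent * common_rate + 1e-9)
  if (n_frames < 1) stop("Streams do not overlap a single frame.", call. = FALSE)
  tk <- seq_len(n_frames) / common_rate

  framed_eeg <- all(c("eeg_c3_meanpeak", "eeg_c4_meanpeak") %in%
                      names(eeg_stream))
  if (framed_eeg) {
    i <- findInterval(tk + 1e-9, eeg_stream$time)
    if (any(i == 0)) stop("EEG feature stream starts after the first frame.",
                          call. = FALSE)
    c3 <- eeg_stream$eeg_c3_meanpeak[i]
    c4 <- eeg_stream$eeg_c4_meanpeak[i]
  } else {
    mean_in <- function(ch) {
      pk <- eeg_stream[eeg_stream$channel == ch, ]
      vapply(tk, function(t) {
        a <- pk$amplitude[pk$time > t - eeg_window & pk$time <= t]
        if (length(a)) mean(a) else 0
      }, numeric(1))
    }
    c3 <- mean_in("C3")
    c4 <- mean_in("C4")
  }

  ni <- findInterval(tk + 1e-9, nirs_stream$time)
  if (any(ni == 0)) stop("NIRS stream starts after the first frame.",
                         call. = FALSE)
  slope <- vapply(seq_along(tk), function(j) {
    i2 <- ni[j]
    i1 <- max(1L, i2 - slope_samples + 1L)
    if (i2 - i1 < 1L) return(0)
    tt <- nirs_stream$time[i1:i2]
    yy <- nirs_stream$hbo[i1:i2]
    sum((tt - mean(tt)) * (yy - mean(yy))) / sum((tt - mean(tt))^2)
  }, numeric(1))

  tibble::tibble(time = tk,
                 eeg_c3_meanpeak = c3, eeg_c4_meanpeak = c4,
                 nirs_mean_hbo = nirs_stream$hbo[ni],
                 nirs_mean_hbr = nirs_stream$hbr[ni],
                 nirs_slope = slope)
}

# Per-frame ground-truth command implied by the schedule. The windows account
# for the physics of the chain, not just the block edges: EEG frames see taps
# through a trailing 2-s causal window and a causal band-pass with a small
# group delay (margin 0.2 s past onset + 11); the NIRS response is lagged by
# onset_lag but the symmetric low-pass smears it ~2 s on both sides, so the
# command window is [onset, onset + nirs_lag + 10 + 2].
frame_truth <- function(frames, schedule, nirs_lag = 2,
                        eeg_margin = 0.2, nirs_smear = 2) {
  cmd <- rep("Stop", nrow(frames))
  for (i in seq_len(nrow(schedule))) {
    tt <- schedule$trial_type[i]
    if (tt == "rest") next
    if (tt %in% c("tap_left", "tap_right")) {
      lo <- schedule$onset[i]; hi <- schedule$onset[i] + 11 + eeg_margin
      cmd[frames$time >= lo & frames$time <= hi] <-
        if (tt == "tap_left") "Left" else "Right"
    } else {
      lo <- schedule$onset[i] + nirs_lag - nirs_smear
      hi <- schedule$onset[i] + nirs_lag + 10 + nirs_smear
      cmd[frames$time >= lo & frames$time <= hi] <-
        if (tt == "mental_arithmetic") "Back" else "Forward"
    }
  }
  cmd
}

#' Estimate rest baselines from synchronized frames
#'
#' Mean and SD of the EEG frame feature (max of the C3/C4 mean peak
#' amplitudes) and of the mean-HbO feature over the clean rest reference
#' windows of each modality (see [rest_windows()]); rest blocks that follow a
#' mental task are excluded for NIRS because the hemodynamic response is
#' still washing out there.
#'
#' @param frames Frames from [synchronize()].
#' @param schedule Session schedule.
#' @param nirs_lag Hemodynamic onset lag, s (kept for interface symmetry).
#' @return List with `eeg` and `nirs`, each `list(mean =, sd =)`.
#' @export
estimate_baselines <- function(frames, schedule, nirs_lag = 2) {
  in_windows <- function(w) {
    sel <- rep(FALSE, nrow(frames))
    for (i in seq_len(nrow(w))) {
      sel <- sel | (frames$time >= w$start[i] & frames$time < w$end[i])
    }
    sel
  }
  eeg_rest <- in_windows(rest_windows(schedule, "eeg"))
  nirs_rest <- in_windows(rest_windows(schedule, "nirs"))
  if (!any(eeg_rest) || !any(nirs_rest)) {
    stop("No rest frames available for baseline estimation.", call. = FALSE)
  }
  eegf <- pmax(frames$eeg_c3_meanpeak, frames$eeg_c4_meanpeak)[eeg_rest]
  list(eeg = list(mean = mean(eegf), sd = stats::sd(eegf)),
       nirs = list(mean = mean(frames$nirs_mean_hbo[nirs_rest]),
                   sd = stats::sd(frames$nirs_mean_hbo[nirs_rest])))
}

#' Per-frame modality states
#'
#' A modality is "active" when its feature magnitude exceeds the rest
#' baseline mean + `k` * SD; NIRS additionally requires a positive trailing
#' HbO slope so that the hemodynamic wash-out after a task decays back to
#' rest instead of being re-detected. Active EEG frames are subclassified
#' left/right by the EEG discriminant, active NIRS frames
#' arithmetic/counting by the NIRS discriminant.
#'
#' @param frames Frames from [synchronize()].
#' @param baselines Baselines from [estimate_baselines()] (typically carried
#'   by the trained models).
#' @param models List with `bci_lda` fits `eeg_lr` (features C3/C4 mean peaks;
#'   levels left/right) and `nirs_ac` (features mean HbO/HbR; levels
#'   arithmetic/counting).
#' @param k Threshold multiplier (default 2).
#' @return `frames` with added `eeg_state` (`rest`/`left_hand`/`right_hand`)
#'   and `nirs_state` (`rest`/`arithmetic`/`counting`).
#' @export
activity_state <- function(frames, baselines, models, k = 2) {
  if (is.null(baselines$eeg) || is.null(baselines$nirs)) {
    stop("Missing baseline statistics; estimate or train them first.",
         call. = FALSE)
  }
  eeg_feat <- pmax(frames$eeg_c3_meanpeak, frames$eeg_c4_meanpeak)
  eeg_active <- eeg_feat > baselines$eeg$mean + k * baselines$eeg$sd
  nirs_active <- frames$nirs_mean_hbo >
    baselines$nirs$mean + k * baselines$nirs$sd
  nirs_active <- nirs_active & frames$nirs_slope > 0

  eeg_state <- rep("rest", nrow(frames))
  if (any(eeg_active)) {
    pred <- predict(models$eeg_lr,
                    frames[eeg_active, c("eeg_c3_meanpeak", "eeg_c4_meanpeak")])
    eeg_state[eeg_active] <- ifelse(pred$.class == "left",
                                    "left_hand", "right_hand")
  }
  nirs_state <- rep("rest", nrow(frames))
  if (any(nirs_active)) {
    pred <- predict(models$nirs_ac,
                    frames[nirs_active, c("nirs_mean_hbo", "nirs_mean_hbr")])
    nirs_state[nirs_active] <- pred$.class
  }
  dplyr::mutate(frames, eeg_state = eeg_state, nirs_state = nirs_state)
}

#' Map modality states to a control command
#'
#' The five-command truth table: left hand -> Left, right hand -> Right,
#' mental arithmetic -> Back, mental counting -> Forward, common rest ->
#' Stop. Simultaneous non-rest states in both modalities cannot occur under
#' the paradigm; as a safety default such conflicts map to Stop with a raised
#' flag.
#'
#' @param eeg_state Character vector in `rest`/`left_hand`/`right_hand`.
#' @param nirs_state Character vector in `rest`/`arithmetic`/`counting`.
#' @param hand_mapping `"direct"` (default; left hand -> Left, the published
#'   truth table) or `"crossed"` (left hand -> Right, the contralateral
#'   reading some descriptions suggest). Exposed because the source material
#'   is ambiguous between the two.
#' @return Tibble with `command` and logical `conflict`.
#' @export
decode_command <- function(eeg_state, nirs_state,
                           hand_mapping = c("direct", "crossed")) {
  hand_mapping <- match.arg(hand_mapping)
  left_cmd <- if (hand_mapping == "direct") "Left" else "Right"
  right_cmd <- if (hand_mapping == "direct") "Right" else "Left"
  conflict <- eeg_state != "rest" & nirs_state != "rest"
  command <- dplyr::case_when(
    conflict ~ "Stop",
    eeg_state == "left_hand" ~ left_cmd,
    eeg_state == "right_hand" ~ right_cmd,
    nirs_state == "arithmetic" ~ "Back",
    nirs_state == "counting" ~ "Forward",
    TRUE ~ "Stop"
  )
  tibble::tibble(command = command, conflict = conflict)
}

#' Train the decoding models on a recording
#'
#' Preprocesses both modalities, synchronizes them, and fits the two state
#' discriminants on the frames of the task analysis windows: left vs right on
#' the EEG features and arithmetic vs counting on the NIRS features. The rest
#' baselines estimated from the same session are stored with the models.
#'
#' @param recording A `bci_recording`.
#' @param optics An [optics_config()] matching the acquisition.
#' @param nirs_lag Hemodynamic onset lag, s.
#' @param k Activity-threshold multiplier carried into decoding.
#' @param ... Passed to [preprocess_nirs()].
#' @return A list of class `bci_models`: `eeg_lr`, `nirs_ac`, `baselines`,
#'   `nirs_lag`, `k`.
#' @export
train_models <- function(recording, optics = optics_config(), nirs_lag = 2,
                         k = 2, ...) {
  pre <- decode_features(recording, optics, nirs_lag = nirs_lag, ...)
  truth <- frame_truth(pre$frames, recording$schedule, nirs_lag)
  fr <- pre$frames

  eeg_idx <- truth %in% c("Left", "Right")
  eeg_lr <- fit_lda(fr[eeg_idx, c("eeg_c3_meanpeak", "eeg_c4_meanpeak")],
                    ifelse(truth[eeg_idx] == "Left", "left", "right"))
  nirs_idx <- truth %in% c("Back", "Forward")
  nirs_ac <- fit_lda(fr[nirs_idx, c("nirs_mean_hbo", "nirs_mean_hbr")],
                     ifelse(truth[nirs_idx] == "Back", "arithmetic", "counting"))
  structure(list(eeg_lr = eeg_lr, nirs_ac = nirs_ac,
                 baselines = estimate_baselines(fr, recording$schedule, nirs_lag),
                 nirs_lag = nirs_lag, k = k),
            class = "bci_models")
}

# shared preprocessing for train/decode: band-pass, denoise, synchronize
decode_features <- function(recording, optics = optics_config(), nirs_lag = 2,
                            common_rate = NULL, ...) {
  rate <- recording$meta$eeg_rate
  common_rate <- common_rate %||% recording$meta$nirs_rate
  eeg_bp <- bandpass_beta(recording$eeg, rate)
  peaks <- eeg_peak_stream(eeg_bp, rate, recording$schedule)
  hemo <- preprocess_nirs(recording, optics, ...)
  stream <- nirs_frame_stream(hemo)
  total <- max(recording$schedule$onset + recording$schedule$duration)
  frames <- synchronize(peaks, stream, common_rate, extent = total)
  list(frames = frames, hemo = hemo, eeg_bp = eeg_bp, peaks = peaks)
}

#' Decode a full session into a command stream
#'
#' Runs the complete chain (NIRS inversion and denoising, beta-band EEG peak
#' extraction, synchronization, activity states, command fusion) and scores
#' it against the schedule: per-frame confusion and per-block majority
#' commands over each block's analysis window.
#'
#' @param recording A `bci_recording`.
#' @param models A `bci_models` from [train_models()] (or a compatible list).
#' @param optics An [optics_config()].
#' @param ... Passed to [preprocess_nirs()].
#' @return A list of class `bci_decode`: `frames` (the command stream with
#'   states, command, conflict and ground truth), `blocks` (per task/rest
#'   block: intended and majority command), `block_accuracy`,
#'   `frame_accuracy` (percent), `confusion` (table).
#' @export
decode_session <- function(recording, models, optics = optics_config(), ...) {
  pre <- decode_features(recording, optics, nirs_lag = models$nirs_lag, ...)
  st <- activity_state(pre$frames, models$baselines, models, k = models$k)
  dec <- decode_command(st$eeg_state, st$nirs_state)
  frames <- dplyr::bind_cols(st, dec)
  frames$truth <- frame_truth(frames, recording$schedule, models$nirs_lag)

  sched <- recording$schedule
  majority <- function(x) names(sort(table(x), decreasing = TRUE))[1]
  blocks <- purrr::map_dfr(seq_len(nrow(sched)), function(i) {
    tt <- sched$trial_type[i]
    win <- switch(tt,
      rest = c(sched$onset[i], sched$onset[i] + sched$duration[i]),
      tap_left = , tap_right = sched$onset[i] + c(1, 11),
      sched$onset[i] + models$nirs_lag + c(0, 10))
    intended <- switch(tt, rest = "Stop", tap_left = "Left",
                       tap_right = "Right", mental_arithmetic = "Back",
                       mental_counting = "Forward")
    sel <- frames$time >= win[1] & frames$time <= win[2]
    if (tt == "rest") sel <- sel & frames$truth == "Stop"
    tibble::tibble(onset = sched$onset[i], trial_type = tt,
                   intended = intended,
                   decoded = if (any(sel)) majority(frames$command[sel])
                             else NA_character_,
                   n_frames = sum(sel))
  })
  ok <- !is.na(blocks$decoded)
  structure(list(
    frames = frames,
    blocks = blocks,
    block_accuracy = 100 * mean(blocks$intended[ok] == blocks$decoded[ok]),
    frame_accuracy = 100 * mean(frames$command == frames$truth),
    confusion = table(truth = frames$truth, decoded = frames$command)
  ), class = "bci_decode")
}

#' @export
print.bci_decode <- function(x, ...) {
  cat(sprintf("Decoded session: %d frames, block accuracy %.1f%%, frame accuracy %.1f%%\n",
              nrow(x$frames), x$block_accuracy, x$frame_accuracy))
  invisible(x)
}

#' Write a command stream as TSV
#'
#' Columns: `time`, `eeg_state`, `nirs_state`, `command`, `conflict_flag`.
#'
#' @param decoded A `bci_decode` (or a frames tibble with the state columns).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_commands <- function(decoded, path) {
  fr <- if (inherits(decoded, "bci_decode")) decoded$frames else decoded
  out <- tibble::tibble(time = sprintf("%.3f", fr$time),
                        eeg_state = fr$eeg_state, nirs_state = fr$nirs_state,
                        command = fr$command, conflict_flag = fr$conflict)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
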