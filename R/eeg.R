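#' Beta-band filtering of EEG
#'
#' Order-4 Butterworth band-pass (12-30 Hz by default). The default is a
#' causal filter so the chain stays online-capable (no future samples); set
#' `zero_phase = TRUE` for offline zero-phase filtering with
#' [signal::filtfilt()].
#'
#' @param eeg Tibble with a `time` column and one numeric column per channel,
#'   or a plain numeric matrix.
#' @param rate Sampling rate in Hz.
#' @param band Numeric pair of band edges in Hz, inside `(0, rate/2)`.
#' @param zero_phase Use forward-backward filtering (offline only).
#' @return The filtered object, same shape as the input.
#' @export
bandpass_beta <- function(eeg, rate = 256, band = c(12, 30),
                          zero_phase = FALSE) {
  if (length(band) != 2 || band[1] <= 0 || band[2] >= rate / 2 ||
      band[1] >= band[2]) {
    stop("`band` must satisfy 0 < low < high < rate/2.", call. = FALSE)
  }
  flt <- signal::butter(4, band / (rate / 2), type = "pass")
  apply_col <- function(x) {
    if (zero_phase) signal::filtfilt(flt, x)
    else as.numeric(signal::filter(flt, x))
  }
  if (is.matrix(eeg)) return(apply(eeg, 2, apply_col))
  out <- eeg
  for (cn in setdiff(names(eeg), "time")) out[[cn]] <- apply_col(eeg[[cn]])
  out
}

#' Segment a recording into epochs
#'
#' One epoch per window; sample indices are the half-open range
#' `[round(start * rate), round(end * rate))`. Overlapping windows are
#' allowed; epochs are independent copies.
#'
#' @param eeg Tibble with `time` + channel columns.
#' @param rate Sampling rate in Hz.
#' @param windows Tibble of windows (`start`, `end`, `label`), e.g. from
#'   [epoch_windows()].
#' @return A list of epochs; each is a list with `data` (tibble), `rate`,
#'   `label`, `start` and `end`, of class `bci_epoch`.
#' @export
segment_epochs <- function(eeg, rate, windows) {
  n <- nrow(eeg)
  lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    i1 <- round(w$start * rate) + 1L
    i2 <- round(w$end * rate)
    if (i1 < 1L || i2 > n) {
      stop("Window [", w$start, ", ", w$end, ") (", w$label,
           ") lies outside the recording.", call. = FALSE)
    }
    structure(list(data = eeg[i1:i2, , drop = FALSE], rate = rate,
                   label = w$label, start = w$start, end = w$end),
              class = "bci_epoch")
  })
}

#' Amplitude envelope of a band-limited signal
#'
#' Rectification followed by Gaussian smoothing, scaled by pi/2 so that the
#' envelope of a pure sinusoid of amplitude A reads approximately A.
#'
#' @param x Numeric vector (band-passed signal).
#' @param rate Sampling rate in Hz.
#' @param smooth Gaussian smoothing width (s).
#' @return Numeric envelope, same length as `x`.
#' @export
eeg_envelope <- function(x, rate, smooth = 0.15) {
  sigma <- max(1, smooth * rate)
  radius <- min(ceiling(4 * sigma), length(x) - 1)
  k <- stats::dnorm(seq(-radius, radius), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  ax <- abs(x)
  pad <- c(ax[(radius:1) + 1], ax, ax[n - (1:radius)])
  y <- stats::filter(pad, k, sides = 2)
  as.numeric(y[radius + seq_len(n)]) * pi / 2
}

# local maxima above a threshold with greedy refractory suppression
find_peaks <- function(env, time, threshold, refractory) {
  n <- length(env)
  if (n < 3) return(tibble::tibble(time = numeric(), amplitude = numeric()))
  is_max <- c(FALSE, env[2:(n - 1)] > env[1:(n - 2)] &
                env[2:(n - 1)] >= env[3:n], FALSE)
  cand <- which(is_max & env > threshold)
  if (!length(cand)) return(tibble::tibble(time = numeric(), amplitude = numeric()))
  cand <- cand[order(env[cand], decreasing = TRUE)]
  kept <- integer()
  for (i in cand) {
    if (!length(kept) || all(abs(time[i] - time[kept]) > refractory)) {
      kept <- c(kept, i)
    }
  }
  kept <- sort(kept)
  tibble::tibble(time = time[kept], amplitude = env[kept])
}

#' Detect tap events in a band-passed epoch
#'
#' Peaks of the rectified-and-smoothed envelope that exceed
#' `baseline mean + k * SD` (default `k = 2`) with a minimum inter-peak
#' distance of `refractory` seconds (default half the tapping period). When
#' no baseline statistics are supplied they are estimated robustly from the
#' epoch's own envelope (median and scaled MAD), which assumes peaks are
#' sparse within the epoch.
#'
#' @param epoch A `bci_epoch` from [segment_epochs()] (band-passed data).
#' @param channel Channel name, e.g. `"C4"`.
#' @param baseline Optional list with `mean` and `sd` of the rest-segment
#'   envelope for this channel.
#' @param k Threshold multiplier.
#' @param refractory Minimum inter-peak distance in seconds.
#' @param smooth Envelope smoothing width (s).
#' @return Tibble with `time` (s) and `amplitude` (uV) of each detected peak.
#' @export
detect_taps <- function(epoch, channel, baseline = NULL, k = 2,
                        refractory = 0.5, smooth = 0.15) {
  if (!channel %in% names(epoch$data)) {
    stop("Unknown channel '", channel, "'.", call. = FALSE)
  }
  env <- eeg_envelope(epoch$data[[channel]], epoch$rate, smooth)
  thr <- if (!is.null(baseline)) {
    baseline$mean + k * baseline$sd
  } else {
    stats::median(env) + k * stats::mad(env)
  }
  find_peaks(env, epoch$data$time, thr, refractory)
}

#' Detect the taps of one tapping block
#'
#' Convenience wrapper around [segment_epochs()] and [detect_taps()] that
#' counts the taps of a single tapping block on its contralateral channel.
#' The detection window is the block shifted half a tap period earlier
#' (`[onset - p/2, onset + duration - p/2]`, `p = 1/tap_rate`), so each tap
#' sits at the centre of its own refractory cell and the tap at block onset
#' is interior to the window.
#'
#' @param eeg_bp Band-passed EEG tibble covering the block and the preceding
#'   rest period.
#' @param rate Sampling rate, Hz.
#' @param block One-row schedule block (`tap_left` or `tap_right`).
#' @param baseline Envelope baseline list (`mean`, `sd`) for the channel,
#'   e.g. from [envelope_baseline()].
#' @param tap_rate Tapping frequency, Hz.
#' @param ... Passed to [detect_taps()].
#' @return Tibble of detected peaks (`time`, `amplitude`).
#' @export
detect_block_taps <- function(eeg_bp, rate, block, baseline = NULL,
                              tap_rate = 1, ...) {
  half <- 0.5 / tap_rate
  channel <- if (block$trial_type[1] == "tap_left") "C4" else "C3"
  ep <- segment_epochs(eeg_bp, rate, tibble::tibble(
    start = block$onset[1] - half,
    end = block$onset[1] + block$duration[1] - half,
    label = block$trial_type[1]))[[1]]
  detect_taps(ep, channel, baseline = baseline,
              refractory = half, ...)
}

#' Envelope baseline statistics from rest windows
#'
#' Mean and SD of the envelope of a band-passed channel over the rest
#' reference windows; used as the detection baseline for [detect_taps()] and
#' for the frame-level activity check.
#'
#' @param eeg_bp Band-passed EEG tibble (`time` + channels).
#' @param rate Sampling rate, Hz.
#' @param windows Rest windows tibble (e.g. [rest_windows()]).
#' @param channel Channel name.
#' @param smooth Envelope smoothing width (s).
#' @return List with `mean` and `sd`.
#' @export
envelope_baseline <- function(eeg_bp, rate, windows, channel, smooth = 0.15) {
  env <- eeg_envelope(eeg_bp[[channel]], rate, smooth)
  sel <- rep(FALSE, length(env))
  for (i in seq_len(nrow(windows))) {
    sel <- sel | (eeg_bp$time >= windows$start[i] & eeg_bp$time < windows$end[i])
  }
  list(mean = mean(env[sel]), sd = stats::sd(env[sel]))
}

#' Mean peak amplitudes on C3 and C4
#'
#' The EEG feature pair of the decoder: arithmetic mean of the detected peak
#' amplitudes on C3 and on C4. A channel with no detected peaks contributes 0.
#' Envelope magnitudes (not signed peaks) are used throughout.
#'
#' @param epoch A `bci_epoch` (band-passed data including C3 and C4).
#' @param baselines Optional named list of per-channel baseline lists
#'   (`list(C3 = list(mean=, sd=), C4 = ...)`).
#' @param peaks Optional named list of precomputed peak tibbles (overrides
#'   detection).
#' @param ... Passed to [detect_taps()].
#' @return One-row tibble with `eeg_c3_meanpeak` and `eeg_c4_meanpeak` (uV).
#' @export
eeg_features <- function(epoch, baselines = NULL, peaks = NULL, ...) {
  get_peaks <- function(ch) {
    if (!is.null(peaks)) return(peaks[[ch]])
    detect_taps(epoch, ch, baseline = baselines[[ch]], ...)
  }
  mean0 <- function(x) if (length(x)) mean(x) else 0
  tibble::tibble(
    eeg_c3_meanpeak = mean0(get_peaks("C3")$amplitude),
    eeg_c4_meanpeak = mean0(get_peaks("C4")$amplitude)
  )
}
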