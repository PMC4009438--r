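# Synthetic recording generator. Every signal model here (pink noise,
# Gaussian-windowed beta bursts, gamma-shaped hemodynamic response, sinusoidal
# physiological noise) is simulator plumbing with exported ground truth -- it
# emulates the study conditions but is not a measurement of any real brain.

#' Construct a hemoglobin concentration series
#'
#' @param time Time axis in seconds.
#' @param hbo,hbr Numeric matrices `[time x 12]` of HbO / HbR concentration
#'   changes in uM.
#' @param rate Sampling rate in Hz.
#' @return A tibble of class `bci_hemo` with columns `time`,
#'   `ch01_hbo`..`ch12_hbo`, `ch01_hbr`..`ch12_hbr` and attribute `rate`.
#' @export
new_hemo <- function(time, hbo, hbr, rate) {
  hbo <- as.matrix(hbo); hbr <- as.matrix(hbr)
  stopifnot(nrow(hbo) == length(time), all(dim(hbo) == dim(hbr)))
  df <- tibble::as_tibble(cbind(hbo, hbr), .name_repair = "minimal")
  names(df) <- hemo_cols()[seq_len(ncol(df))]
  out <- tibble::new_tibble(dplyr::bind_cols(tibble::tibble(time = time), df),
                            class = "bci_hemo")
  attr(out, "rate") <- rate
  out
}

hemo_matrix <- function(hemo, species = c("hbo", "hbr")) {
  species <- match.arg(species)
  cols <- grep(paste0("_", species, "$"), names(hemo), value = TRUE)
  as.matrix(hemo[cols])
}

#' Pink (1/f) noise
#'
#' Spectral-synthesis pink noise: white Gaussian noise is shaped in the
#' frequency domain with amplitude proportional to f^(-1/2) (power ~ 1/f)
#' and normalised to the requested RMS.
#'
#' @param n Number of samples.
#' @param rms Target root-mean-square amplitude.
#' @return Numeric vector of length `n` (zeros when `rms = 0`).
#' @export
pink_noise <- function(n, rms = 1) {
  if (rms == 0 || n == 0) return(numeric(n))
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k)            # symmetric frequency index
  scale <- ifelse(f == 0, 0, 1 / sqrt(f))
  y <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  y <- y - mean(y)
  y * rms / stats::sd(y)
}

#' Tap event times within a tapping block
#'
#' Taps are evenly spaced at the tapping frequency starting at block onset;
#' a 10-s block at 1 Hz yields 10 taps.
#'
#' @param block A single-row schedule block (list or one-row tibble with
#'   `onset`, `duration`, `trial_type`).
#' @param cfg A [sim_config()].
#' @return Numeric vector of tap times in seconds.
#' @export
simulate_taps <- function(block, cfg = sim_config()) {
  if (!block$trial_type[1] %in% c("tap_left", "tap_right")) {
    stop("`block` must be a tapping block, got ", block$trial_type[1],
         call. = FALSE)
  }
  n_taps <- floor(block$duration[1] * cfg$tap_rate + 1e-9)
  block$onset[1] + (seq_len(n_taps) - 1) / cfg$tap_rate
}

#' Simulate the EEG stream of a session
#'
#' Pink-noise background on all eight channels; at each tap event a
#' Gaussian-windowed beta-band burst (carrier `beta_burst_freq`) is added to
#' the channel contralateral to the tapping hand (left hand -> C4, right hand
#' -> C3), with the left-hand amplitude deliberately larger. Deterministic
#' given `cfg$seed`.
#'
#' @param schedule A schedule tibble (any set of blocks with valid labels;
#'   typically from [build_session()]).
#' @param cfg A [sim_config()].
#' @return A list with `data` (tibble `time` + the 8 EEG channels, uV),
#'   `taps` (tibble `time`, `hand`) and `rate`.
#' @export
simulate_eeg <- function(schedule, cfg = sim_config()) {
  total <- max(schedule$onset + schedule$duration)
  n <- round(total * cfg$eeg_rate)
  t <- (seq_len(n) - 1) / cfg$eeg_rate
  withr::with_seed(cfg$seed, {
    dat <- matrix(0, n, length(eeg_channels),
                  dimnames = list(NULL, eeg_channels))
    for (ch in seq_along(eeg_channels)) {
      dat[, ch] <- pink_noise(n, cfg$eeg_noise)
    }
    taps <- list()
    tap_blocks <- schedule[schedule$trial_type %in% c("tap_left", "tap_right"), ]
    for (b in seq_len(nrow(tap_blocks))) {
      blk <- tap_blocks[b, ]
      times <- simulate_taps(blk, cfg)
      hand <- if (blk$trial_type == "tap_left") "left" else "right"
      target <- if (hand == "left") "C4" else "C3"   # contralateral physiology
      amp <- if (hand == "left") cfg$tap_amp_left else cfg$tap_amp_right
      for (t0 in times) {
        a <- amp * exp(stats::rnorm(1, 0, cfg$tap_amp_jitter))
        i <- which(abs(t - t0) <= 4 * cfg$tap_width)
        dt <- t[i] - t0
        dat[i, target] <- dat[i, target] +
          a * exp(-dt^2 / (2 * cfg$tap_width^2)) *
          cos(2 * pi * cfg$beta_burst_freq * dt)
      }
      taps[[b]] <- tibble::tibble(time = times, hand = hand)
    }
    list(data = dplyr::bind_cols(tibble::tibble(time = t),
                                 tibble::as_tibble(dat)),
         taps = if (length(taps)) dplyr::bind_rows(taps)
                else tibble::tibble(time = numeric(), hand = character()),
         rate = cfg$eeg_rate)
  })
}

# Unit-peak hemodynamic block response sampled at arbitrary lags relative to
# block onset. The impulse response is a gamma kernel delayed by the onset lag
# and tapered to zero (settle_time - onset_lag - 1) s after the lag, so the
# 10-s block response peaks around task end and has fully settled
# settle_time - 1 s after task end.
block_response_fun <- function(cfg, block_duration = 10) {
  support <- cfg$settle_time - cfg$onset_lag - 1
  stopifnot(support > 2)
  dt <- 0.02
  tau <- seq(0, support, by = dt)
  h <- stats::dgamma(tau, shape = 5, scale = support / 6.5)
  taper_from <- 0.8 * support
  w <- rep(1, length(tau))
  in_tap <- tau > taper_from
  w[in_tap] <- 0.5 * (1 + cos(pi * (tau[in_tap] - taper_from) /
                                (support - taper_from)))
  h <- h * w
  n_box <- round(block_duration / dt)
  r <- stats::convolve(c(h, numeric(n_box)), rev(rep(1, n_box)), type = "open")
  r <- r[seq_len(length(tau) + n_box)] * dt
  r <- r / max(r)
  tr <- cfg$onset_lag + seq(0, by = dt, length.out = length(r))
  function(rel_t) {
    y <- numeric(length(rel_t))
    ok <- rel_t >= tr[1] & rel_t <= tr[length(tr)]
    y[ok] <- stats::approx(tr, r, xout = rel_t[ok])$y
    y
  }
}

#' Simulate ground-truth hemodynamics of a session
#'
#' Noise-free HbO/HbR concentration changes on the 12 prefrontal channels.
#' Each mental block drives a delayed, smoothly rising and settling HbO
#' response (onset lag `cfg$onset_lag`, settled within `cfg$settle_time` after
#' task end); HbR is a scaled negative copy. Mental arithmetic and mental
#' counting differ in their spatial amplitude weights and HbO:HbR ratio so the
#' two classes are separable from channel-mean features.
#'
#' @inheritParams simulate_eeg
#' @return A [new_hemo()] tibble at the NIRS rate (ground truth).
#' @export
simulate_hemodynamics <- function(schedule, cfg = sim_config()) {
  total <- max(schedule$onset + schedule$duration)
  n <- floor(total * cfg$nirs_rate + 1e-9)
  t <- (seq_len(n) - 1) / cfg$nirs_rate
  hbo <- matrix(0, n, 12)
  hbr <- matrix(0, n, 12)
  resp <- block_response_fun(cfg)
  mb <- schedule[schedule$trial_type %in%
                   c("mental_arithmetic", "mental_counting"), ]
  gains <- withr::with_seed(cfg$seed + 2L,
                            exp(stats::rnorm(nrow(mb), 0, cfg$response_gain_sd)))
  for (b in seq_len(nrow(mb))) {
    blk <- mb[b, ]
    r <- resp(t - blk$onset)
    if (blk$trial_type == "mental_arithmetic") {
      w <- cfg$w_arithmetic; hscale <- cfg$hbr_scale_arithmetic
    } else {
      w <- cfg$w_counting; hscale <- cfg$hbr_scale_counting
    }
    add <- gains[b] * cfg$hbo_peak * outer(r, w)
    hbo <- hbo + add
    hbr <- hbr + hscale * add
  }
  new_hemo(t, hbo, hbr, cfg$nirs_rate)
}

#' Forward modified Beer-Lambert model: concentrations to raw intensities
#'
#' For each channel and wavelength the optical-density change is
#' `dA(t; lambda) = (alpha_HbO(lambda) dcHbO + alpha_HbR(lambda) dcHbR) * l *
#' d(lambda)`, and the emitted intensity is
#' `I_out(t; lambda) = I_in(lambda) * exp(-A0(lambda) - dA)`. Physiological
#' noise (cardiac, respiratory and Mayer-wave sinusoids with random phases)
#' plus white measurement noise is added in the optical-density domain when
#' `cfg` is supplied with non-zero amplitudes.
#'
#' @param truth A [new_hemo()] ground-truth series.
#' @param optics An [optics_config()].
#' @param cfg A [sim_config()] controlling the noise terms, or `NULL` for a
#'   noise-free forward model.
#' @return A tibble `time` + 24 intensity columns `ch01_760`, `ch01_830`, ...
#'   with attributes `rate` and `wavelengths`.
#' @export
forward_mbll <- function(truth, optics = optics_config(), cfg = NULL) {
  if (abs(det(optics$extinction)) < 1e-15) {
    stop("Extinction matrix is singular.", call. = FALSE)
  }
  hbo <- hemo_matrix(truth, "hbo")
  hbr <- hemo_matrix(truth, "hbr")
  t <- truth$time
  n <- length(t)
  out <- matrix(0, n, 24)
  noisy <- !is.null(cfg) &&
    (cfg$cardiac_amp > 0 || cfg$resp_amp > 0 || cfg$mayer_amp > 0 ||
       cfg$od_noise > 0 || cfg$drift_amp > 0)
  gen <- function() {
    for (wl in 1:2) {
      dA <- (optics$extinction[wl, 1] * hbo + optics$extinction[wl, 2] * hbr) *
        optics$l * optics$dpf[wl]
      if (noisy) {
        for (ch in 1:12) {
          phases <- stats::runif(3 + cfg$n_drift, 0, 2 * pi)
          drift_f <- stats::runif(cfg$n_drift, cfg$drift_band[1],
                                  cfg$drift_band[2])
          drift <- 0
          for (j in seq_len(cfg$n_drift)) {
            drift <- drift +
              cfg$drift_amp * sin(2 * pi * drift_f[j] * t + phases[3 + j])
          }
          dA[, ch] <- dA[, ch] + drift +
            cfg$cardiac_amp * sin(2 * pi * cfg$cardiac_freq * t + phases[1]) +
            cfg$resp_amp * sin(2 * pi * cfg$resp_freq * t + phases[2]) +
            cfg$mayer_amp * sin(2 * pi * cfg$mayer_freq * t + phases[3]) +
            stats::rnorm(n, 0, cfg$od_noise)
        }
      }
      out[, seq(wl, 24, by = 2)] <<- optics$I_in[wl] * exp(-optics$A0[wl] - dA)
    }
  }
  if (noisy) withr::with_seed(cfg$seed + 1L, gen()) else gen()
  colnames(out) <- nirs_intensity_cols(optics$wavelengths)
  res <- dplyr::bind_cols(tibble::tibble(time = t), tibble::as_tibble(out))
  attr(res, "rate") <- attr(truth, "rate")
  attr(res, "wavelengths") <- optics$wavelengths
  res
}

#' Simulate a complete recording bundle
#'
#' Builds the session schedule, simulates EEG and ground-truth hemodynamics,
#' and pushes the truth through the forward optical model to obtain raw
#' two-wavelength intensities.
#'
#' @param n_samples Number of 60-s samples (default 5, a 5-min session).
#' @param cfg A [sim_config()].
#' @param optics An [optics_config()].
#' @param ... Passed to [build_session()] (`first_hand`, `first_mental`,
#'   `alternate`).
#' @return A list of class `bci_recording` with elements `eeg` (tibble),
#'   `nirs` (tibble of raw intensities), `schedule`, `taps`, `ground_truth`
#'   (noise-free [new_hemo()] series) and `meta`.
#' @export
simulate_session <- function(n_samples = 5, cfg = sim_config(),
                             optics = optics_config(), ...) {
  schedule <- build_session(n_samples, ...)
  eeg <- simulate_eeg(schedule, cfg)
  truth <- simulate_hemodynamics(schedule, cfg)
  nirs <- forward_mbll(truth, optics, cfg)
  structure(list(
    eeg = eeg$data,
    nirs = nirs,
    schedule = schedule,
    taps = eeg$taps,
    ground_truth = truth,
    meta = list(
      eeg_rate = cfg$eeg_rate,
      nirs_rate = cfg$nirs_rate,
      wavelengths = optics$wavelengths,
      montage = default_montage(),
      eeg_channels = eeg_channels,
      seed = cfg$seed,
      config = unclass(cfg),
      optics = list(l = optics$l, dpf = optics$dpf, I_in = optics$I_in,
                    A0 = optics$A0,
                    extinction = as.vector(optics$extinction))
    )
  ), class = "bci_recording")
}
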