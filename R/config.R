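#' EEG montage channel names
#'
#' Eight electrodes over the sensorimotor strip in the international 10-20
#' system; only C3 and C4 carry task features, the remaining channels are
#' recorded and stored but unused by the decoder.
#' @format Character vector of length 8.
#' @export
eeg_channels <- c("C3", "C4", "T3", "T4", "P3", "P4", "F3", "F4")

#' Molar extinction coefficients of hemoglobin
#'
#' Standard published molar extinction coefficients of oxy- and
#' deoxy-hemoglobin at 760 and 830 nm, expressed in uM^-1 cm^-1 as used by the
#' modified Beer-Lambert law. Overridable through [optics_config()].
#'
#' @format A 2 x 2 matrix; rows are wavelengths (760, 830 nm), columns the
#'   chromophores (HbO, HbR).
#' @export
hb_extinction <- matrix(
  c(5.860e-4, 1.5485e-3,   # 760 nm: HbO, HbR
    9.740e-4, 6.930e-4),   # 830 nm: HbO, HbR
  nrow = 2, byrow = TRUE,
  dimnames = list(c("760", "830"), c("HbO", "HbR"))
)

#' Default prefrontal NIRS montage
#'
#' Twelve measurement channels formed from 3 sources and 8 detectors covering
#' the prefrontal area (Fp1/Fp2). The exact pairing geometry of the original
#' probe is not published; this layout is a documented plausible arrangement,
#' not a reconstruction.
#'
#' @return A tibble with columns `channel` (`ch01`..`ch12`), `source`
#'   (`S1`..`S3`) and `detector` (`D1`..`D8`).
#' @export
default_montage <- function() {
  tibble::tibble(
    channel = sprintf("ch%02d", 1:12),
    source = paste0("S", c(1, 1, 1, 1, 2, 2, 2, 2, 3, 3, 3, 3)),
    detector = paste0("D", c(1, 2, 3, 4, 3, 4, 5, 6, 5, 6, 7, 8))
  )
}

#' Optical configuration for the modified Beer-Lambert law
#'
#' Houses everything the forward and inverse models share: wavelengths,
#' extinction coefficients, source-detector distance `l`, differential
#' path-length factors `d`, incident intensities and baseline absorbance.
#' Scattering loss is constant in time and cancels when optical-density
#' *changes* are formed, so it is folded into `A0`.
#'
#' @param wavelengths Numeric pair of wavelengths in nm.
#' @param extinction 2 x 2 extinction matrix in uM^-1 cm^-1, rows =
#'   wavelengths, columns = (HbO, HbR). Must be invertible.
#' @param l Source-detector distance in cm.
#' @param dpf Differential path-length factor per wavelength (dimensionless).
#'   When the two values differ, each optical-density change is divided by its
#'   own `l * dpf` before the 2 x 2 inversion.
#' @param I_in Incident intensity per wavelength (arbitrary units).
#' @param A0 Baseline absorbance per wavelength (includes scattering loss).
#' @return A list of class `bci_optics`.
#' @export
optics_config <- function(wavelengths = c(760, 830),
                          extinction = hb_extinction,
                          l = 3,
                          dpf = c(6, 6),
                          I_in = c(1000, 1000),
                          A0 = c(1, 1)) {
  extinction <- as.matrix(extinction)
  if (!all(dim(extinction) == c(2, 2)) || !all(is.finite(extinction))) {
    stop("`extinction` must be a finite 2 x 2 matrix.", call. = FALSE)
  }
  if (abs(det(extinction)) < 1e-15) {
    stop("Extinction matrix is singular; cannot configure the MBLL.",
         call. = FALSE)
  }
  if (l <= 0 || any(dpf <= 0)) {
    stop("`l` and `dpf` must be positive.", call. = FALSE)
  }
  structure(list(wavelengths = wavelengths, extinction = extinction, l = l,
                 dpf = rep_len(dpf, 2), I_in = rep_len(I_in, 2),
                 A0 = rep_len(A0, 2)),
            class = "bci_optics")
}

#' Simulation configuration
#'
#' Parameters of the synthetic recording generator. Defaults encode the study
#' conditions of the emulated session: 256 Hz EEG on 8 motor-strip channels,
#' 1.81 Hz NIRS on 12 prefrontal channels at 760/830 nm, 1 Hz tapping with a
#' stronger left hand, a 2-s hemodynamic onset lag and settling within ~12 s
#' after task end. Amplitudes and noise levels are generator tuning (the
#' emulated study reports none), chosen to give a realistically separable but
#' noisy session.
#'
#' @param eeg_rate EEG sampling rate, Hz.
#' @param nirs_rate NIRS sampling rate, Hz.
#' @param tap_rate Tapping frequency, Hz.
#' @param tap_amp_left,tap_amp_right Peak amplitude (uV) of the beta burst
#'   injected per tap; left is deliberately stronger than right so amplitude
#'   carries the hand information (`tap_amp_left > tap_amp_right`).
#' @param tap_width Gaussian temporal width (s) of each tap burst.
#' @param beta_burst_freq Carrier frequency (Hz) of the injected burst; must
#'   lie inside `beta_band`.
#' @param beta_band Beta band, Hz pair.
#' @param eeg_noise RMS amplitude (uV) of the pink-noise EEG background
#'   (0 disables noise).
#' @param hbo_peak Peak HbO concentration change (uM) of a unit-weight channel
#'   during a mental block.
#' @param hbr_scale_arithmetic,hbr_scale_counting HbR response as a (negative)
#'   fraction of the HbO response per task; the two tasks differ in this ratio
#'   as well as in spatial weights, making them separable from the channel
#'   means.
#' @param w_arithmetic,w_counting Length-12 spatial amplitude weights across
#'   the NIRS channels per task.
#' @param onset_lag Hemodynamic onset delay after the prompt, s.
#' @param settle_time Time (s) for the response to settle (< 5 % of peak)
#'   after task end.
#' @param cardiac_amp,cardiac_freq,resp_amp,resp_freq,mayer_amp,mayer_freq
#'   Amplitudes (optical-density units) and frequencies (Hz) of the sinusoidal
#'   physiological noise added to the optical signal.
#' @param od_noise White measurement noise SD in the optical-density domain.
#' @param drift_amp Amplitude (optical-density units) of each slow
#'   physiological drift sinusoid per channel (0 disables drift).
#' @param drift_band Frequency range (Hz) the `n_drift` drift sinusoids are
#'   drawn from; below the low-pass cutoff, so drifts survive preprocessing
#'   and limit rest-vs-task separability like real slow oscillations do.
#' @param n_drift Number of drift sinusoids per channel.
#' @param response_gain_sd Log-normal SD of the per-block hemodynamic
#'   response gain (trial-to-trial variability of the true response).
#' @param tap_amp_jitter Log-normal SD of the per-tap burst amplitude.
#' @param seed Integer seed; all simulators are deterministic given the seed.
#' @return A list of class `bci_sim_config`.
#' @export
sim_config <- function(eeg_rate = 256,
                       nirs_rate = 1.81,
                       tap_rate = 1,
                       tap_amp_left = 30,
                       tap_amp_right = 15,
                       tap_width = 0.1,
                       beta_burst_freq = 21,
                       beta_band = c(12, 30),
                       eeg_noise = 3,
                       hbo_peak = 1.5,
                       hbr_scale_arithmetic = -0.25,
                       hbr_scale_counting = -0.45,
                       w_arithmetic = c(1.5, 1.4, 1.3, 1.3, 1.2, 1.1,
                                        1.0, 1.0, 0.9, 0.9, 0.9, 0.8),
                       w_counting = c(0.5, 0.5, 0.6, 0.6, 0.6, 0.7,
                                      0.7, 0.7, 0.8, 0.8, 0.7, 0.6),
                       onset_lag = 2,
                       settle_time = 12,
                       cardiac_amp = 0.003, cardiac_freq = 1.1,
                       resp_amp = 0.002, resp_freq = 0.3,
                       mayer_amp = 0.0015, mayer_freq = 0.1,
                       od_noise = 0.0008,
                       drift_amp = 0.004, drift_band = c(0.005, 0.04),
                       n_drift = 3,
                       response_gain_sd = 0.3,
                       tap_amp_jitter = 0.15,
                       seed = 1L) {
  if (eeg_rate <= 0 || nirs_rate <= 0 || tap_rate <= 0) {
    stop("Sampling and tapping rates must be positive.", call. = FALSE)
  }
  if (!(tap_amp_left > tap_amp_right && tap_amp_right > 0)) {
    stop("Need tap_amp_left > tap_amp_right > 0.", call. = FALSE)
  }
  if (!(hbo_peak > 0)) stop("`hbo_peak` must be positive.", call. = FALSE)
  if (hbr_scale_arithmetic >= 0 || hbr_scale_counting >= 0) {
    stop("HbR scales must be negative (HbR mirrors HbO).", call. = FALSE)
  }
  if (length(w_arithmetic) != 12L || length(w_counting) != 12L) {
    stop("Spatial weight vectors must have length 12.", call. = FALSE)
  }
  structure(list(
    eeg_rate = eeg_rate, nirs_rate = nirs_rate, tap_rate = tap_rate,
    tap_amp_left = tap_amp_left, tap_amp_right = tap_amp_right,
    tap_width = tap_width, beta_burst_freq = beta_burst_freq,
    beta_band = beta_band, eeg_noise = eeg_noise,
    hbo_peak = hbo_peak,
    hbr_scale_arithmetic = hbr_scale_arithmetic,
    hbr_scale_counting = hbr_scale_counting,
    w_arithmetic = w_arithmetic, w_counting = w_counting,
    onset_lag = onset_lag, settle_time = settle_time,
    cardiac_amp = cardiac_amp, cardiac_freq = cardiac_freq,
    resp_amp = resp_amp, resp_freq = resp_freq,
    mayer_amp = mayer_amp, mayer_freq = mayer_freq,
    od_noise = od_noise,
    drift_amp = drift_amp, drift_band = drift_band, n_drift = n_drift,
    response_gain_sd = response_gain_sd, tap_amp_jitter = tap_amp_jitter,
    seed = as.integer(seed)
  ), class = "bci_sim_config")
}

# column name helpers shared by simulator and IO
nirs_intensity_cols <- function(wavelengths = c(760, 830)) {
  as.vector(t(outer(sprintf("ch%02d", 1:12), wavelengths,
                    function(ch, wl) paste0(ch, "_", wl))))
}

hemo_cols <- function() {
  c(paste0(sprintf("ch%02d", 1:12), "_hbo"),
    paste0(sprintf("ch%02d", 1:12), "_hbr"))
}
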