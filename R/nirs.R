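#' Optical-density changes from raw intensities
#'
#' `dA(t; lambda) = ln(I_ref(lambda) / I_out(t; lambda))`, where `I_ref` is
#' the geometric-mean intensity over a baseline interval (default the initial
#' 5-s rest block), i.e. the arithmetic mean in the log/absorbance domain
#' where the signal is linear, so the differencing is exact. Referencing the
#' in-run baseline cancels the incident intensity, baseline absorbance and
#' scattering loss, which is what makes the modified Beer-Lambert inversion
#' possible without knowing them.
#'
#' @param intensity Tibble `time` + 24 columns `ch01_760`, `ch01_830`, ... as
#'   produced by [forward_mbll()] or read from `nirs.csv`.
#' @param optics An [optics_config()] (used only for wavelength naming here).
#' @param baseline Length-2 numeric, the baseline interval in seconds.
#' @return A tibble `time` + 24 dimensionless `dA` columns with attribute
#'   `rate`.
#' @export
optical_density <- function(intensity, optics = optics_config(),
                            baseline = c(0, 5)) {
  cols <- setdiff(names(intensity), "time")
  mat <- as.matrix(intensity[cols])
  if (any(!is.finite(mat)) || any(mat <= 0)) {
    bad <- which(!is.finite(mat) | mat <= 0, arr.ind = TRUE)[1, ]
    stop("Non-positive intensity in channel ", cols[bad[2]],
         " at sample ", bad[1], ".", call. = FALSE)
  }
  in_base <- intensity$time >= baseline[1] & intensity$time < baseline[2]
  if (!any(in_base)) stop("Baseline interval contains no samples.", call. = FALSE)
  log_ref <- colMeans(log(mat[in_base, , drop = FALSE]))
  dA <- matrix(log_ref, nrow(mat), ncol(mat), byrow = TRUE) - log(mat)
  res <- dplyr::bind_cols(tibble::tibble(time = intensity$time),
                          tibble::as_tibble(dA, .name_repair = "minimal"))
  names(res) <- c("time", cols)
  attr(res, "rate") <- attr(intensity, "rate") %||% infer_rate(intensity$time)
  res
}

infer_rate <- function(time) 1 / stats::median(diff(time))

#' Invert the modified Beer-Lambert law
#'
#' Per channel and time point solves the 2 x 2 linear system
#' `dA(lambda_i) / (l * d(lambda_i)) = alpha_HbO(lambda_i) dcHbO +
#' alpha_HbR(lambda_i) dcHbR` for the concentration changes. Each wavelength's
#' optical density is divided by its own path-length product before the
#' inversion, which resolves the ambiguity of a single scalar `1/(l d)` factor
#' when the two differential path-length factors differ.
#'
#' @param od Optical-density tibble from [optical_density()].
#' @param optics An [optics_config()].
#' @return A [new_hemo()] tibble of concentration changes in uM.
#' @export
mbll_invert <- function(od, optics = optics_config()) {
  E <- optics$extinction
  if (abs(det(E)) < 1e-15 * max(abs(E))^2) {
    stop("Extinction matrix is singular; check the optics configuration.",
         call. = FALSE)
  }
  Einv <- solve(E)
  cols <- setdiff(names(od), "time")
  wl1 <- grep(paste0("_", optics$wavelengths[1], "$"), cols, value = TRUE)
  wl2 <- grep(paste0("_", optics$wavelengths[2], "$"), cols, value = TRUE)
  a1 <- as.matrix(od[wl1]) / (optics$l * optics$dpf[1])
  a2 <- as.matrix(od[wl2]) / (optics$l * optics$dpf[2])
  hbo <- Einv[1, 1] * a1 + Einv[1, 2] * a2
  hbr <- Einv[2, 1] * a1 + Einv[2, 2] * a2
  new_hemo(od$time, hbo, hbr, attr(od, "rate") %||% infer_rate(od$time))
}

#' Gaussian low-pass filter
#'
#' Convolves each channel with a unit-DC-gain Gaussian kernel whose -3 dB
#' point equals `cutoff`; edges are reflect-padded so the output length equals
#' the input length. Used to suppress cardiac and respiratory oscillations in
#' the hemodynamic traces while passing the block-design frequencies
#' (~0.017 Hz).
#'
#' @param series A tibble with a `time` column and numeric channel columns
#'   (e.g. a [new_hemo()] series).
#' @param cutoff -3 dB cutoff frequency in Hz (default 0.1).
#' @param rate Sampling rate in Hz; taken from the series attribute if absent.
#' @return The filtered series, same shape and class.
#' @export
gaussian_lowpass <- function(series, cutoff = 0.1, rate = NULL) {
  rate <- rate %||% attr(series, "rate") %||% infer_rate(series$time)
  if (cutoff <= 0 || cutoff >= rate / 2) {
    stop("`cutoff` must lie in (0, rate/2).", call. = FALSE)
  }
  # |H(f)| = exp(-2 pi^2 sigma^2 f^2); |H(cutoff)| = 1/sqrt(2)
  sigma <- sqrt(log(2)) / (2 * pi * cutoff) * rate   # in samples
  n <- nrow(series)
  radius <- max(1L, min(ceiling(4 * sigma), n - 1L))
  k <- stats::dnorm(seq(-radius, radius), sd = sigma)
  k <- k / sum(k)
  cols <- setdiff(names(series), "time")
  out <- series
  for (cn in cols) {
    x <- series[[cn]]
    pad <- c(x[(radius:1) + 1], x, x[n - (1:radius)])
    y <- stats::filter(pad, k, sides = 2)
    out[[cn]] <- as.numeric(y[radius + seq_len(n)])
  }
  out
}

# ---- discrete wavelet transform ------------------------------------------
# Periodized orthogonal pyramid transform, implemented in-package. Filter taps
# are the standard published Daubechies scaling coefficients.
wavelet_filters <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(-0.12940952255092145, 0.22414386804185735,
          0.836516303737469, 0.48296291314469025),
  db5 = c(0.003335725285001549, -0.012580751999015526,
          -0.006241490213011705, 0.07757149384006515,
          -0.03224486958502952, -0.24229488706619015,
          0.13842814590110342, 0.7243085284385744,
          0.6038292697974729, 0.160102397974125)
)

wt_highpass <- function(lo) rev(lo) * (-1)^(seq_along(lo) - 1)

dwt_step <- function(x, lo, hi) {
  n <- length(x)
  L <- length(lo)
  half <- n %/% 2L
  idx <- outer(2 * (seq_len(half) - 1L), seq_len(L) - 1L, "+") %% n + 1L
  xm <- matrix(x[idx], half, L)
  list(approx = as.numeric(xm %*% lo), detail = as.numeric(xm %*% hi))
}

idwt_step <- function(approx, detail, lo, hi) {
  half <- length(approx)
  n <- 2L * half
  L <- length(lo)
  x <- numeric(n)
  for (m in seq_len(L)) {
    pos <- (2 * (seq_len(half) - 1L) + (m - 1L)) %% n + 1L
    contrib <- lo[m] * approx + hi[m] * detail
    x[pos] <- x[pos] + contrib
  }
  x
}

dwt_periodic <- function(x, lo, level) {
  hi <- wt_highpass(lo)
  details <- vector("list", level)
  a <- x
  for (j in seq_len(level)) {
    s <- dwt_step(a, lo, hi)
    details[[j]] <- s$detail
    a <- s$approx
  }
  list(approx = a, details = details)
}

idwt_periodic <- function(dec, lo) {
  hi <- wt_highpass(lo)
  a <- dec$approx
  for (j in rev(seq_along(dec$details))) {
    a <- idwt_step(a, dec$details[[j]], lo, hi)
  }
  a
}

#' Wavelet denoising of hemodynamic traces
#'
#' Per channel: periodized discrete wavelet decomposition to the given level,
#' soft/hard thresholding of all detail coefficients at the universal
#' threshold `sigma * sqrt(2 log N)` with `sigma` estimated from the
#' median absolute deviation of the finest-level details, then
#' reconstruction. Signals whose length is not a multiple of `2^level` are
#' reflect-padded internally and trimmed back.
#'
#' @inheritParams gaussian_lowpass
#' @param family Wavelet family; one of `"db1"`, `"db2"`, `"db5"` (default
#'   `"db5"`).
#' @param level Decomposition depth (default 4).
#' @param rule `"soft"` (default) or `"hard"` thresholding.
#' @return The denoised series, same shape and class.
#' @export
wavelet_denoise <- function(series, family = "db5", level = 4,
                            rule = c("soft", "hard")) {
  rule <- match.arg(rule)
  lo <- wavelet_filters[[family]]
  if (is.null(lo)) {
    stop("Unknown wavelet family '", family, "'. Available: ",
         paste(names(wavelet_filters), collapse = ", "), call. = FALSE)
  }
  if (level < 1 || level != round(level)) {
    stop("`level` must be a positive integer.", call. = FALSE)
  }
  cols <- setdiff(names(series), "time")
  n <- nrow(series)
  block <- 2^level
  n_pad <- ceiling(n / block) * block
  if (n_pad / block < length(lo) / 2 || n < block) {
    stop("Series too short (", n, " samples) for a level-", level,
         " '", family, "' decomposition.", call. = FALSE)
  }
  out <- series
  for (cn in cols) {
    x <- series[[cn]]
    if (n_pad > n) x <- c(x, x[n - seq_len(n_pad - n)])  # reflect pad
    dec <- dwt_periodic(x, lo, level)
    sigma <- stats::median(abs(dec$details[[1]])) / 0.6745
    thr <- sigma * sqrt(2 * log(n))
    dec$details <- lapply(dec$details, function(d) {
      if (rule == "soft") sign(d) * pmax(abs(d) - thr, 0) else d * (abs(d) > thr)
    })
    out[[cn]] <- idwt_periodic(dec, lo)[seq_len(n)]
  }
  out
}

#' Window-averaged NIRS features
#'
#' The NIRS feature pair of the decoder: mean HbO and mean HbR over an
#' analysis window and over a channel subset.
#'
#' @param series A [new_hemo()] series.
#' @param window A one-row window (list/tibble with `start`, `end` in
#'   seconds), e.g. a row of [epoch_windows()].
#' @param channels Integer or `chXX` character subset of the 12 channels
#'   (default all).
#' @return A one-row tibble with `nirs_mean_hbo` and `nirs_mean_hbr` (uM).
#' @export
nirs_features <- function(series, window, channels = 1:12) {
  if (length(channels) == 0) stop("Empty channel selection.", call. = FALSE)
  if (is.character(channels)) channels <- match(channels, sprintf("ch%02d", 1:12))
  sel <- series$time >= window$start[1] & series$time < window$end[1]
  if (!any(sel)) {
    stop("Window [", window$start[1], ", ", window$end[1],
         ") contains no samples.", call. = FALSE)
  }
  hbo <- hemo_matrix(series, "hbo")[sel, channels, drop = FALSE]
  hbr <- hemo_matrix(series, "hbr")[sel, channels, drop = FALSE]
  tibble::tibble(nirs_mean_hbo = mean(hbo), nirs_mean_hbr = mean(hbr))
}

#' Full NIRS preprocessing chain
#'
#' Raw intensities -> optical density (baseline-referenced) -> modified
#' Beer-Lambert inversion -> Gaussian low-pass -> wavelet denoising. The
#' low-pass runs first so the wavelet threshold is estimated on the remaining
#' broadband measurement noise rather than on cardiac oscillations.
#'
#' @param recording A `bci_recording` (or any list with `nirs` and `schedule`).
#' @param optics An [optics_config()]; must match the acquisition optics.
#' @param cutoff Gaussian low-pass cutoff in Hz.
#' @param wavelet,level,rule Passed to [wavelet_denoise()]; set
#'   `wavelet = NULL` to skip the wavelet stage.
#' @param baseline Baseline interval for [optical_density()]; defaults to the
#'   session's initial 5-s rest block.
#' @return A denoised [new_hemo()] series.
#' @export
preprocess_nirs <- function(recording, optics = optics_config(),
                            cutoff = 0.1, wavelet = "db5", level = 4,
                            rule = "soft", baseline = c(0, 5)) {
  od <- optical_density(recording$nirs, optics, baseline = baseline)
  hemo <- mbll_invert(od, optics)
  hemo <- gaussian_lowpass(hemo, cutoff)
  if (!is.null(wavelet)) {
    hemo <- wavelet_denoise(hemo, family = wavelet, level = level, rule = rule)
  }
  hemo
}

`%||%` <- function(a, b) if (is.null(a)) b else a
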