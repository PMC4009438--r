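make_intensity <- function(mat, rate = 1.81) {
  out <- dplyr::bind_cols(
    tibble::tibble(time = (seq_len(nrow(mat)) - 1) / rate),
    tibble::as_tibble(mat, .name_repair = "minimal"))
  names(out) <- c("time", hybridbci:::nirs_intensity_cols())
  attr(out, "rate") <- rate
  out
}

test_that("optical density is zero for baseline intensity and one for I_ref/e", {
  I <- make_intensity(matrix(500, 40, 24))
  od <- optical_density(I)
  expect_true(all(as.matrix(od[-1]) == 0))

  m <- matrix(500, 40, 24)
  m[20, ] <- 500 / exp(1)
  od2 <- optical_density(make_intensity(m), baseline = c(0, 5))
  expect_equal(unname(as.matrix(od2[-1])[20, ]), rep(1, 24), tolerance = 1e-12)
})

test_that("optical density matches the forward model's absorbance exactly", {
  opt <- optics_config()
  cfg <- sim_config(seed = 5)
  s <- build_session(1)
  tr <- simulate_hemodynamics(s, cfg)     # zero during the initial rest block
  I <- forward_mbll(tr, opt, cfg = NULL)
  od <- optical_density(I, opt)
  hbo <- hybridbci:::hemo_matrix(tr, "hbo")
  hbr <- hybridbci:::hemo_matrix(tr, "hbr")
  for (wl in 1:2) {
    expected <- (opt$extinction[wl, 1] * hbo + opt$extinction[wl, 2] * hbr) *
      opt$l * opt$dpf[wl]
    got <- as.matrix(od[grep(paste0("_", opt$wavelengths[wl]), names(od))])
    expect_lt(max(abs(got - expected)), 1e-12)
  }
})

test_that("non-positive intensities raise an error naming the sample", {
  m <- matrix(500, 10, 24)
  m[4, 7] <- 0
  expect_error(optical_density(make_intensity(m)), "channel ch04_760.*sample 4")
})

test_that("the MBLL inversion solves the 2x2 extinction system", {
  opt <- optics_config()
  zero <- make_intensity(matrix(1, 5, 24))
  names(zero) <- c("time", hybridbci:::nirs_intensity_cols())
  od0 <- optical_density(zero)
  h0 <- mbll_invert(od0, opt)
  expect_true(all(as.matrix(h0[-1]) == 0))

  # identity extinction with unit path length returns the od traces themselves
  opt_id <- optics_config(extinction = diag(2), l = 1, dpf = c(1, 1))
  withr::with_seed(2, od <- matrix(rnorm(20 * 24), 20))
  od_direct <- dplyr::bind_cols(tibble::tibble(time = (0:19) / 1.81),
                                tibble::as_tibble(od, .name_repair = "minimal"))
  names(od_direct) <- c("time", hybridbci:::nirs_intensity_cols())
  attr(od_direct, "rate") <- 1.81
  h <- mbll_invert(od_direct, opt_id)
  expect_equal(unname(hybridbci:::hemo_matrix(h, "hbo")),
               unname(od[, seq(1, 24, 2)]))
  expect_equal(unname(hybridbci:::hemo_matrix(h, "hbr")),
               unname(od[, seq(2, 24, 2)]))

  # random invertible extinction vs the closed-form cofactor solution
  withr::with_seed(9, {
    for (rep in 1:20) {
      E <- matrix(rnorm(4), 2)
      while (abs(det(E)) < 0.05) E <- matrix(rnorm(4), 2)
      o <- optics_config(extinction = E, l = 2.5, dpf = c(4, 7))
      a <- matrix(rnorm(2), 2)   # dA at the two wavelengths, one channel
      od1 <- od_direct
      od1[, 1 + 1] <- a[1]; od1[, 2 + 1] <- a[2]
      h1 <- mbll_invert(od1, o)
      rhs <- c(a[1] / (2.5 * 4), a[2] / (2.5 * 7))
      cof <- c(E[2, 2] * rhs[1] - E[1, 2] * rhs[2],
               -E[2, 1] * rhs[1] + E[1, 1] * rhs[2]) / det(E)
      expect_equal(unname(hybridbci:::hemo_matrix(h1, "hbo")[1, 1]), cof[1],
                   tolerance = 1e-12)
      expect_equal(unname(hybridbci:::hemo_matrix(h1, "hbr")[1, 1]), cof[2],
                   tolerance = 1e-12)
    }
  })
})

test_that("the MBLL inversion is linear in the optical densities", {
  opt <- optics_config()
  base <- dplyr::bind_cols(tibble::tibble(time = (0:9) / 1.81),
                           tibble::as_tibble(matrix(0, 10, 24),
                                             .name_repair = "minimal"))
  names(base) <- c("time", hybridbci:::nirs_intensity_cols())
  withr::with_seed(4, {
    X <- base; X[-1] <- matrix(rnorm(240), 10)
    Y <- base; Y[-1] <- matrix(rnorm(240), 10)
  })
  lin <- function(od) as.matrix(mbll_invert(od, opt)[-1])
  Z <- base; Z[-1] <- 2 * X[-1] + 3 * Y[-1]
  expect_equal(lin(Z), 2 * lin(X) + 3 * lin(Y), tolerance = 1e-10)
})

test_that("gaussian low-pass keeps DC, kills fast oscillations, smooths noise", {
  rate <- 10
  tt <- (0:999) / rate
  const <- tibble::tibble(time = tt, x = rep(4.2, 1000))
  expect_equal(gaussian_lowpass(const, 0.1, rate = rate)$x, const$x,
               tolerance = 1e-9)

  sine <- tibble::tibble(time = tt, x = sin(2 * pi * 0.9 * tt))
  out <- gaussian_lowpass(sine, 0.1, rate = rate)
  mid <- out$x[100:900]
  expect_lt(max(abs(mid)), 0.05)

  withr::with_seed(6, noise <- tibble::tibble(time = tt, x = rnorm(1000)))
  expect_lt(stats::var(gaussian_lowpass(noise, 0.5, rate = rate)$x),
            stats::var(noise$x))

  expect_error(gaussian_lowpass(sine, 5.1, rate = rate), "cutoff")
})

test_that("the internal wavelet transform reconstructs perfectly", {
  for (fam in c("db1", "db2", "db5")) {
    lo <- hybridbci:::wavelet_filters[[fam]]
    withr::with_seed(8, x <- rnorm(256))
    dec <- hybridbci:::dwt_periodic(x, lo, 4)
    expect_equal(hybridbci:::idwt_periodic(dec, lo), x, tolerance = 1e-9)
  }
})

test_that("wavelet denoising preserves structure and removes noise", {
  tt <- (0:511) / 10
  zero <- tibble::tibble(time = tt, x = numeric(512))
  expect_true(all(wavelet_denoise(zero)$x == 0))

  ramp <- tibble::tibble(time = tt, x = seq(0, 1, length.out = 512))
  out <- wavelet_denoise(ramp, family = "db5", level = 4)
  expect_lt(max(abs(out$x - ramp$x)), 1e-8)

  clean <- ifelse(tt > 15 & tt < 35, 1, 0)
  clean <- gaussian_lowpass(tibble::tibble(time = tt, x = clean), 0.3,
                            rate = 10)$x
  withr::with_seed(10, noisy <- clean + rnorm(512, sd = 0.2))
  den <- wavelet_denoise(tibble::tibble(time = tt, x = noisy))$x
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(den, clean), rmse(noisy, clean))

  expect_error(wavelet_denoise(tibble::tibble(time = 1:8, x = rnorm(8)),
                               level = 4), "too short|Series too short")
})

test_that("window features average HbO/HbR over time and channels", {
  tt <- (0:99) / 1.81
  h <- new_hemo(tt, matrix(2, 100, 12), matrix(-0.5, 100, 12), 1.81)
  f <- nirs_features(h, tibble::tibble(start = 10, end = 20))
  expect_equal(f$nirs_mean_hbo, 2)
  expect_equal(f$nirs_mean_hbr, -0.5)

  # antisymmetric segments average to zero
  x <- rep(c(1, -1), each = 50)
  h2 <- new_hemo(tt, matrix(x, 100, 12), matrix(x, 100, 12), 1.81)
  f2 <- nirs_features(h2, tibble::tibble(start = 0, end = 100 / 1.81))
  expect_equal(f2$nirs_mean_hbo, 0)

  expect_error(nirs_features(h, tibble::tibble(start = 10, end = 20),
                             channels = integer(0)), "Empty channel")
  expect_error(nirs_features(h, tibble::tibble(start = 500, end = 510)),
               "no samples")
})

test_that("the preprocessing chain preserves length and rate", {
  rec <- default_session()
  hemo <- preprocess_nirs(rec)
  expect_equal(nrow(hemo), nrow(rec$nirs))
  expect_equal(attr(hemo, "rate"), rec$meta$nirs_rate)
  expect_equal(names(hemo), c("time", hybridbci:::hemo_cols()))
})

test_that("the full chain recovers ground-truth HbO with high correlation", {
  cors <- sapply(1:5, function(seed) {
    rec <- simulate_session(2, sim_config(seed = seed))
    hemo <- preprocess_nirs(rec)
    stats::cor(rowMeans(hybridbci:::hemo_matrix(hemo, "hbo")),
               rowMeans(hybridbci:::hemo_matrix(rec$ground_truth, "hbo")))
  })
  expect_true(all(cors > 0.9))
})
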