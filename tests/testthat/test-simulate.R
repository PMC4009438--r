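test_that("tap events tile the block at the tapping frequency", {
  blk <- single_tap_schedule()[2, ]
  expect_equal(length(simulate_taps(blk, sim_config())), 10)
  expect_equal(length(simulate_taps(blk, sim_config(tap_rate = 0.5))), 5)
  blk35 <- tibble::tibble(onset = 35, duration = 10, trial_type = "tap_left")
  times <- simulate_taps(blk35, sim_config())
  expect_equal(times, 35:44)
  expect_error(simulate_taps(tibble::tibble(onset = 0, duration = 5,
                                            trial_type = "rest"),
                             sim_config()),
               "tapping block")
})

test_that("tap bursts go only to the contralateral motor channel", {
  cfg <- quiet_config()
  sim <- simulate_eeg(single_tap_schedule("tap_left"), cfg)
  quiet_chans <- setdiff(eeg_channels, "C4")
  expect_true(all(as.matrix(sim$data[quiet_chans]) == 0))
  expect_gt(max(abs(sim$data$C4)), 10)
  sim_r <- simulate_eeg(single_tap_schedule("tap_right"), cfg)
  expect_true(all(sim_r$data$C4 == 0))
  expect_gt(max(abs(sim_r$data$C3)), 5)
})

test_that("simulators are bit-identical for a fixed seed", {
  cfg <- sim_config(seed = 7)
  s <- build_session(1)
  expect_identical(simulate_eeg(s, cfg), simulate_eeg(s, cfg))
  expect_identical(simulate_hemodynamics(s, cfg), simulate_hemodynamics(s, cfg))
  tr <- simulate_hemodynamics(s, cfg)
  expect_identical(forward_mbll(tr, optics_config(), cfg),
                   forward_mbll(tr, optics_config(), cfg))
})

test_that("beta band power at C4 rises during left tapping across seeds", {
  s <- single_tap_schedule("tap_left")
  band_var <- function(x) stats::var(x)
  wins <- 0
  for (seed in 1:20) {
    sim <- simulate_eeg(s, sim_config(seed = seed))
    bp <- bandpass_beta(sim$data, 256)
    tap <- bp$C4[sim$data$time >= 5 & sim$data$time < 15]
    rest <- bp$C4[sim$data$time >= 16 & sim$data$time < 20]
    wins <- wins + (band_var(tap) > band_var(rest))
  }
  expect_equal(wins, 20)
})

test_that("hemodynamics are silent without stimulation and causal with it", {
  cfg <- sim_config(seed = 1)
  h0 <- simulate_hemodynamics(rest_only_schedule(), cfg)
  expect_true(all(as.matrix(h0[-1]) == 0))

  s <- build_session(1)
  h <- simulate_hemodynamics(s, cfg)
  hbo <- rowMeans(as.matrix(h[paste0(sprintf("ch%02d", 1:12), "_hbo")]))
  first_mental <- min(s$onset[startsWith(s$trial_type, "mental")])
  expect_true(all(hbo[h$time <= first_mental + cfg$onset_lag] == 0))
  expect_gt(h$time[which.max(hbo)], first_mental + cfg$onset_lag)
})

test_that("the block response settles below 5% of peak by task end + settle_time", {
  cfg <- sim_config()
  resp <- hybridbci:::block_response_fun(cfg)
  tt <- seq(0, 40, by = 0.05)
  r <- resp(tt)
  after_settle <- tt >= 10 + cfg$settle_time
  expect_lt(max(r[after_settle]), 0.05 * max(r))
})

test_that("the forward optical model obeys the Beer-Lambert structure", {
  opt <- optics_config()
  tt <- (0:49) / 1.81
  zero <- new_hemo(tt, matrix(0, 50, 12), matrix(0, 50, 12), 1.81)
  I <- forward_mbll(zero, opt, cfg = NULL)
  for (wl in 1:2) {
    cols <- grep(paste0("_", opt$wavelengths[wl]), names(I))
    expect_equal(unname(as.matrix(I[cols])),
                 matrix(opt$I_in[wl] * exp(-opt$A0[wl]), 50, 12))
  }

  withr::with_seed(11, {
    hbo <- matrix(rnorm(50 * 12), 50); hbr <- matrix(rnorm(50 * 12), 50)
  })
  tr <- new_hemo(tt, hbo, hbr, 1.81)
  # doubling l doubles the optical-density excursion (linearity in path length)
  I1 <- forward_mbll(tr, optics_config(l = 3), NULL)
  I2 <- forward_mbll(tr, optics_config(l = 6), NULL)
  dA1 <- log(opt$I_in[1] * exp(-opt$A0[1])) - log(as.matrix(I1[seq(2, 25, 2)]))
  dA2 <- log(opt$I_in[1] * exp(-opt$A0[1])) - log(as.matrix(I2[seq(2, 25, 2)]))
  expect_equal(dA2, 2 * dA1, tolerance = 1e-10)

  expect_error(forward_mbll(tr, optics_config(extinction = matrix(1, 2, 2))),
               "singular")
})

test_that("forward model then inversion recovers ground truth exactly", {
  opt <- optics_config(dpf = c(5.5, 6.5))
  tt <- (0:108) / 1.81
  withr::with_seed(3, {
    mk <- function() {
      m <- matrix(rnorm(109 * 12, sd = 2), 109)
      sweep(m, 2, colMeans(m[tt < 5, ]))  # concentration changes from baseline
    }
    tr <- new_hemo(tt, mk(), mk(), 1.81)
  })
  I <- forward_mbll(tr, opt, cfg = NULL)
  rec <- mbll_invert(optical_density(I, opt), opt)
  expect_lt(max(abs(as.matrix(tr[-1]) - as.matrix(rec[-1]))), 1e-9)
})

test_that("a simulated bundle carries the full montage and ground truth", {
  rec <- default_session()
  expect_equal(names(rec$eeg), c("time", eeg_channels))
  expect_equal(ncol(rec$nirs) - 1, 24)
  expect_true(all(as.matrix(rec$nirs[-1]) > 0))
  expect_equal(rec$eeg$time[1], 0)
  expect_equal(rec$nirs$time[1], 0)
  expect_equal(nrow(rec$meta$montage), 12)
  expect_s3_class(rec$ground_truth, "bci_hemo")
  expect_equal(nrow(rec$taps), 5 * 2 * 10)
})

test_that("mental-block HbO exceeds rest HbO in nearly all seeds", {
  wins <- 0
  n_seeds <- 100
  opt <- optics_config()
  s <- build_session(1)
  wa <- epoch_windows(s, "nirs")
  wr <- rest_windows(s, "nirs")
  for (seed in seq_len(n_seeds)) {
    cfg <- sim_config(seed = seed)
    tr <- simulate_hemodynamics(s, cfg)
    I <- forward_mbll(tr, opt, cfg)
    hemo <- gaussian_lowpass(mbll_invert(optical_density(I, opt), opt))
    task <- mean(sapply(seq_len(nrow(wa)), function(i)
      nirs_features(hemo, wa[i, ])$nirs_mean_hbo))
    rest <- mean(sapply(seq_len(nrow(wr)), function(i)
      nirs_features(hemo, wr[i, ])$nirs_mean_hbo))
    wins <- wins + (task > rest)
  }
  expect_gte(wins, 95)
})
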