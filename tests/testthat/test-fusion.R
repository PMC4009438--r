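test_that("a 300-s session synchronizes to 543 frames on the decision grid", {
  nirs <- tibble::tibble(time = (0:542) / 1.81, hbo = 0, hbr = 0)
  eeg <- tibble::tibble(time = numeric(), channel = character(),
                        amplitude = numeric())
  fr <- synchronize(eeg, nirs, common_rate = 1.81, extent = 300)
  expect_equal(nrow(fr), 543)
  expect_equal(fr$time, (1:543) / 1.81)
  expect_true(all(abs(fr$time - seq_len(543) / 1.81) < 0.5 / 1.81))
})

test_that("already-framed streams pass through synchronization unchanged", {
  tk <- (1:100) / 1.81
  eeg <- tibble::tibble(time = tk, eeg_c3_meanpeak = sin(tk),
                        eeg_c4_meanpeak = cos(tk))
  nirs <- tibble::tibble(time = tk, hbo = tk / 100, hbr = -tk / 200)
  fr <- synchronize(eeg, nirs, common_rate = 1.81, extent = 100 / 1.81)
  expect_equal(nrow(fr), 100)
  expect_equal(fr$eeg_c3_meanpeak, eeg$eeg_c3_meanpeak)
  expect_equal(fr$eeg_c4_meanpeak, eeg$eeg_c4_meanpeak)
  expect_equal(fr$nirs_mean_hbo, nirs$hbo)
  expect_equal(fr$nirs_mean_hbr, nirs$hbr)
})

test_that("frames are causal: truncating the streams preserves the past", {
  withr::with_seed(21, {
    peaks <- tibble::tibble(time = sort(runif(40, 0, 100)),
                            channel = sample(c("C3", "C4"), 40, TRUE),
                            amplitude = runif(40, 5, 20))
  })
  nirs <- tibble::tibble(time = (0:180) / 1.81,
                         hbo = cumsum(rnorm(181, sd = 0.01)), hbr = 0)
  full <- synchronize(peaks, nirs, extent = 100)
  t_cut <- 60
  part <- synchronize(peaks[peaks$time <= t_cut, ],
                      nirs[nirs$time <= t_cut, ], extent = t_cut)
  keep <- full$time <= t_cut
  expect_equal(part, full[keep, ])
})

test_that("the command truth table matches the five-command design", {
  expect_equal(decode_command("rest", "rest")$command, "Stop")
  expect_equal(decode_command("left_hand", "rest")$command, "Left")
  expect_equal(decode_command("right_hand", "rest")$command, "Right")
  expect_equal(decode_command("rest", "arithmetic")$command, "Back")
  expect_equal(decode_command("rest", "counting")$command, "Forward")
  conf <- decode_command("left_hand", "counting")
  expect_equal(conf$command, "Stop")
  expect_true(conf$conflict)
  # the crossed-hand reading is available as a switch
  expect_equal(decode_command("left_hand", "rest", "crossed")$command, "Right")
  # vectorised and total: exactly one command per frame
  out <- decode_command(c("rest", "left_hand", "rest"),
                        c("rest", "rest", "counting"))
  expect_equal(out$command, c("Stop", "Left", "Forward"))
  expect_equal(nrow(out), 3)
})

test_that("activity states fall back to rest at baseline and for huge k", {
  frames <- tibble::tibble(time = (1:10) / 1.81,
                           eeg_c3_meanpeak = 1, eeg_c4_meanpeak = 1,
                           nirs_mean_hbo = 0.5, nirs_mean_hbr = -0.1,
                           nirs_slope = 0.01)
  baselines <- list(eeg = list(mean = 1, sd = 0.2),
                    nirs = list(mean = 0.5, sd = 0.1))
  d <- gaussian_classes(seed = 2)
  dummy <- fit_lda(d$x, d$labels)
  models <- list(eeg_lr = dummy, nirs_ac = dummy)
  st <- activity_state(frames, baselines, models)
  expect_true(all(st$eeg_state == "rest"))
  expect_true(all(st$nirs_state == "rest"))

  frames2 <- dplyr::mutate(frames, eeg_c4_meanpeak = 50, nirs_mean_hbo = 50)
  st2 <- activity_state(frames2, baselines, models, k = 1e12)
  expect_true(all(st2$eeg_state == "rest"))
  expect_true(all(st2$nirs_state == "rest"))

  expect_error(activity_state(frames, list(eeg = NULL, nirs = NULL), models),
               "baseline")
})

test_that("a noise-free session decodes every block and stops on rest", {
  cfg <- quiet_config(seed = 1)
  rec <- simulate_session(2, cfg)
  models <- train_models(rec)
  dec <- decode_session(rec, models)
  expect_equal(dec$block_accuracy, 100)
  expect_equal(dec$blocks$decoded, dec$blocks$intended)
  rest <- dec$frames[dec$frames$truth == "Stop", ]
  expect_true(all(rest$command == "Stop"))
  # any simultaneous-activity conflicts must have resolved to Stop
  expect_true(all(dec$frames$command[dec$frames$conflict] == "Stop"))
})

test_that("a rest-only recording decodes to Stop on every frame", {
  cfg <- quiet_config(seed = 2)
  # physically rest-only: a valid schedule but with no task activity injected
  rec <- simulate_session(1, cfg)
  silent_cfg <- cfg
  sim <- simulate_eeg(rest_only_schedule(60), silent_cfg)
  rec$eeg <- sim$data
  rec$taps <- sim$taps
  truth0 <- simulate_hemodynamics(rest_only_schedule(60), silent_cfg)
  rec$nirs <- forward_mbll(truth0, optics_config(), silent_cfg)
  rec$ground_truth <- truth0
  models <- train_models(simulate_session(1, quiet_config(seed = 3)))
  dec <- decode_session(rec, models)
  expect_true(all(dec$frames$command == "Stop"))
})

test_that("decoding at default noise stays accurate across seeds", {
  accs <- sapply(4:6, function(seed) {
    rec <- simulate_session(2, sim_config(seed = seed))
    dec <- decode_session(rec, train_models(rec))
    dec$block_accuracy
  })
  expect_true(all(accs >= 80))
})

test_that("trained state models separate hands and mental tasks", {
  rec <- default_session()
  models <- train_models(rec)
  expect_s3_class(models$eeg_lr, "bci_lda")
  expect_equal(sort(models$eeg_lr$levels), c("left", "right"))
  expect_equal(sort(models$nirs_ac$levels), c("arithmetic", "counting"))
  expect_true(models$baselines$nirs$sd >= 0)
})

test_that("command streams serialize with states and conflict flags", {
  rec <- default_session()
  dec <- cached("decoded_default", decode_session(rec, train_models(rec)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_commands(dec, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(names(back),
               c("time", "eeg_state", "nirs_state", "command", "conflict_flag"))
  expect_equal(nrow(back), nrow(dec$frames))
  expect_true(all(back$command %in% commands))
})
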