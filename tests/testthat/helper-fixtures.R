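# Shared fixtures, all generated in code.

# noise-free simulator settings (trial-to-trial gain/amplitude variability
# stays on; "noise-free" means no measurement or background noise)
quiet_config <- function(seed = 0, ...) {
  sim_config(seed = seed, eeg_noise = 0, cardiac_amp = 0, resp_amp = 0,
             mayer_amp = 0, od_noise = 0, drift_amp = 0, ...)
}

# minimal schedule holding one tapping block between rest periods
single_tap_schedule <- function(hand = "tap_left") {
  tibble::tibble(onset = c(0, 5, 15), duration = c(5, 10, 5),
                 trial_type = c("rest", hand, "rest"))
}

# a schedule made only of rest blocks (not a valid paradigm sample; used to
# exercise the no-stimulus paths of the simulators)
rest_only_schedule <- function(total = 60) {
  n <- total / 5
  tibble::tibble(onset = 5 * (seq_len(n) - 1), duration = 5,
                 trial_type = "rest")
}

# cache expensive objects across tests within a run
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) {
    assign(key, force(expr), .fixture_cache)
  }
  get(key, .fixture_cache)
}

default_session <- function(seed = 0, n_samples = 5) {
  cached(sprintf("session_%d_%d", seed, n_samples),
         simulate_session(n_samples, sim_config(seed = seed)))
}

# random two-class Gaussian feature set
gaussian_classes <- function(n_per = 20, p = 2, delta = 2, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(stats::rnorm(n_per * p), n_per),
               matrix(stats::rnorm(n_per * p, mean = delta), n_per))
    colnames(x) <- paste0("f", seq_len(p))
    list(x = x, labels = rep(c("rest", "active"), each = n_per))
  })
}
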