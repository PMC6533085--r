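# Shared fixtures for the test suite. Sweeps are generated in code; a
# reduced sampling rate (12.5 kHz, still >= 5 samples per kernel rise
# constant) is used where many sweeps are rendered.

fast_protocol <- function(n_pulses = 10, n_trains = 10, frequency = 100) {
  stimulus_protocol(n_pulses = n_pulses, frequency = frequency,
                    n_trains = n_trains, sampling_rate = 12500)
}

# Pure-noise sweep (no stimuli rendered): one nominal stimulus at t = 0.
noise_sweep <- function(sigma, seed, sampling_rate = 12500, post_ms = 20) {
  dt <- 1000 / sampling_rate
  tb <- seq(-300, post_ms, by = dt)
  set.seed(seed)
  sweep_recording(tb, rnorm(length(tb), 0, sigma), stimulus_times = 0,
                  sampling_rate = sampling_rate)
}

# Small deterministic train-features object for QC-rule tests.
fake_features <- function(charges, failures) {
  structure(list(
    charges = charges, failures = failures,
    mean_charge = colMeans(charges),
    median_charge = apply(charges, 2, stats::median),
    failure_rate = colMeans(failures),
    success_rate_1 = 1 - mean(failures[, 1]),
    ppr = colMeans(charges)[2] / colMeans(charges)[1],
    n_trains = nrow(charges), low_n = nrow(charges) < 7
  ), class = "epsc_train_features")
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
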