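# Charge extraction, failure detection and minimal-stimulation QC.

test_that("noise SD is recovered from the baseline window", {
  sw <- noise_sweep(sigma = 5, seed = 1, sampling_rate = 50000)
  expect_equal(estimate_noise_sigma(sw), 5, tolerance = 0.02)
  flat <- sweep_recording(seq(-300, 20, by = 0.02),
                          rep(0, length(seq(-300, 20, by = 0.02))),
                          stimulus_times = 0)
  expect_identical(estimate_noise_sigma(flat), 0)
  # round trip through the generator
  params <- quantal_synapse_params(4, 0.5, 100, noise_sigma = 2.5)
  sw2 <- render_sweep(rep(0, 10), params, stimulus_protocol(), seed = 4)
  expect_equal(estimate_noise_sigma(sw2), 2.5, tolerance = 0.05)
})

test_that("failure detection thresholds at k times sigma", {
  params <- quantal_synapse_params(1, 0.5, 100, noise_sigma = 0)
  protocol <- stimulus_protocol()
  sigma <- quantal_peak_amplitude(params) / 10     # peak = 10 sigma
  sw <- render_sweep(c(1, rep(0, 9)), params, protocol, seed = 1)
  expect_false(detect_failure(sw, 1, sigma = sigma))
  expect_true(detect_failure(sw, 2, sigma = sigma))  # no event at stimulus 2
  # peak of exactly 2 sigma stays below the 3-sigma threshold
  sigma_big <- quantal_peak_amplitude(params) / 2
  expect_true(detect_failure(sw, 1, sigma = sigma_big))
  expect_error(detect_failure(sw, 11, sigma = sigma), "out of range")
  expect_error(detect_failure(sw, 1, sigma = 0), "sigma")
})

test_that("noise-only sweeps are declared failures at the null-oracle rate", {
  sigma <- 2
  sr <- 12500
  n_mc <- 10000
  declared <- vapply(seq_len(n_mc), function(i) {
    detect_failure(noise_sweep(sigma, seed = 20000 + i, sampling_rate = sr),
                   1, sigma = sigma)
  }, logical(1))
  rate <- mean(declared)
  expect_gte(rate, 0.95)
  # independent Monte-Carlo oracle: fresh noise draws, same decision rule
  # (0.5 ms boxcar smoothing, negative peak in the 1-9 ms window vs 3 sigma)
  width <- round(0.5 * sr / 1000)
  dt <- 1000 / sr
  win <- seq(round(1 / dt), round(9 / dt)) + 1L
  set.seed(999)
  oracle <- mean(vapply(seq_len(n_mc), function(i) {
    x <- rnorm(round(10 / dt) + 1L, 0, sigma)
    sm <- as.numeric(stats::filter(x, rep(1 / width, width), sides = 2))
    -min(sm[win], na.rm = TRUE) <= 3 * sigma
  }, logical(1)))
  expect_lt(abs(rate - oracle), 0.02)
})

test_that("failure detection is invariant to a constant baseline offset", {
  params <- quantal_synapse_params(2, 0.5, 80, noise_sigma = 1)
  sw <- render_sweep(c(1, 0, 2, rep(0, 7)), params, stimulus_protocol(),
                     seed = 3)
  sigma <- estimate_noise_sigma(sw)
  shifted <- sw
  shifted$current <- sw$current + 37.5
  for (i in c(1, 2, 3)) {
    expect_identical(detect_failure(shifted, i, sigma = sigma),
                     detect_failure(sw, i, sigma = sigma))
  }
  # charge integration is also baseline-invariant
  expect_equal(integrate_epsc_charge(shifted, 1), integrate_epsc_charge(sw, 1),
               tolerance = 1e-6)
})

test_that("charge integration is linear and conserves charge across windows", {
  params <- quantal_synapse_params(4, 0.5, 100, noise_sigma = 0)
  protocol <- stimulus_protocol()
  sw <- render_sweep(c(2, 1, rep(0, 8)), params, protocol, seed = 1)
  # scaling the trace scales the integral
  scaled <- sw
  scaled$current <- 3 * sw$current
  expect_equal(integrate_epsc_charge(scaled, 1),
               3 * integrate_epsc_charge(sw, 1), tolerance = 1e-10)
  # the decay tail crossing the window boundary is conserved: the two
  # window integrals sum to the total integral of the trace
  total <- -pracma::trapz(sw$time_base, sw$current)
  split_sum <- integrate_epsc_charge(sw, 1) + integrate_epsc_charge(sw, 2) +
    sum(vapply(3:10, function(i) integrate_epsc_charge(sw, i), 0))
  expect_equal(split_sum, total, tolerance = 0.005)
  # flat zero trace has zero charge
  flat <- render_sweep(rep(0, 10), params, protocol, seed = 1)
  expect_identical(integrate_epsc_charge(flat, 5), 0)
})

test_that("train features aggregate charges, failures and PPR", {
  params <- quantal_synapse_params(4, 0.5, 100, noise_sigma = 0)
  protocol <- stimulus_protocol(n_trains = 10)
  sw <- render_sweep(c(2, 3, rep(1, 8)), params, protocol, seed = 1)
  feats <- compute_train_features(rep(list(sw), 10))
  # identical noiseless sweeps: median = mean = single-sweep charges
  expect_equal(feats$median_charge, feats$mean_charge, tolerance = 1e-12)
  expect_equal(feats$mean_charge,
               vapply(1:10, function(i) integrate_epsc_charge(sw, i), 0),
               tolerance = 1e-12)
  # PPR is the ratio of aggregated charges (3 quanta vs 2 quanta ~ 1.5,
  # up to the small decay tail crossing the window boundary)
  expect_equal(feats$ppr, 1.5, tolerance = 0.01)
  expect_identical(feats$n_trains, 10L)
  expect_false(feats$low_n)
  expect_warning(compute_train_features(rep(list(sw), 6)), "low_n")
})

test_that("median aggregation is invariant to train order", {
  params <- make_class_archetype("C2", seed = 1)
  sweeps <- simulate_synapse_sweeps(params, fast_protocol(), seed = 5)
  f1 <- compute_train_features(sweeps)
  f2 <- compute_train_features(rev(sweeps))
  expect_equal(f1$median_charge, f2$median_charge, tolerance = 1e-12)
  expect_equal(f1$failure_rate, f2$failure_rate, tolerance = 1e-12)
})

test_that("detector recovers the generator failure rate for a uniquantal synapse", {
  # constant-probability uniquantal synapse: near-instant refill, no
  # facilitation, p = 0.7 -> failure rate 0.3 at every stimulus
  params <- quantal_synapse_params(1, 0.7, 100, facil_increment = 0,
                                   tau_recovery = 0.5, reluctant_gain = 1)
  params$noise_sigma <- quantal_peak_amplitude(params) / 10
  protocol <- fast_protocol(n_trains = 300)
  feats <- compute_train_features(
    simulate_synapse_sweeps(params, protocol, seed = 8))
  se <- sqrt(0.3 * 0.7 / 300)
  expect_true(all(abs(feats$failure_rate - 0.3) < 3 * se))
})

test_that("minimal-stimulation QC applies the acceptance rules", {
  good <- fake_features(
    charges = matrix(c(rep(100, 10), rep(150, 10)), ncol = 2),
    failures = matrix(c(rep(FALSE, 10), rep(FALSE, 10)), ncol = 2)
  )
  qc <- minimal_stimulation_qc(list(good))
  expect_true(qc$verdicts$accepted[1])
  expect_identical(qc$verdicts$rejection_codes[1], "")

  # one aberrant train PPR (> 4) -> code v
  ch <- matrix(c(rep(100, 10), rep(150, 10)), ncol = 2)
  ch[4, 2] <- 450
  qc_v <- minimal_stimulation_qc(list(fake_features(ch, good$failures)))
  expect_false(qc_v$verdicts$accepted[1])
  expect_match(qc_v$verdicts$rejection_codes[1], "v")

  # high failure rate at stimulus 1 with no decrease at stimulus 2 -> iii
  fl <- matrix(FALSE, 10, 2)
  fl[1:4, 1] <- TRUE
  fl[1:4, 2] <- TRUE
  qc_iii <- minimal_stimulation_qc(list(fake_features(good$charges, fl)))
  expect_false(qc_iii$verdicts$accepted[1])
  expect_match(qc_iii$verdicts$rejection_codes[1], "iii")

  # a 5-fold outlier charge at stimulus 1 -> iv
  ch_iv <- matrix(c(rep(100, 10), rep(150, 10)), ncol = 2)
  ch_iv[7, 1] <- 600
  qc_iv <- minimal_stimulation_qc(list(fake_features(ch_iv, good$failures)))
  expect_match(qc_iv$verdicts$rejection_codes[1], "iv")

  # lowest accepted intensity is chosen
  qc_multi <- minimal_stimulation_qc(
    list(fake_features(ch, good$failures), good, good),
    intensities = c(10, 20, 30))
  expect_identical(qc_multi$chosen_intensity, 20)
  expect_error(minimal_stimulation_qc(list()), "no intensities")
})
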