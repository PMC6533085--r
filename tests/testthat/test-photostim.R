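# Photostimulation analyses: charge binning, PSTH, latency coupling and
# time-course classification.

test_that("binned charge conserves the quantal charge of a single kernel", {
  params <- quantal_synapse_params(1, 1, 120, noise_sigma = 0)
  ep <- simulate_photostim_episode(params,
                                   gc_burst(n_spikes = 1, onset_jitter = 0,
                                            spike_jitter = 0),
                                   seed = 1)
  course <- bin_charge_time_course(ep$sweep)
  expect_equal(sum(course$charge_per_bin), 120, tolerance = 0.01)
  expect_lt(course$delay_to_epsc_peak, 20)
  expect_identical(length(course$charge_per_bin), 20L)
})

test_that("binning localizes a late kernel and validates its arguments", {
  # single quantum at ~80 ms: a slow burst whose first (only) spike is late
  params <- quantal_synapse_params(1, 1, 120, noise_sigma = 0)
  dt <- 0.02
  tb <- seq(-300, 150, by = dt)
  cur <- numeric(length(tb))
  onset_i <- which.min(abs(tb - 80))
  tail_i <- onset_i + seq_len(min(4000, length(tb) - onset_i))
  cur[tail_i] <- -120 * (exp(-(tb[tail_i] - 80) / 2) -
                           exp(-(tb[tail_i] - 80) / 0.4)) / 1.6
  sw <- sweep_recording(tb, cur, stimulus_times = 80)
  course <- bin_charge_time_course(sw)
  expect_gte(course$delay_to_epsc_peak, 80)
  expect_lte(course$delay_to_epsc_peak, 90)
  # flat zero trace: all bins zero
  flat <- sweep_recording(tb, numeric(length(tb)), stimulus_times = 0)
  c0 <- bin_charge_time_course(flat)
  expect_true(all(c0$charge_per_bin == 0))
  expect_error(bin_charge_time_course(sw, span = 97), "multiple")
  expect_error(bin_charge_time_course(sw, span = 10000), "cover")
})

test_that("binned charges are additive under trace superposition", {
  params <- quantal_synapse_params(4, 0.5, 100, noise_sigma = 0)
  ep1 <- simulate_photostim_episode(params, gc_burst(n_spikes = 3), seed = 2)
  ep2 <- simulate_photostim_episode(params, gc_burst(n_spikes = 8), seed = 9)
  both <- ep1$sweep
  both$current <- ep1$sweep$current + ep2$sweep$current
  b <- bin_charge_time_course(both)
  expect_equal(b$charge_per_bin,
               bin_charge_time_course(ep1$sweep)$charge_per_bin +
                 bin_charge_time_course(ep2$sweep)$charge_per_bin,
               tolerance = 1e-9)
})

test_that("photostimulation episodes respect burst edge cases", {
  params <- photostim_archetype("phasic_large")
  expect_error(simulate_photostim_episode(params, gc_burst(), duration = 80),
               "100 ms")
  # zero-spike burst: flat noise, near-zero evoked charge
  p0 <- params
  p0$noise_sigma <- 0
  ep <- simulate_photostim_episode(p0, gc_burst(n_spikes = 0), seed = 4)
  expect_identical(length(ep$spike_times), 0L)
  expect_equal(sum(bin_charge_time_course(ep$sweep)$charge_per_bin), 0)
  expect_error(photostim_archetype("nope"), "unknown class_id")
})

test_that("phasic archetypes peak before tonic archetypes", {
  delays <- vapply(c("phasic_large", "phasic_small", "tonic"), function(cl) {
    params <- photostim_archetype(cl)
    params$noise_sigma <- 0
    courses <- lapply(1:12, function(j) {
      ep <- simulate_photostim_episode(params, gc_burst(), seed = 100 + j)
      bin_charge_time_course(ep$sweep)
    })
    average_charge_time_courses(courses)$delay_to_epsc_peak
  }, 0)
  expect_lt(delays["phasic_large"], delays["tonic"])
  expect_lt(delays["phasic_small"], delays["tonic"])
})

test_that("the PSTH matches deterministic and Poisson oracles", {
  # deterministic raster: one spike at 12 ms in every repeat
  det <- compute_psth(rep(list(12), 50))
  peak_bin <- which.max(det$psth)
  expect_identical(peak_bin, 3L)                  # [10, 15) ms
  expect_equal(det$delay_to_frequency_peak, 12.5)
  expect_equal(det$firing_probability[peak_bin], 1)
  expect_equal(det$baseline_rate, 0)
  # doubling the repeats with identical rasters leaves the PSTH unchanged
  det2 <- compute_psth(rep(list(12), 100))
  expect_equal(det2$psth, det$psth)
  # homogeneous Poisson process at 10 Hz
  rasters <- simulate_mli_spiking(baseline_rate = 10, gain = 0,
                                  n_repeats = 200, seed = 21,
                                  t_start = -500, t_end = 100)
  ff <- compute_psth(rasters)
  lam <- 10 * 0.005                              # expected count/bin/repeat
  se <- sqrt(lam / 200) / 0.005                  # rate-scale SE
  expect_true(all(abs(ff$psth - 10) < 3.5 * se))
  expect_equal(ff$baseline_rate, 10, tolerance = 0.15)
  # empty rasters: flagged, all-zero
  e <- compute_psth(list(numeric(0), numeric(0)))
  expect_true(e$no_evoked_spikes)
  expect_true(all(e$psth == 0))
  expect_true(is.na(e$delay_to_frequency_peak))
})

test_that("spiking simulation is silent with zero rates and couples to charge timing", {
  empty <- simulate_mli_spiking(baseline_rate = 0, gain = 0, n_repeats = 5,
                                seed = 2)
  expect_true(all(lengths(empty) == 0L))
  # homogeneous 10 Hz for 1 s: mean count within 3 SE of 10
  hom <- simulate_mli_spiking(baseline_rate = 10, gain = 0, n_repeats = 100,
                              seed = 5, t_start = 0, t_end = 1000)
  expect_lt(abs(mean(lengths(hom)) - 10), 3 * sqrt(10 / 100))
  # early- vs late-peaking charge input shifts the PSTH peak
  edges <- seq(0, 100, by = 5)
  early <- structure(list(bin_edges = edges,
                          charge_per_bin = c(500, rep(0, 19)), onset = 0,
                          peak_charge = 500, delay_to_epsc_peak = 2.5),
                     class = "charge_time_course")
  late <- structure(list(bin_edges = edges,
                         charge_per_bin = c(rep(0, 17), 500, 0, 0), onset = 0,
                         peak_charge = 500, delay_to_epsc_peak = 87.5),
                    class = "charge_time_course")
  f_early <- compute_psth(simulate_mli_spiking(early, 5, 1, 100, seed = 9))
  f_late <- compute_psth(simulate_mli_spiking(late, 5, 1, 100, seed = 9))
  expect_lt(f_early$delay_to_frequency_peak, f_late$delay_to_frequency_peak)
})

test_that("delay correlation behaves on exact, coupled and null data", {
  x <- c(10, 20, 30, 40, 50)
  expect_equal(correlate_delays(x, 2 * x + 3)$r, 1, tolerance = 1e-12)
  expect_error(correlate_delays(x, rep(5, 5)), "zero variance")
  expect_error(correlate_delays(1:2, 1:2), "3 complete pairs")
  # permutation null: independently shuffled pairs rarely reach |r| > 0.5
  set.seed(15)
  a <- runif(30, 0, 100)
  b <- runif(30, 0, 100)
  exceed <- mean(vapply(1:1000, function(i) {
    abs(correlate_delays(sample(a), b)$r) > 0.5
  }, TRUE))
  expect_lte(exceed, 0.05)
})

test_that("time-course classification recovers planted archetypes", {
  classes <- rep(c("phasic_large", "phasic_small", "tonic"), each = 8)
  courses <- lapply(seq_along(classes), function(i) {
    params <- photostim_archetype(classes[i], seed = 500 + i)
    params$noise_sigma <- 0
    average_charge_time_courses(lapply(1:7, function(j) {
      ep <- simulate_photostim_episode(params, gc_burst(),
                                       seed = (500 + i) * 41 + j)
      bin_charge_time_course(ep$sweep)
    }))
  })
  cls <- classify_time_courses(courses, k = 3, seed = 6)
  expect_equal(ari(classes, cls$labels), 1)
  # single archetype with k = 1: one class, proportion 1
  one <- classify_time_courses(courses[1:8], k = 1, seed = 6)
  expect_equal(one$proportions$reference, 1)
})
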