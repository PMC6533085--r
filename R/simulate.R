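# Stochastic quantal-release simulator.
#
# Model: a synapse carries n_sites independent release sites. A site occupied
# by a fully-releasable vesicle releases on stimulus i with probability
# p_i = min(1, p_fr + F_i), where the facilitation variable F is incremented
# by facil_increment after every stimulus and decays exponentially with
# tau_facil between stimuli. Released sites refill from the reluctant/reserve
# supply as an exponential process with time constant tau_recovery; during
# high-frequency drive (inter-stimulus interval <= 25 ms) the refill rate is
# multiplied by reluctant_gain, expressing recruitment of reluctant vesicles
# by high-frequency trains only. Releases are binomial draws over currently
# occupied sites, so the stimulus-1 failure probability is exactly
# (1 - p_fr)^n_sites.

HF_INTERVAL_MS <- 25

# Facilitation state and release probability per stimulus are deterministic
# given the stimulus times, so they are computed once for all trains.
#' @keywords internal
#' @noRd
release_probabilities <- function(params, stim_times) {
  n <- length(stim_times)
  p <- numeric(n)
  f <- 0
  for (i in seq_len(n)) {
    if (i > 1L) {
      dt <- stim_times[i] - stim_times[i - 1L]
      f <- f * exp(-dt / params$tau_facil)
    }
    p[i] <- min(1, params$p_fr + f)
    f <- f + params$facil_increment
  }
  p
}

# Per-interval refill probability of an empty site.
#' @keywords internal
#' @noRd
refill_probabilities <- function(params, stim_times) {
  n <- length(stim_times)
  if (n <= 1L) return(numeric(0))
  dt <- diff(stim_times)
  gain <- ifelse(dt <= HF_INTERVAL_MS, params$reluctant_gain, 1)
  if (is.infinite(params$tau_recovery)) {
    rep(0, n - 1L)
  } else {
    1 - exp(-dt * gain / params$tau_recovery)
  }
}

#' Simulate quantal release over repeated stimulus trains
#'
#' Draws, for each train, the number of vesicles released at each stimulus of
#' a depletion--facilitation site model (see package vignette). Releases are
#' binomial over occupied sites; occupancy depletes on release and refills
#' between stimuli.
#'
#' @param params a [quantal_synapse_params()] object.
#' @param protocol a [stimulus_protocol()] object (its `frequency` and
#'   `n_pulses` define the stimulus times; the first stimulus is at t = 0).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param n_trains number of independent trains to draw
#'   (`simulate_release_trains` only).
#'
#' @return `simulate_release_train`: an integer vector of released quanta,
#'   one per stimulus, each in `[0, n_sites]`. `simulate_release_trains`:
#'   an integer matrix with one row per train.
#' @examples
#' p <- quantal_synapse_params(n_sites = 4, p_fr = 0.5, q_charge = 100,
#'                             tau_recovery = Inf)
#' simulate_release_train(p, stimulus_protocol(), seed = 1)
#' @export
simulate_release_train <- function(params, protocol, seed) {
  drop(simulate_release_trains(params, protocol, seed, n_trains = 1L))
}

#' @rdname simulate_release_train
#' @export
simulate_release_trains <- function(params, protocol, seed, n_trains) {
  stopifnot(inherits(params, "quantal_synapse_params"),
            inherits(protocol, "stimulus_protocol"))
  check_scalar(seed, "seed", integer = TRUE)
  check_scalar(n_trains, "n_trains", lower = 1, integer = TRUE)
  sim_quanta_at_times(params, protocol_stimulus_times(protocol), seed,
                      n_trains)
}

# Core of the stochastic model at arbitrary (ascending) stimulus times;
# shared by the train and photostimulation simulators.
#' @keywords internal
#' @noRd
sim_quanta_at_times <- function(params, stim_times, seed, n_trains = 1L) {
  p_rel <- release_probabilities(params, stim_times)
  p_ref <- refill_probabilities(params, stim_times)
  n_stim <- length(stim_times)
  quanta <- matrix(0L, nrow = n_trains, ncol = n_stim)
  with_seed(seed, {
    occ <- rep(params$n_sites, n_trains)
    for (i in seq_len(n_stim)) {
      if (i > 1L) {
        occ <- occ + stats::rbinom(n_trains, params$n_sites - occ, p_ref[i - 1L])
      }
      rel <- stats::rbinom(n_trains, occ, p_rel[i])
      occ <- occ - rel
      quanta[, i] <- rel
    }
  })
  quanta
}

#' Expected release and charge profile of a simulated synapse
#'
#' Exact mean of the stochastic model: because the release probabilities are
#' deterministic functions of the stimulus times and both release and refill
#' are linear in site occupancy, the expected occupancy propagates in closed
#' form. `expected_charge_profile` multiplies the expected quanta by the
#' quantal charge.
#'
#' @inheritParams simulate_release_train
#' @return numeric vector, one value per stimulus (expected quanta, or
#'   expected charge in fC).
#' @examples
#' p <- quantal_synapse_params(4, 0.5, 100, tau_recovery = Inf)
#' expected_release_profile(p, stimulus_protocol())
#' @export
expected_release_profile <- function(params, protocol) {
  stopifnot(inherits(params, "quantal_synapse_params"),
            inherits(protocol, "stimulus_protocol"))
  stim_times <- protocol_stimulus_times(protocol)
  p_rel <- release_probabilities(params, stim_times)
  p_ref <- refill_probabilities(params, stim_times)
  n_stim <- length(stim_times)
  occ <- params$n_sites
  out <- numeric(n_stim)
  for (i in seq_len(n_stim)) {
    if (i > 1L) occ <- occ + (params$n_sites - occ) * p_ref[i - 1L]
    out[i] <- occ * p_rel[i]
    occ <- occ - out[i]
  }
  out
}

#' @rdname expected_release_profile
#' @export
expected_charge_profile <- function(params, protocol) {
  expected_release_profile(params, protocol) * params$q_charge
}

# Unit EPSC kernel: difference of exponentials, analytically normalized so
# its time integral is 1 (per ms). Multiplying by q_charge (fC) and the
# quanta count gives a current in pA whose integral over time (ms) is the
# released charge in fC (pA * ms = fC).
#' @keywords internal
#' @noRd
epsc_kernel <- function(t_ms, rise, decay) {
  (exp(-t_ms / decay) - exp(-t_ms / rise)) / (decay - rise)
}

#' Render a voltage-clamp sweep from released quanta
#'
#' Builds a sampled current trace: Gaussian baseline noise plus, at each
#' stimulus time, a negative-going biexponential EPSC scaled by the released
#' quanta. The unit kernel is normalized analytically so that the time
#' integral of a single-quantum EPSC equals `q_charge` (in fC, with current
#' in pA and time in ms).
#'
#' @param quanta integer vector of released quanta, one per stimulus (e.g.
#'   from [simulate_release_train()]).
#' @inheritParams simulate_release_train
#' @param seed integer seed for the noise draw.
#'
#' @return A [sweep_recording()] with ground-truth quanta stored in the
#'   `truth_quanta` field.
#' @examples
#' p <- quantal_synapse_params(4, 0.5, 100, noise_sigma = 0)
#' sw <- render_sweep(c(1, rep(0, 9)), p, stimulus_protocol(), seed = 1)
#' range(sw$current)
#' @export
render_sweep <- function(quanta, params, protocol, seed) {
  stopifnot(inherits(params, "quantal_synapse_params"),
            inherits(protocol, "stimulus_protocol"))
  if (length(quanta) != protocol$n_pulses) {
    stop("length(quanta) must equal protocol$n_pulses", call. = FALSE)
  }
  if (any(quanta < 0) || any(quanta > params$n_sites)) {
    stop("quanta must lie in [0, n_sites]", call. = FALSE)
  }
  dt <- 1000 / protocol$sampling_rate               # sample period, ms
  if (params$kernel_rise / dt < 5) {
    stop("sampling_rate too low to resolve kernel_rise (need >= 5 samples per rise constant)",
         call. = FALSE)
  }
  stim_times <- protocol_stimulus_times(protocol)
  isi <- 1000 / protocol$frequency
  t0 <- -protocol$pre_stimulus_baseline
  t_end <- stim_times[length(stim_times)] + isi
  time_base <- seq(t0, t_end, by = dt)
  n <- length(time_base)
  current <- if (params$noise_sigma > 0) {
    with_seed(seed, stats::rnorm(n, 0, params$noise_sigma))
  } else {
    numeric(n)
  }
  # Kernel support truncated where the decay term falls below exp(-25).
  tail_samples <- ceiling(25 * params$kernel_decay / dt)
  for (i in seq_along(stim_times)) {
    if (quanta[i] == 0) next
    i0 <- round((stim_times[i] - t0) / dt) + 1L
    i1 <- min(n, i0 + tail_samples)
    tau <- time_base[i0:i1] - stim_times[i]
    current[i0:i1] <- current[i0:i1] -
      quanta[i] * params$q_charge * epsc_kernel(tau, params$kernel_rise,
                                                params$kernel_decay)
  }
  sweep_recording(time_base, current, stim_times,
                  sampling_rate = protocol$sampling_rate,
                  baseline_window = c(stim_times[1L] - 300, stim_times[1L]),
                  truth_quanta = as.integer(quanta))
}

#' Simulate all sweeps of one synapse under a train protocol
#'
#' Draws `protocol$n_trains` release trains and renders each as a sweep,
#' with per-train sub-seeds derived deterministically from `seed`.
#'
#' @inheritParams simulate_release_train
#' @return list of [sweep_recording()] objects, one per train.
#' @export
simulate_synapse_sweeps <- function(params, protocol, seed) {
  quanta <- simulate_release_trains(params, protocol, derive_seed(seed, 1L),
                                    n_trains = protocol$n_trains)
  lapply(seq_len(protocol$n_trains), function(j) {
    render_sweep(quanta[j, ], params, protocol, derive_seed(seed, 1L + j))
  })
}
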