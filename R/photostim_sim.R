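# Simulation of photostimulation episodes: a granule-cell burst evoked by
# glutamate uncaging drives the quantal-release model of one synapse, and
# the resulting evoked-charge density can drive interneuron spiking.

#' Describe a granule-cell burst evoked by photostimulation
#'
#' @param n_spikes number of spikes in the burst (>= 0).
#' @param rate intra-burst firing rate, Hz (> 0).
#' @param onset_jitter SD (ms) of the latency of the first spike after the
#'   photostimulation onset.
#' @param spike_jitter SD (ms) of the timing jitter of individual spikes.
#' @return list of class `gc_burst`.
#' @export
gc_burst <- function(n_spikes = 10, rate = 100, onset_jitter = 2,
                     spike_jitter = 0.5) {
  check_scalar(n_spikes, "n_spikes", lower = 0, integer = TRUE)
  check_scalar(rate, "rate", lower = .Machine$double.xmin)
  check_scalar(onset_jitter, "onset_jitter", lower = 0)
  check_scalar(spike_jitter, "spike_jitter", lower = 0)
  structure(list(n_spikes = as.integer(n_spikes), rate = rate,
                 onset_jitter = onset_jitter, spike_jitter = spike_jitter),
            class = "gc_burst")
}

# Photostimulation connection archetypes: phasic-large responses peak right
# at burst onset and depress (high initial p, slow refill); phasic-small
# responses are weaker and peak slightly later; tonic responses facilitate
# and peak late in the burst (fast reluctant-pool recruitment).
PHOTOSTIM_BASE <- list(
  phasic_large = list(n_sites = 15, p_fr = 0.50, q_charge = 50,
                      facil_increment = 0.20, tau_facil = 30,
                      tau_recovery = 300, reluctant_gain = 1.5),
  phasic_small = list(n_sites = 12, p_fr = 0.15, q_charge = 30,
                      facil_increment = 0.30, tau_facil = 50,
                      tau_recovery = 150, reluctant_gain = 2),
  tonic = list(n_sites = 18, p_fr = 0.08, q_charge = 40,
               facil_increment = 0.15, tau_facil = 80,
               tau_recovery = 40, reluctant_gain = 3)
)

#' Parameter set of a photostimulation connection archetype
#'
#' @param class_id `"phasic_large"`, `"phasic_small"` or `"tonic"`.
#' @param genotype `"WT"` or `"KO"` (knockout scales release probability
#'   and site number as in [make_class_archetype()]).
#' @param seed optional integer seed for jitter.
#' @param jitter_sd SD of the log-normal jitter.
#' @return a [quantal_synapse_params()] with attributes `class_id`,
#'   `genotype`.
#' @export
photostim_archetype <- function(class_id, genotype = c("WT", "KO"),
                                seed = NULL, jitter_sd = 0.05) {
  if (!is.character(class_id) || length(class_id) != 1L ||
      !class_id %in% names(PHOTOSTIM_BASE)) {
    stop("unknown class_id; must be phasic_large, phasic_small or tonic",
         call. = FALSE)
  }
  genotype <- match.arg(genotype)
  b <- PHOTOSTIM_BASE[[class_id]]
  if (!is.null(seed) && jitter_sd > 0) {
    jit <- with_seed(seed, exp(stats::rnorm(3, 0, jitter_sd)))
    b$p_fr <- min(0.95, b$p_fr * jit[1L])
    b$q_charge <- b$q_charge * jit[2L]
    if (b$facil_increment > 0) b$facil_increment <- b$facil_increment * jit[3L]
  }
  if (genotype == "KO") {
    b$p_fr <- b$p_fr * KO_P_FACTOR
    b$n_sites <- max(1L, as.integer(floor(b$n_sites * KO_SITE_FACTOR + 0.5)))
  }
  params <- quantal_synapse_params(
    n_sites = b$n_sites, p_fr = b$p_fr, q_charge = b$q_charge,
    facil_increment = b$facil_increment, tau_facil = b$tau_facil,
    tau_recovery = b$tau_recovery, reluctant_gain = b$reluctant_gain
  )
  params$noise_sigma <- quantal_peak_amplitude(params) / 10
  attr(params, "class_id") <- class_id
  attr(params, "genotype") <- genotype
  params
}

#' Simulate one photostimulation episode
#'
#' Draws the granule-cell spike times of a burst, runs the quantal-release
#' dynamics at those spike times, and renders the evoked EPSC trace. The
#' episode must extend at least 100 ms past the photostimulation onset so
#' the downstream 5-ms binning over 0--100 ms fits.
#'
#' @param params a [quantal_synapse_params()] (e.g. from
#'   [photostim_archetype()]).
#' @param burst a [gc_burst()] description.
#' @param seed integer seed.
#' @param duration episode length after the onset, ms (>= 100).
#' @param pre_baseline ms of baseline trace before the onset (>= 300).
#' @param sampling_rate Hz.
#'
#' @return list with `sweep` (a [sweep_recording()]; onset at t = 0),
#'   `spike_times` (GC spike times, ms) and `quanta` (latent released
#'   quanta per spike).
#' @export
simulate_photostim_episode <- function(params, burst = gc_burst(), seed = 1,
                                       duration = 250, pre_baseline = 300,
                                       sampling_rate = 50000) {
  stopifnot(inherits(params, "quantal_synapse_params"),
            inherits(burst, "gc_burst"))
  check_scalar(seed, "seed", integer = TRUE)
  if (duration < 100) {
    stop("episode must cover at least 100 ms post-onset for binning",
         call. = FALSE)
  }
  check_scalar(pre_baseline, "pre_baseline", lower = 300)
  dt <- 1000 / sampling_rate
  if (params$kernel_rise / dt < 5) {
    stop("sampling_rate too low to resolve kernel_rise", call. = FALSE)
  }
  time_base <- seq(-pre_baseline, duration, by = dt)
  n <- length(time_base)
  if (burst$n_spikes == 0L) {
    current <- with_seed(derive_seed(seed, 3L),
                         stats::rnorm(n, 0, params$noise_sigma))
    sweep <- sweep_recording(time_base, current, stimulus_times = 0,
                             sampling_rate = sampling_rate,
                             baseline_window = c(-300, 0))
    return(list(sweep = sweep, spike_times = numeric(0),
                quanta = integer(0)))
  }
  spike_times <- with_seed(derive_seed(seed, 1L), {
    first <- abs(stats::rnorm(1, 0, burst$onset_jitter))
    st <- first + (seq_len(burst$n_spikes) - 1L) * 1000 / burst$rate +
      stats::rnorm(burst$n_spikes, 0, burst$spike_jitter)
    sort(pmax(st, 0))
  })
  # keep spikes strictly inside the episode
  spike_times <- spike_times[spike_times < duration - 5]
  quanta <- drop(sim_quanta_at_times(params, spike_times,
                                     derive_seed(seed, 2L)))
  current <- with_seed(derive_seed(seed, 3L),
                       stats::rnorm(n, 0, params$noise_sigma))
  tail_samples <- ceiling(25 * params$kernel_decay / dt)
  for (i in seq_along(spike_times)) {
    if (quanta[i] == 0) next
    i0 <- min(n, round((spike_times[i] + pre_baseline) / dt) + 1L)
    i1 <- min(n, i0 + tail_samples)
    tau <- time_base[i0:i1] - spike_times[i]
    current[i0:i1] <- current[i0:i1] -
      quanta[i] * params$q_charge * epsc_kernel(pmax(tau, 0),
                                                params$kernel_rise,
                                                params$kernel_decay)
  }
  sweep <- sweep_recording(time_base, current, stimulus_times = spike_times,
                           sampling_rate = sampling_rate,
                           baseline_window = c(-300, 0))
  list(sweep = sweep, spike_times = spike_times,
       quanta = as.integer(quanta))
}

#' Simulate interneuron spiking coupled to an evoked-charge time course
#'
#' Inhomogeneous Poisson point process with instantaneous rate
#' `baseline_rate + gain * charge density` (the charge density in fC/ms is
#' piecewise constant over the bins of the supplied time course, zero
#' outside them). With `gain = 0` the process is homogeneous at the
#' baseline rate. Negative instantaneous rates are clipped to zero and
#' counted in the `n_clipped` attribute.
#'
#' @param course a `charge_time_course` (see [bin_charge_time_course()]),
#'   or `NULL` for a purely homogeneous process.
#' @param baseline_rate baseline firing rate, Hz (>= 0).
#' @param gain spikes per unit charge density, Hz per (fC/ms). May be
#'   negative (inhibitory coupling); rates are clipped at zero.
#' @param n_repeats number of repeats (loose-patch sweeps) to draw (>= 1).
#' @param seed integer seed.
#' @param t_start,t_end raster window, ms (default -500 to 50 ms past the
#'   course span, or 1000 ms for a homogeneous process).
#'
#' @return list of `n_repeats` sorted spike-time vectors (ms), with
#'   attribute `n_clipped`.
#' @export
simulate_mli_spiking <- function(course = NULL, baseline_rate = 10, gain = 0,
                                 n_repeats = 10, seed = 1,
                                 t_start = -500, t_end = NULL) {
  check_scalar(baseline_rate, "baseline_rate", lower = 0)
  check_scalar(n_repeats, "n_repeats", lower = 1, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  if (is.null(t_end)) {
    t_end <- if (is.null(course)) t_start + 1000 else
      max(course$bin_edges) + 50
  }
  dt <- 0.5                                   # ms, rate discretization
  grid <- seq(t_start, t_end - dt, by = dt)
  rate <- rep(baseline_rate, length(grid))
  if (!is.null(course) && gain != 0) {
    stopifnot(inherits(course, "charge_time_course"))
    width <- diff(course$bin_edges[1:2])
    density <- course$charge_per_bin / width    # fC per ms
    bin_of <- findInterval(grid, course$bin_edges,
                           rightmost.closed = FALSE)
    inside <- bin_of >= 1L & bin_of <= length(density) &
      grid < max(course$bin_edges)
    rate[inside] <- rate[inside] + gain * density[bin_of[inside]]
  }
  n_clipped <- sum(rate < 0)
  if (n_clipped > 0) {
    message(sprintf("simulate_mli_spiking: %d rate samples clipped at 0",
                    n_clipped))
    rate <- pmax(rate, 0)
  }
  lambda <- rate * dt / 1000                  # expected spikes per step
  rasters <- with_seed(seed, {
    lapply(seq_len(n_repeats), function(r) {
      counts <- stats::rpois(length(grid), lambda)
      idx <- rep(seq_along(grid), counts)
      if (!length(idx)) return(numeric(0))
      sort(grid[idx] + stats::runif(length(idx), 0, dt))
    })
  })
  attr(rasters, "n_clipped") <- n_clipped
  rasters
}
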