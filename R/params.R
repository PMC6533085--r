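#' Generative parameters of a simulated quantal synapse
#'
#' Describes one synapse under a two-pool quantal-release model: `n_sites`
#' independent release sites, each either occupied by a fusion-competent
#' (fully-releasable) vesicle or empty. On each action potential an occupied
#' site releases with the instantaneous probability; released sites refill
#' from the reluctant/reserve supply with time constant `tau_recovery`, and
#' the refilling rate is multiplied by `reluctant_gain` during high-frequency
#' drive (inter-stimulus intervals of 25 ms or less), expressing the
#' recruitment of reluctant vesicles by high-frequency trains only.
#'
#' @param n_sites integer number of release sites (>= 1).
#' @param p_fr initial release probability of a fully-releasable vesicle per
#'   site per stimulus, in \[0, 1\].
#' @param q_charge quantal charge magnitude in fC (> 0): the time integral of
#'   the EPSC evoked by one released vesicle.
#' @param facil_increment additive increase of release probability contributed
#'   by each preceding stimulus (>= 0, dimensionless).
#' @param tau_facil decay time constant of facilitation, ms (> 0).
#' @param tau_recovery site refilling time constant, ms (> 0). Use `Inf` for
#'   a non-recovering (pure depletion) synapse.
#' @param reluctant_gain multiplier (>= 1) applied to the refilling rate for
#'   inter-stimulus intervals <= 25 ms.
#' @param kernel_rise EPSC kernel rise time constant, ms (> 0).
#' @param kernel_decay EPSC kernel decay time constant, ms (> `kernel_rise`).
#' @param noise_sigma baseline current noise SD in pA (>= 0).
#'
#' @return An object of class `quantal_synapse_params`.
#' @examples
#' p <- quantal_synapse_params(n_sites = 4, p_fr = 0.5, q_charge = 100)
#' p$p_fr
#' @export
quantal_synapse_params <- function(n_sites, p_fr, q_charge,
                                   facil_increment = 0, tau_facil = 40,
                                   tau_recovery = 50, reluctant_gain = 1,
                                   kernel_rise = 0.4, kernel_decay = 2,
                                   noise_sigma = 1) {
  check_scalar(n_sites, "n_sites", lower = 1, integer = TRUE)
  check_scalar(p_fr, "p_fr", lower = 0, upper = 1)
  check_scalar(q_charge, "q_charge", lower = .Machine$double.xmin)
  check_scalar(facil_increment, "facil_increment", lower = 0)
  check_scalar(tau_facil, "tau_facil", lower = .Machine$double.xmin)
  if (!is.numeric(tau_recovery) || length(tau_recovery) != 1L ||
      is.na(tau_recovery) || tau_recovery <= 0) {
    stop("'tau_recovery' must be a single positive number (Inf allowed)",
         call. = FALSE)
  }
  check_scalar(reluctant_gain, "reluctant_gain", lower = 1)
  check_scalar(kernel_rise, "kernel_rise", lower = .Machine$double.xmin)
  check_scalar(kernel_decay, "kernel_decay", lower = .Machine$double.xmin)
  check_scalar(noise_sigma, "noise_sigma", lower = 0)
  if (kernel_decay <= kernel_rise) {
    stop("'kernel_decay' must exceed 'kernel_rise' (biexponential difference)",
         call. = FALSE)
  }
  structure(list(
    n_sites = as.integer(n_sites), p_fr = p_fr, q_charge = q_charge,
    facil_increment = facil_increment, tau_facil = tau_facil,
    tau_recovery = tau_recovery, reluctant_gain = reluctant_gain,
    kernel_rise = kernel_rise, kernel_decay = kernel_decay,
    noise_sigma = noise_sigma
  ), class = "quantal_synapse_params")
}

#' @export
print.quantal_synapse_params <- function(x, ...) {
  cat("Quantal synapse parameters\n")
  cat(sprintf("  sites: %d   p_fr: %.3f   q: %.1f fC\n",
              x$n_sites, x$p_fr, x$q_charge))
  cat(sprintf("  facilitation: +%.3f / tau %.0f ms   recovery: tau %s ms (gain %.1f)\n",
              x$facil_increment, x$tau_facil, format(x$tau_recovery),
              x$reluctant_gain))
  cat(sprintf("  kernel: rise %.2f / decay %.2f ms   noise SD: %.2f pA\n",
              x$kernel_rise, x$kernel_decay, x$noise_sigma))
  invisible(x)
}

#' Stimulation protocol for simulated trains
#'
#' Defaults mirror the minimal-stimulation train protocol used throughout:
#' 10 pulses at 100 Hz, repeated 10 times, with a 300 ms pre-stimulus
#' baseline recorded at 50 kHz.
#'
#' @param n_pulses number of stimuli per train (>= 1).
#' @param frequency intra-train stimulation frequency, Hz (> 0).
#' @param n_trains number of repeated trains (>= 1). Analyses downstream
#'   expect at least 7.
#' @param inter_train_interval seconds between train onsets.
#' @param pre_stimulus_baseline ms of trace recorded before the first
#'   stimulus; must be >= 300 so the noise-estimation window fits.
#' @param sampling_rate sampling rate, Hz.
#'
#' @return An object of class `stimulus_protocol`.
#' @examples
#' stimulus_protocol()
#' @export
stimulus_protocol <- function(n_pulses = 10, frequency = 100, n_trains = 10,
                              inter_train_interval = 60,
                              pre_stimulus_baseline = 300,
                              sampling_rate = 50000) {
  check_scalar(n_pulses, "n_pulses", lower = 1, integer = TRUE)
  check_scalar(frequency, "frequency", lower = .Machine$double.xmin)
  check_scalar(n_trains, "n_trains", lower = 1, integer = TRUE)
  check_scalar(inter_train_interval, "inter_train_interval", lower = 0)
  check_scalar(pre_stimulus_baseline, "pre_stimulus_baseline", lower = 300)
  check_scalar(sampling_rate, "sampling_rate", lower = 1)
  structure(list(
    n_pulses = as.integer(n_pulses), frequency = frequency,
    n_trains = as.integer(n_trains),
    inter_train_interval = inter_train_interval,
    pre_stimulus_baseline = pre_stimulus_baseline,
    sampling_rate = sampling_rate
  ), class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("Stimulus protocol: %d pulses @ %g Hz, %d trains, %g ms baseline, %g kHz\n",
              x$n_pulses, x$frequency, x$n_trains, x$pre_stimulus_baseline,
              x$sampling_rate / 1000))
  invisible(x)
}

# Stimulus times in ms, first stimulus at t = 0.
#' @keywords internal
#' @noRd
protocol_stimulus_times <- function(protocol) {
  (seq_len(protocol$n_pulses) - 1L) * 1000 / protocol$frequency
}
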