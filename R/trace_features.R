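# Per-stimulus EPSC charge extraction, failure detection and
# minimal-stimulation quality control.

# Baseline level of a sweep: mean current over the baseline window.
#' @keywords internal
#' @noRd
sweep_baseline <- function(sweep) {
  i0 <- sweep_index(sweep, sweep$baseline_window[1L])
  i1 <- sweep_index(sweep, sweep$baseline_window[2L])
  mean(sweep$current[i0:i1])
}

#' Estimate the baseline noise SD of a sweep
#'
#' Standard deviation of the baseline-subtracted current over the sweep's
#' baseline window (at least 300 ms preceding the first stimulus).
#'
#' @param sweep a [sweep_recording()].
#' @return noise SD in pA (0 for a constant trace).
#' @export
estimate_noise_sigma <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_recording"))
  i0 <- sweep_index(sweep, sweep$baseline_window[1L])
  i1 <- sweep_index(sweep, sweep$baseline_window[2L])
  if (i1 - i0 < 2L) stop("baseline window outside the trace", call. = FALSE)
  stats::sd(sweep$current[i0:i1])
}

#' Detect a release failure at one stimulus
#'
#' A stimulus is declared a failure when the peak negative deflection of the
#' baseline-subtracted (and lightly smoothed) current within the detection
#' window after the stimulus does not exceed `k` times the baseline noise SD
#' in magnitude. Smoothing (a short moving average, default 0.5 ms) guards
#' the peak search against single-sample noise excursions; the noise SD is
#' always taken from the raw baseline.
#'
#' @param sweep a [sweep_recording()].
#' @param stimulus_index index of the stimulus to test (1-based).
#' @param sigma baseline noise SD in pA; defaults to
#'   [estimate_noise_sigma()] of the sweep. Must be > 0.
#' @param k threshold multiplier (default 3).
#' @param window length-2 numeric, peak-search window in ms after the
#'   stimulus (default `c(1, 9)`; excludes the stimulus-time sample).
#' @param smooth_ms moving-average width in ms applied before the peak
#'   search (0 disables smoothing).
#'
#' @return `TRUE` if the stimulus is a failure, `FALSE` if an EPSC was
#'   detected.
#' @export
detect_failure <- function(sweep, stimulus_index, sigma = NULL, k = 3,
                           window = c(1, 9), smooth_ms = 0.5) {
  stopifnot(inherits(sweep, "sweep_recording"))
  n_stim <- length(sweep$stimulus_times)
  if (stimulus_index < 1L || stimulus_index > n_stim) {
    stop(sprintf("stimulus_index %d out of range [1, %d]",
                 stimulus_index, n_stim), call. = FALSE)
  }
  if (is.null(sigma)) sigma <- estimate_noise_sigma(sweep)
  if (!is.numeric(sigma) || sigma <= 0) {
    stop("'sigma' must be > 0", call. = FALSE)
  }
  all(failure_flags(sweep, sigma = sigma, k = k, window = window,
                    smooth_ms = smooth_ms)[stimulus_index])
}

# Vectorized failure flags for all stimuli of a sweep (single smoothing pass).
#' @keywords internal
#' @noRd
failure_flags <- function(sweep, sigma, k = 3, window = c(1, 9),
                          smooth_ms = 0.5) {
  base <- sweep_baseline(sweep)
  x <- sweep$current - base
  if (smooth_ms > 0) {
    width <- max(1L, round(smooth_ms * sweep$sampling_rate / 1000))
    x <- moving_average(x, width)
  }
  vapply(sweep$stimulus_times, function(st) {
    i0 <- sweep_index(sweep, st + window[1L])
    i1 <- sweep_index(sweep, st + window[2L])
    peak <- -min(x[i0:i1])               # magnitude of the negative peak
    peak <= k * sigma
  }, logical(1L))
}

#' Integrate the EPSC charge evoked by one stimulus
#'
#' Trapezoidal integral of the baseline-subtracted current over the window
#' from the stimulus time to the next stimulus (the last stimulus uses a
#' window of one inter-stimulus interval, or to the end of the trace for a
#' single stimulus). Returned as a magnitude in fC (negative-going EPSCs
#' integrate to positive charges); failures contribute their measured
#' near-zero integral, not an imputed zero.
#'
#' @param sweep a [sweep_recording()].
#' @param stimulus_index index of the stimulus (1-based).
#' @return charge in fC (pA x ms).
#' @export
integrate_epsc_charge <- function(sweep, stimulus_index) {
  stopifnot(inherits(sweep, "sweep_recording"))
  n_stim <- length(sweep$stimulus_times)
  if (stimulus_index < 1L || stimulus_index > n_stim) {
    stop(sprintf("stimulus_index %d out of range [1, %d]",
                 stimulus_index, n_stim), call. = FALSE)
  }
  sweep_charges(sweep)[stimulus_index]
}

# Per-stimulus charges for all stimuli of a sweep (shared baseline pass).
#' @keywords internal
#' @noRd
sweep_charges <- function(sweep) {
  base <- sweep_baseline(sweep)
  st <- sweep$stimulus_times
  n_stim <- length(st)
  isi <- if (n_stim > 1L) st[2L] - st[1L] else
    sweep$time_base[length(sweep$time_base)] - st[1L]
  ends <- c(st[-1L], st[n_stim] + isi)
  vapply(seq_len(n_stim), function(i) {
    i0 <- sweep_index(sweep, st[i])
    i1 <- sweep_index(sweep, ends[i])
    if (i1 - i0 < 2L) stop("integration window shorter than 2 samples",
                           call. = FALSE)
    -pracma::trapz(sweep$time_base[i0:i1], sweep$current[i0:i1] - base)
  }, numeric(1L))
}

#' Aggregate train features of one synapse
#'
#' Extracts per-stimulus, per-train EPSC charges and failure flags from the
#' repeated sweeps of one synapse, and aggregates them: mean and median
#' charge across trains, per-stimulus failure rates, success rate at the
#' first stimulus, and the paired-pulse ratio (PPR) computed on the
#' across-train mean charges.
#'
#' @param sweeps list of [sweep_recording()]s sharing the same stimulus
#'   count (the repeated trains of one synapse). Fewer than 7 sweeps is
#'   flagged (`low_n`), not fatal.
#' @param k failure-detection threshold multiplier (see [detect_failure()]).
#' @param window,smooth_ms passed to the failure detector.
#'
#' @return An object of class `epsc_train_features`: list with `charges`
#'   and `failures` matrices (trains x stimuli), `mean_charge`,
#'   `median_charge`, `failure_rate`, `success_rate_1`, `ppr`, `n_trains`,
#'   `low_n`.
#' @export
compute_train_features <- function(sweeps, k = 3, window = c(1, 9),
                                   smooth_ms = 0.5) {
  if (!length(sweeps) || !all(vapply(sweeps, inherits, TRUE, "sweep_recording"))) {
    stop("'sweeps' must be a non-empty list of sweep_recording objects",
         call. = FALSE)
  }
  n_stim <- length(sweeps[[1L]]$stimulus_times)
  if (!all(vapply(sweeps, function(s) length(s$stimulus_times), 0L) == n_stim)) {
    stop("all sweeps must share the same stimulus count", call. = FALSE)
  }
  n_trains <- length(sweeps)
  low_n <- n_trains < 7L
  if (low_n) {
    warning(sprintf("only %d trains (< 7): features flagged low_n", n_trains),
            call. = FALSE)
  }
  charges <- t(vapply(sweeps, sweep_charges, numeric(n_stim)))
  failures <- t(vapply(sweeps, function(s) {
    failure_flags(s, sigma = estimate_noise_sigma(s), k = k,
                  window = window, smooth_ms = smooth_ms)
  }, logical(n_stim)))
  if (n_stim == 1L) {           # vapply drops to vectors for single stimulus
    charges <- matrix(charges, ncol = 1L)
    failures <- matrix(failures, ncol = 1L)
  }
  mean_charge <- colMeans(charges)
  median_charge <- apply(charges, 2L, stats::median)
  failure_rate <- colMeans(failures)
  ppr <- if (n_stim >= 2L && mean_charge[1L] > 0) {
    mean_charge[2L] / mean_charge[1L]
  } else {
    NA_real_
  }
  structure(list(
    charges = charges, failures = failures,
    mean_charge = mean_charge, median_charge = median_charge,
    failure_rate = failure_rate, success_rate_1 = 1 - failure_rate[1L],
    ppr = ppr, n_trains = n_trains, low_n = low_n
  ), class = "epsc_train_features")
}

#' @export
print.epsc_train_features <- function(x, ...) {
  cat(sprintf("EPSC train features: %d trains x %d stimuli%s\n", x$n_trains,
              ncol(x$charges), if (x$low_n) " [low_n]" else ""))
  cat(sprintf("  EPSC1 mean %.1f fC, failure rate %.2f, PPR %.2f\n",
              x$mean_charge[1L], x$failure_rate[1L], x$ppr))
  invisible(x)
}

#' Minimal-stimulation quality control
#'
#' Applies the minimal-stimulation acceptance rules to the train features
#' measured at each tested stimulation intensity, and selects the lowest
#' accepted intensity. An intensity is rejected with codes:
#' `low_success` -- success rate at stimulus 1 not above 0.4;
#' `i` -- systematic failures at stimulus 1;
#' `ii` -- failure rate increases at stimulus 2;
#' `iii` -- no decrease of the failure rate at stimulus 2 for synapses with
#' a high (0.3--0.6) failure rate at stimulus 1;
#' `iv` -- any train whose stimulus-1 charge exceeds 5x the across-train
#' median;
#' `v` -- any train with a paired-pulse ratio above 4.
#'
#' @param features_by_intensity list of [compute_train_features()] results,
#'   one per tested intensity.
#' @param intensities numeric stimulation intensities (same length);
#'   defaults to the list index.
#'
#' @return list with `verdicts` (data.frame: intensity, accepted,
#'   rejection_codes) and `chosen_intensity` (lowest accepted, or `NA`).
#' @export
minimal_stimulation_qc <- function(features_by_intensity,
                                   intensities = seq_along(features_by_intensity)) {
  if (!length(features_by_intensity)) {
    stop("no intensities supplied", call. = FALSE)
  }
  if (length(intensities) != length(features_by_intensity)) {
    stop("'intensities' must match 'features_by_intensity' in length",
         call. = FALSE)
  }
  codes_list <- lapply(features_by_intensity, function(f) {
    stopifnot(inherits(f, "epsc_train_features"))
    codes <- character(0)
    fr <- f$failure_rate
    if (f$success_rate_1 <= 0.4) codes <- c(codes, "low_success")
    if (fr[1L] >= 1) codes <- c(codes, "i")
    if (length(fr) >= 2L) {
      if (fr[2L] > fr[1L]) codes <- c(codes, "ii")
      if (fr[1L] >= 0.3 && fr[1L] <= 0.6 && fr[2L] >= fr[1L]) {
        codes <- c(codes, "iii")
      }
      c1 <- f$charges[, 1L]
      if (any(c1 > 5 * stats::median(c1))) codes <- c(codes, "iv")
      ok1 <- c1 > 0
      train_ppr <- f$charges[ok1, 2L] / c1[ok1]
      if (any(train_ppr > 4)) codes <- c(codes, "v")
    }
    codes
  })
  accepted <- lengths(codes_list) == 0L
  verdicts <- data.frame(
    intensity = intensities,
    accepted = accepted,
    rejection_codes = vapply(codes_list, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
  chosen <- if (any(accepted)) min(intensities[accepted]) else NA_real_
  list(verdicts = verdicts, chosen_intensity = chosen)
}

#' Extract features and the STP profile matrix of a whole cohort
#'
#' Streams over the synapses of a simulated cohort: renders the sweeps of
#' each synapse, extracts [compute_train_features()], and assembles the
#' profile matrix of aggregated per-stimulus charges (one row per synapse)
#' used by the classification stage.
#'
#' @param cohort an `stp_cohort` from [make_cohort()].
#' @param aggregate `"median"` (default, used for classification) or
#'   `"mean"` per-stimulus aggregate for the profile matrix.
#' @param k,window,smooth_ms failure-detector settings.
#'
#' @return list with `features` (per-synapse list), `profiles` (matrix,
#'   synapses x stimuli), `truth` (character class labels), `table`
#'   (data.frame: synapse_id, class_id, genotype, epsc1_fC, ppr,
#'   failure_rate_1, qc_accepted, qc_codes).
#' @export
cohort_features <- function(cohort, aggregate = c("median", "mean"),
                            k = 3, window = c(1, 9), smooth_ms = 0.5) {
  stopifnot(inherits(cohort, "stp_cohort"))
  aggregate <- match.arg(aggregate)
  n <- length(cohort$synapses)
  features <- vector("list", n)
  for (i in seq_len(n)) {
    sweeps <- synapse_sweeps(cohort, i)
    features[[i]] <- compute_train_features(sweeps, k = k, window = window,
                                            smooth_ms = smooth_ms)
  }
  profiles <- t(vapply(features, function(f) {
    if (aggregate == "median") f$median_charge else f$mean_charge
  }, numeric(cohort$protocol$n_pulses)))
  rownames(profiles) <- vapply(cohort$synapses, `[[`, "", "id")
  qc <- lapply(features, function(f) minimal_stimulation_qc(list(f)))
  tab <- data.frame(
    synapse_id = rownames(profiles),
    class_id = vapply(cohort$synapses, `[[`, "", "class_id"),
    genotype = vapply(cohort$synapses, `[[`, "", "genotype"),
    epsc1_fC = vapply(features, function(f) f$mean_charge[1L], 0),
    ppr = vapply(features, function(f) f$ppr, 0),
    failure_rate_1 = vapply(features, function(f) f$failure_rate[1L], 0),
    qc_accepted = vapply(qc, function(q) q$verdicts$accepted[1L], TRUE),
    qc_codes = vapply(qc, function(q) q$verdicts$rejection_codes[1L], ""),
    stringsAsFactors = FALSE
  )
  list(features = features, profiles = profiles,
       truth = tab$class_id, table = tab)
}
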