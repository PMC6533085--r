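#' A sampled voltage-clamp sweep with stimulus annotations
#'
#' The raw unit of electrophysiology input: one current trace (pA, EPSCs
#' negative-going) on a regular time base (ms), with the stimulus times and
#' a baseline window of at least 300 ms ending at or before the first
#' stimulus, used for noise estimation and baseline subtraction.
#'
#' @param time_base numeric vector of sample times, ms, strictly increasing
#'   and regularly spaced.
#' @param current numeric vector of currents, pA, same length as `time_base`.
#' @param stimulus_times numeric vector of stimulus times, ms, strictly
#'   ascending, all within the trace.
#' @param sampling_rate sampling rate in Hz; defaults to the reciprocal of
#'   the median sample period.
#' @param baseline_window length-2 numeric `(start, end)` in ms; must span at
#'   least 300 ms and end at or before the first stimulus. Defaults to the
#'   300 ms preceding the first stimulus.
#' @param truth_quanta optional integer vector of ground-truth released
#'   quanta per stimulus (simulated sweeps only).
#'
#' @return An object of class `sweep_recording`.
#' @export
sweep_recording <- function(time_base, current, stimulus_times,
                            sampling_rate = NULL, baseline_window = NULL,
                            truth_quanta = NULL) {
  if (length(time_base) != length(current)) {
    stop("'time_base' and 'current' must have the same length", call. = FALSE)
  }
  if (length(time_base) < 2L) stop("trace too short", call. = FALSE)
  if (any(!is.finite(current))) stop("non-finite current values", call. = FALSE)
  if (is.unsorted(stimulus_times, strictly = TRUE)) {
    stop("'stimulus_times' must be strictly ascending", call. = FALSE)
  }
  dt <- stats::median(diff(time_base))
  if (is.null(sampling_rate)) sampling_rate <- 1000 / dt
  if (is.null(baseline_window)) {
    baseline_window <- c(stimulus_times[1L] - 300, stimulus_times[1L])
  }
  if (length(baseline_window) != 2L || diff(baseline_window) < 300 - 1e-9) {
    stop("'baseline_window' must span at least 300 ms", call. = FALSE)
  }
  if (baseline_window[2L] > stimulus_times[1L] + 1e-9) {
    stop("'baseline_window' must end at or before the first stimulus",
         call. = FALSE)
  }
  if (baseline_window[1L] < time_base[1L] - 1e-9 ||
      stimulus_times[length(stimulus_times)] > time_base[length(time_base)]) {
    stop("baseline window or stimuli fall outside the trace", call. = FALSE)
  }
  structure(list(
    time_base = time_base, current = current,
    stimulus_times = stimulus_times, sampling_rate = sampling_rate,
    baseline_window = baseline_window, truth_quanta = truth_quanta
  ), class = "sweep_recording")
}

#' @export
print.sweep_recording <- function(x, ...) {
  cat(sprintf("Sweep recording: %.0f ms at %.1f kHz, %d stimuli\n",
              diff(range(x$time_base)), x$sampling_rate / 1000,
              length(x$stimulus_times)))
  invisible(x)
}

# Index of the sample at (or immediately at/after) time t_ms.
#' @keywords internal
#' @noRd
sweep_index <- function(sweep, t_ms) {
  dt <- 1000 / sweep$sampling_rate
  i <- as.integer(round((t_ms - sweep$time_base[1L]) / dt)) + 1L
  min(max(i, 1L), length(sweep$time_base))
}
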