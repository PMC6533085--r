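# Photostimulation analyses: binned evoked-charge time courses, PSTHs of
# interneuron spiking, and the coupling between charge and firing latencies.

#' Bin the evoked charge time course of a sweep
#'
#' Integrates the baseline-subtracted current magnitude in consecutive bins
#' (default 5 ms) from the stimulation onset to `span` ms post-stimulus.
#' The peak charge is the maximum bin and the delay to EPSC peak is the
#' center of the (earliest) peak bin, measured from the onset.
#'
#' @param sweep a [sweep_recording()] covering `onset + span`.
#' @param onset stimulation onset, ms (default 0).
#' @param bin_width bin width, ms (default 5). `span` must be divisible by
#'   `bin_width`.
#' @param span analysis span after the onset, ms (default 100).
#'
#' @return An object of class `charge_time_course`: list with `bin_edges`
#'   (ms, relative to onset at 0), `charge_per_bin` (fC), `onset`,
#'   `peak_charge` and `delay_to_epsc_peak` (ms).
#' @export
bin_charge_time_course <- function(sweep, onset = 0, bin_width = 5,
                                   span = 100) {
  stopifnot(inherits(sweep, "sweep_recording"))
  check_scalar(bin_width, "bin_width", lower = .Machine$double.xmin)
  check_scalar(span, "span", lower = bin_width)
  n_bins <- span / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    stop("'span' must be an integer multiple of 'bin_width'", call. = FALSE)
  }
  n_bins <- as.integer(round(n_bins))
  if (onset + span > sweep$time_base[length(sweep$time_base)] + 1e-9) {
    stop("trace does not cover onset + span", call. = FALSE)
  }
  base <- sweep_baseline(sweep)
  edges <- onset + bin_width * (0:n_bins)
  idx <- vapply(edges, function(e) sweep_index(sweep, e), 0L)
  # cumulative trapezoid evaluated at the bin edges, then differenced:
  # guarantees that bin charges are additive and sum to the span integral.
  charge <- vapply(seq_len(n_bins), function(b) {
    sel <- idx[b]:idx[b + 1L]
    -pracma::trapz(sweep$time_base[sel], sweep$current[sel] - base)
  }, numeric(1L))
  new_charge_time_course(edges - onset, charge, onset)
}

#' @keywords internal
#' @noRd
new_charge_time_course <- function(bin_edges, charge_per_bin, onset) {
  peak_bin <- which.max(charge_per_bin)      # earliest bin on ties
  structure(list(
    bin_edges = bin_edges, charge_per_bin = charge_per_bin, onset = onset,
    peak_charge = charge_per_bin[peak_bin],
    delay_to_epsc_peak = (bin_edges[peak_bin] + bin_edges[peak_bin + 1L]) / 2
  ), class = "charge_time_course")
}

#' @export
print.charge_time_course <- function(x, ...) {
  cat(sprintf("Charge time course: %d bins of %g ms, peak %.1f fC at %.1f ms\n",
              length(x$charge_per_bin), diff(x$bin_edges[1:2]),
              x$peak_charge, x$delay_to_epsc_peak))
  invisible(x)
}

#' Average charge time courses over repeated sweeps
#'
#' Element-wise mean of the per-bin charges over at least one (typically
#' >= 7) repeated episodes sharing the same binning; peak and delay are
#' recomputed on the averaged course.
#'
#' @param courses list of `charge_time_course` objects with identical bins.
#' @return a `charge_time_course`.
#' @export
average_charge_time_courses <- function(courses) {
  if (!length(courses) ||
      !all(vapply(courses, inherits, TRUE, "charge_time_course"))) {
    stop("'courses' must be a non-empty list of charge_time_course objects",
         call. = FALSE)
  }
  edges <- courses[[1L]]$bin_edges
  if (!all(vapply(courses, function(x) identical(x$bin_edges, edges), TRUE))) {
    stop("all courses must share the same binning", call. = FALSE)
  }
  m <- rowMeans(vapply(courses, `[[`, numeric(length(edges) - 1L),
                       "charge_per_bin"))
  new_charge_time_course(edges, m, courses[[1L]]$onset)
}

#' Peristimulus time histogram and firing features of spike rasters
#'
#' Bins spikes across repeats from the stimulation onset: rate per bin
#' (Hz) = spike count / (repeats x bin width), baseline rate from a
#' pre-onset window, delay to frequency peak = center of the (earliest)
#' maximum-rate bin measured from the onset, and per-bin firing probability
#' (fraction of repeats with at least one spike in the bin).
#'
#' @param rasters list of spike-time vectors (ms), one per repeat.
#' @param onset stimulation onset, ms.
#' @param bin_width bin width, ms (default 5).
#' @param span analysis span after the onset, ms (default 100).
#' @param baseline_window length of the pre-onset window used for the
#'   baseline rate, ms (default 500).
#'
#' @return An object of class `firing_features`: list with `bin_edges`
#'   (relative to onset), `psth` (Hz per bin), `baseline_rate` (Hz),
#'   `peak_rate` (Hz), `delay_to_frequency_peak` (ms, `NA` with a flag if
#'   no spike fell in the span), `firing_probability`, `n_repeats`.
#' @export
compute_psth <- function(rasters, onset = 0, bin_width = 5, span = 100,
                         baseline_window = 500) {
  if (!is.list(rasters) || !length(rasters)) {
    stop("'rasters' must be a non-empty list of spike-time vectors",
         call. = FALSE)
  }
  check_scalar(bin_width, "bin_width", lower = .Machine$double.xmin)
  n_bins <- span / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    stop("'span' must be an integer multiple of 'bin_width'", call. = FALSE)
  }
  n_bins <- as.integer(round(n_bins))
  n_rep <- length(rasters)
  edges <- onset + bin_width * (0:n_bins)
  counts <- matrix(0L, nrow = n_rep, ncol = n_bins)
  base_count <- 0L
  for (r in seq_len(n_rep)) {
    s <- rasters[[r]]
    base_count <- base_count + sum(s >= onset - baseline_window & s < onset)
    if (length(s)) {
      b <- findInterval(s, edges, rightmost.closed = FALSE)
      b <- b[b >= 1L & b <= n_bins & s < edges[n_bins + 1L]]
      if (length(b)) counts[r, ] <- tabulate(b, n_bins)
    }
  }
  total <- colSums(counts)
  psth <- total / (n_rep * bin_width / 1000)
  baseline_rate <- base_count / (n_rep * baseline_window / 1000)
  empty <- sum(total) == 0L
  if (empty) {
    delay <- NA_real_
    peak_rate <- 0
  } else {
    peak_bin <- which.max(psth)
    peak_rate <- psth[peak_bin]
    delay <- (edges[peak_bin] + edges[peak_bin + 1L]) / 2 - onset
  }
  structure(list(
    bin_edges = edges - onset, psth = psth, baseline_rate = baseline_rate,
    peak_rate = peak_rate, delay_to_frequency_peak = delay,
    firing_probability = colMeans(counts > 0L), n_repeats = n_rep,
    no_evoked_spikes = empty
  ), class = "firing_features")
}

#' @export
print.firing_features <- function(x, ...) {
  cat(sprintf("Firing features: %d repeats, baseline %.1f Hz, peak %.1f Hz at %s ms\n",
              x$n_repeats, x$baseline_rate, x$peak_rate,
              format(x$delay_to_frequency_peak)))
  invisible(x)
}

#' Correlate charge-domain and spike-domain latencies
#'
#' Pearson correlation (with two-sided p-value) between the delay to EPSC
#' peak and the delay to frequency peak across synapses.
#'
#' @param epsc_delays numeric vector of delays to EPSC peak, ms.
#' @param firing_delays numeric vector of delays to frequency peak, ms
#'   (same length, >= 3 complete pairs).
#' @return list with `r`, `p` and `n`.
#' @export
correlate_delays <- function(epsc_delays, firing_delays) {
  if (length(epsc_delays) != length(firing_delays)) {
    stop("delay vectors must have the same length", call. = FALSE)
  }
  ok <- is.finite(epsc_delays) & is.finite(firing_delays)
  x <- epsc_delays[ok]
  y <- firing_delays[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one of the delay variables", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Classify photostimulation charge time courses
#'
#' Treats the per-bin charges of each synapse's (averaged) time course as
#' its feature vector and delegates to [classify_cohort()] (min-max
#' normalization, PCA fitted on the reference cohort, k-means with k = 3 by
#' default, optional projection of a test cohort).
#'
#' @param courses_ref list of `charge_time_course` objects (reference
#'   cohort, identical binning).
#' @param courses_test optional list for a test cohort, or `NULL`.
#' @param k number of clusters (default 3).
#' @param seed integer seed.
#' @param ... passed on to [classify_cohort()].
#' @return an `stp_classification` (see [classify_cohort()]).
#' @export
classify_time_courses <- function(courses_ref, courses_test = NULL, k = 3,
                                  seed = 1, ...) {
  as_matrix <- function(courses) {
    edges <- courses[[1L]]$bin_edges
    if (!all(vapply(courses, function(x) identical(x$bin_edges, edges), TRUE))) {
      stop("all courses must share the same binning", call. = FALSE)
    }
    m <- t(vapply(courses, `[[`, numeric(length(edges) - 1L),
                  "charge_per_bin"))
    rownames(m) <- names(courses)
    m
  }
  ref <- as_matrix(courses_ref)
  test <- if (!is.null(courses_test)) as_matrix(courses_test) else NULL
  classify_cohort(ref, test, k = k, seed = seed, ...)
}
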