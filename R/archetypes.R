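# Archetype parameter sets for the four observed classes of unitary
# GC-MLI connections, calibrated once to the qualitative shape constraints:
#   C1 -- largest first EPSC, paired-pulse facilitation, depression of
#         release after the second stimulus;
#   C2 -- strong facilitation, charge rising through ~stimulus 4 and
#         depressing afterwards;
#   C3 -- strong facilitation sustained through the whole 100 Hz train
#         (fast recruitment of the reluctant pool);
#   C4 -- uniquantal bouton (one site), small but stable EPSCs.
# First-EPSC mean charges (n_sites * p_fr * q_charge) are anchored near
# 200 / 126 / 126 / 75 fC to keep the simulated cohort on a realistic scale.

ARCHETYPE_BASE <- list(
  C1 = list(n_sites = 15, p_fr = 0.35, q_charge = 38,
            facil_increment = 0.55, tau_facil = 30,
            tau_recovery = 150, reluctant_gain = 3),
  C2 = list(n_sites = 15, p_fr = 0.12, q_charge = 70,
            facil_increment = 0.18, tau_facil = 60,
            tau_recovery = 140, reluctant_gain = 3),
  C3 = list(n_sites = 18, p_fr = 0.10, q_charge = 70,
            facil_increment = 0.15, tau_facil = 80,
            tau_recovery = 40, reluctant_gain = 3),
  C4 = list(n_sites = 1, p_fr = 0.3, q_charge = 100,
            facil_increment = 0.65, tau_facil = 60,
            tau_recovery = 8, reluctant_gain = 2)
)

# Genotype effect: loss of synapsin II lowers the release probability of
# fully-releasable vesicles and the number of docked vesicles (release
# sites), leaving the refilling (reluctant-pool) dynamics untouched.
KO_P_FACTOR <- 0.65
KO_SITE_FACTOR <- 0.7

#' Peak amplitude of a single-quantum EPSC
#'
#' Analytic peak (pA, magnitude) of the normalized biexponential kernel
#' scaled by the quantal charge; used to set the default noise level
#' (peak about 10x the noise SD).
#'
#' @param params a [quantal_synapse_params()] object.
#' @return peak amplitude in pA (positive magnitude).
#' @export
quantal_peak_amplitude <- function(params) {
  r <- params$kernel_rise
  d <- params$kernel_decay
  t_peak <- log(d / r) * r * d / (d - r)
  params$q_charge * epsc_kernel(t_peak, r, d)
}

#' Construct the parameter set of an STP class archetype
#'
#' Returns [quantal_synapse_params()] for one of the four connection
#' classes (`"C1"`..`"C4"`), with small seeded multiplicative jitter on the
#' continuous parameters so that a cohort of archetypes shows biological
#' diversity. For the synapsin-II-knockout genotype the initial release
#' probability is scaled by 0.65 and the number of sites by 0.7 (minimum 1),
#' leaving the refilling dynamics untouched. The default noise SD is set so
#' the single-quantum EPSC peak is about 10x the noise SD.
#'
#' @param class_id one of `"C1"`, `"C2"`, `"C3"`, `"C4"`.
#' @param genotype `"WT"` or `"KO"`.
#' @param seed integer seed for the jitter; `NULL` for the unjittered
#'   archetype.
#' @param jitter_sd SD of the log-normal jitter (0 disables it).
#'
#' @return a [quantal_synapse_params()] object with attributes `class_id`
#'   and `genotype`.
#' @examples
#' make_class_archetype("C1", "WT")
#' @export
make_class_archetype <- function(class_id, genotype = c("WT", "KO"),
                                 seed = NULL, jitter_sd = 0.05) {
  if (!is.character(class_id) || length(class_id) != 1L ||
      !class_id %in% names(ARCHETYPE_BASE)) {
    stop("unknown class_id; must be one of C1, C2, C3, C4", call. = FALSE)
  }
  genotype <- match.arg(genotype)
  b <- ARCHETYPE_BASE[[class_id]]
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

#' Generate a ground-truth cohort of simulated synapses
#'
#' Builds the synapse-level ground truth for a cohort: one archetype-derived
#' parameter set per synapse, with class labels and per-synapse sub-seeds
#' derived deterministically from the master seed. Sweeps are generated
#' lazily by [cohort_features()] or [synapse_sweeps()] so that large cohorts
#' need not be held in memory.
#'
#' @param n_per_class named integer vector of synapse counts per class,
#'   e.g. `c(C1 = 24, C2 = 24, C3 = 24, C4 = 24)`; a single unnamed number
#'   is recycled over the four classes.
#' @param genotype `"WT"` or `"KO"` for the whole cohort.
#' @param protocol a [stimulus_protocol()]; `n_trains` should be >= 7 to
#'   satisfy the downstream analysis minimum.
#' @param seed master integer seed.
#'
#' @return An object of class `stp_cohort`: list with `synapses` (each a
#'   list `id`, `class_id`, `genotype`, `params`, `seed`), `protocol`,
#'   `genotype` and `seed`.
#' @examples
#' coh <- make_cohort(c(C1 = 2, C2 = 2, C3 = 2, C4 = 2), seed = 1)
#' length(coh$synapses)
#' @export
make_cohort <- function(n_per_class = c(C1 = 24, C2 = 24, C3 = 24, C4 = 24),
                        genotype = c("WT", "KO"),
                        protocol = stimulus_protocol(), seed = 1) {
  genotype <- match.arg(genotype)
  if (is.null(names(n_per_class))) {
    if (length(n_per_class) == 1L) {
      n_per_class <- stats::setNames(rep(n_per_class, 4), names(ARCHETYPE_BASE))
    } else {
      stop("'n_per_class' must be named by class", call. = FALSE)
    }
  }
  if (!all(names(n_per_class) %in% names(ARCHETYPE_BASE))) {
    stop("unknown class names in 'n_per_class'", call. = FALSE)
  }
  check_scalar(seed, "seed", integer = TRUE)
  classes <- rep(names(n_per_class), times = n_per_class)
  synapses <- lapply(seq_along(classes), function(i) {
    syn_seed <- derive_seed(seed, i)
    list(
      id = sprintf("%s_syn%03d", tolower(genotype), i),
      class_id = classes[i], genotype = genotype,
      params = make_class_archetype(classes[i], genotype,
                                    seed = derive_seed(syn_seed, 0L)),
      seed = syn_seed
    )
  })
  structure(list(synapses = synapses, protocol = protocol,
                 genotype = genotype, seed = as.integer(seed)),
            class = "stp_cohort")
}

#' @export
print.stp_cohort <- function(x, ...) {
  tab <- table(vapply(x$synapses, `[[`, "", "class_id"))
  cat(sprintf("STP cohort (%s): %d synapses [%s], seed %d\n", x$genotype,
              length(x$synapses),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              x$seed))
  invisible(x)
}

#' @rdname make_cohort
#' @param cohort an `stp_cohort`.
#' @param index synapse index within the cohort.
#' @return `synapse_sweeps`: the list of rendered [sweep_recording()]s for
#'   one synapse of the cohort.
#' @export
synapse_sweeps <- function(cohort, index) {
  stopifnot(inherits(cohort, "stp_cohort"))
  syn <- cohort$synapses[[index]]
  simulate_synapse_sweeps(syn$params, cohort$protocol, derive_seed(syn$seed, 1000L))
}
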