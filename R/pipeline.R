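# End-to-end driver: simulate -> extract -> QC -> classify (reference
# cohort with test-cohort overlay) -> photostimulation branch ->
# morphometry branch, with all tables written as plain text.

#' Configuration of a full pipeline run
#'
#' Collects every tunable of [run_pipeline()] with the package defaults:
#' 10-pulse 100 Hz trains repeated 10 times, 3-sigma failure detection,
#' k = 4 classes for train profiles and k = 3 for photostimulation time
#' courses, 5-ms bins over 100 ms, 50-nm docking cutoff. All randomness
#' derives from the single `seed`.
#'
#' @param seed master integer seed.
#' @param outdir output directory (created if needed).
#' @param wt_per_class named counts of wild-type synapses per class.
#' @param ko_per_class named counts of knockout synapses per class (the
#'   default mixture is skewed to the facilitating/uniquantal classes, as
#'   observed after synapsin II deletion).
#' @param protocol a [stimulus_protocol()].
#' @param detect_k failure-detection threshold multiplier.
#' @param k_train clusters for train-profile classification.
#' @param k_photostim clusters for time-course classification.
#' @param n_restarts k-means restarts.
#' @param photostim_per_class synapses per photostimulation archetype.
#' @param photostim_sweeps episodes per photostimulated synapse (>= 7).
#' @param mli_gain coupling gain, Hz per (fC/ms), of interneuron spiking to
#'   the evoked-charge density.
#' @param mli_baseline_rate baseline interneuron firing rate, Hz.
#' @param mli_repeats loose-patch repeats per synapse.
#' @param morpho_n boutons per genotype in the morphometry branch.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1, outdir = tempfile("synstp_run"),
                       wt_per_class = c(C1 = 24, C2 = 24, C3 = 24, C4 = 24),
                       ko_per_class = c(C1 = 1, C2 = 3, C3 = 12, C4 = 12),
                       protocol = stimulus_protocol(),
                       detect_k = 3, k_train = 4, k_photostim = 3,
                       n_restarts = 50,
                       photostim_per_class = 10, photostim_sweeps = 7,
                       mli_gain = 0.5, mli_baseline_rate = 12.75,
                       mli_repeats = 40, morpho_n = 200) {
  check_scalar(seed, "seed", integer = TRUE)
  stopifnot(inherits(protocol, "stimulus_protocol"))
  structure(list(
    seed = as.integer(seed), outdir = outdir,
    wt_per_class = wt_per_class, ko_per_class = ko_per_class,
    protocol = protocol, detect_k = detect_k, k_train = k_train,
    k_photostim = k_photostim, n_restarts = n_restarts,
    photostim_per_class = photostim_per_class,
    photostim_sweeps = photostim_sweeps, mli_gain = mli_gain,
    mli_baseline_rate = mli_baseline_rate, mli_repeats = mli_repeats,
    morpho_n = morpho_n
  ), class = "run_config")
}

#' Run the full analysis pipeline on synthetic cohorts
#'
#' Reproduces the figure-level analyses on simulated data: a wild-type
#' train cohort is simulated, features extracted and QC'd, classified by
#' PCA + k-means; a knockout cohort is projected into the wild-type PC
#' space and assigned to the nearest centroids; photostimulation episodes
#' with coupled interneuron spiking yield charge/latency features, their
#' correlation and a k = 3 time-course classification; and a morphometry
#' cohort yields docked-vesicle counts and the AZ-length correlation.
#' All outputs are written as deterministic plain text under
#' `config$outdir`; repeated runs with the same config are byte-identical.
#'
#' @param config a [run_config()].
#' @param verbose emit per-stage `message()` lines.
#' @return the run report (named list, also written as `report.json`),
#'   invisibly.
#' @export
run_pipeline <- function(config = run_config(), verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed

  # --- stage 1: simulate + extract, wild-type reference cohort ----------
  say("[simulate] wild-type cohort (%d synapses)", sum(config$wt_per_class))
  wt <- make_cohort(config$wt_per_class, "WT", config$protocol,
                    seed = derive_seed(seed, 101L))
  wt_feat <- cohort_features(wt, k = config$detect_k)
  write_features_csv(wt_feat$features, wt_feat$table$synapse_id,
                     file.path(config$outdir, "wt_features.csv"),
                     qc_codes = wt_feat$table$qc_codes)

  # --- stage 2: simulate + extract, knockout test cohort ----------------
  say("[simulate] knockout cohort (%d synapses)", sum(config$ko_per_class))
  ko <- make_cohort(config$ko_per_class, "KO", config$protocol,
                    seed = derive_seed(seed, 102L))
  ko_feat <- cohort_features(ko, k = config$detect_k)
  write_features_csv(ko_feat$features, ko_feat$table$synapse_id,
                     file.path(config$outdir, "ko_features.csv"),
                     qc_codes = ko_feat$table$qc_codes)

  # --- stage 3: classification with knockout overlay --------------------
  say("[classify] k = %d on reference scores, knockout projected",
      config$k_train)
  cls <- classify_cohort(wt_feat$profiles, ko_feat$profiles,
                         k = config$k_train,
                         seed = derive_seed(seed, 103L),
                         n_restarts = config$n_restarts)
  write_classification_json(cls, file.path(config$outdir,
                                           "classification.json"))
  score_tab <- data.frame(
    synapse_id = c(rownames(cls$scores), rownames(cls$test_scores)),
    cohort = c(rep("reference", nrow(cls$scores)),
               rep("test", length(cls$test_labels))),
    pc1 = c(cls$scores[, 1L], cls$test_scores[, 1L]),
    pc2 = c(cls$scores[, 2L], cls$test_scores[, 2L]),
    label = c(cls$labels, cls$test_labels),
    truth = c(wt_feat$truth, ko_feat$truth),
    stringsAsFactors = FALSE
  )
  utils::write.csv(score_tab, file.path(config$outdir, "scores_labels.csv"),
                   row.names = FALSE)
  summaries <- class_summaries(cls, wt_feat$table)
  utils::write.csv(summaries$table,
                   file.path(config$outdir, "class_summaries.csv"),
                   row.names = FALSE)

  # --- stage 4: photostimulation branch ---------------------------------
  say("[photostim] %d synapses x %d episodes",
      3 * config$photostim_per_class, config$photostim_sweeps)
  ps_classes <- rep(names(PHOTOSTIM_BASE), each = config$photostim_per_class)
  ps <- lapply(seq_along(ps_classes), function(i) {
    s0 <- derive_seed(seed, 200L + i)
    params <- photostim_archetype(ps_classes[i], "WT",
                                  seed = derive_seed(s0, 0L))
    courses <- lapply(seq_len(config$photostim_sweeps), function(j) {
      ep <- simulate_photostim_episode(params, gc_burst(),
                                       seed = derive_seed(s0, j))
      bin_charge_time_course(ep$sweep)
    })
    course <- average_charge_time_courses(courses)
    rasters <- simulate_mli_spiking(course, config$mli_baseline_rate,
                                    config$mli_gain, config$mli_repeats,
                                    seed = derive_seed(s0, 999L))
    firing <- compute_psth(rasters)
    list(id = sprintf("ps_syn%03d", i), class_id = ps_classes[i],
         course = course, firing = firing)
  })
  ps_tab <- data.frame(
    synapse_id = vapply(ps, `[[`, "", "id"),
    class_id = vapply(ps, `[[`, "", "class_id"),
    peak_charge_fC = vapply(ps, function(x) x$course$peak_charge, 0),
    delay_to_epsc_peak_ms = vapply(ps, function(x) x$course$delay_to_epsc_peak, 0),
    baseline_rate_hz = vapply(ps, function(x) x$firing$baseline_rate, 0),
    peak_rate_hz = vapply(ps, function(x) x$firing$peak_rate, 0),
    delay_to_frequency_peak_ms =
      vapply(ps, function(x) x$firing$delay_to_frequency_peak, 0),
    stringsAsFactors = FALSE
  )
  utils::write.csv(ps_tab, file.path(config$outdir, "photostim_features.csv"),
                   row.names = FALSE)
  delay_cor <- correlate_delays(ps_tab$delay_to_epsc_peak_ms,
                                ps_tab$delay_to_frequency_peak_ms)
  courses <- lapply(ps, `[[`, "course")
  names(courses) <- ps_tab$synapse_id
  ps_cls <- classify_time_courses(courses, k = config$k_photostim,
                                  seed = derive_seed(seed, 300L),
                                  n_restarts = config$n_restarts)
  write_classification_json(ps_cls,
                            file.path(config$outdir,
                                      "photostim_classification.json"))

  # --- stage 5: morphometry branch --------------------------------------
  say("[morphometry] %d boutons per genotype", config$morpho_n)
  morpho_wt <- make_morphometry_fixture(config$morpho_n, "WT",
                                        seed = derive_seed(seed, 401L))
  morpho_ko <- make_morphometry_fixture(config$morpho_n, "KO",
                                        seed = derive_seed(seed, 402L))
  write_morphometry_csv(c(morpho_wt, morpho_ko),
                        file.path(config$outdir, "morphometry.csv"))
  docked_wt <- vapply(morpho_wt, count_docked, 0L)
  docked_ko <- vapply(morpho_ko, count_docked, 0L)
  morpho_cor <- az_docked_correlation(morpho_wt)

  # --- run report --------------------------------------------------------
  report <- list(
    package_version = as.character(utils::packageVersion("synstp")),
    config = list(
      seed = config$seed,
      wt_per_class = as.list(config$wt_per_class),
      ko_per_class = as.list(config$ko_per_class),
      n_pulses = config$protocol$n_pulses,
      frequency = config$protocol$frequency,
      n_trains = config$protocol$n_trains,
      detect_k = config$detect_k, k_train = config$k_train,
      k_photostim = config$k_photostim
    ),
    wt = list(
      n = nrow(wt_feat$profiles),
      mean_epsc1_fC = mean(wt_feat$table$epsc1_fC),
      failure_rate_1 = mean(wt_feat$table$failure_rate_1),
      qc_warnings = sum(!wt_feat$table$qc_accepted),
      low_n_flags = sum(vapply(wt_feat$features, `[[`, TRUE, "low_n"))
    ),
    ko = list(
      n = nrow(ko_feat$profiles),
      mean_epsc1_fC = mean(ko_feat$table$epsc1_fC),
      failure_rate_1 = mean(ko_feat$table$failure_rate_1),
      qc_warnings = sum(!ko_feat$table$qc_accepted),
      low_n_flags = sum(vapply(ko_feat$features, `[[`, TRUE, "low_n"))
    ),
    classification = list(
      explained_variance_2 = cls$explained_variance_2,
      proportions = cls$proportions
    ),
    photostim = list(
      delay_correlation_r = delay_cor$r,
      delay_correlation_p = delay_cor$p,
      proportions = ps_cls$proportions$reference
    ),
    morphometry = list(
      mean_docked_wt = mean(docked_wt),
      mean_docked_ko = mean(docked_ko),
      mean_az_wt = mean(vapply(morpho_wt, `[[`, 0, "az_length")),
      mean_az_ko = mean(vapply(morpho_ko, `[[`, 0, "az_length")),
      az_docked_r = morpho_cor$r,
      az_docked_p = morpho_cor$p
    )
  )
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("[done] outputs in %s", config$outdir)
  invisible(report)
}
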