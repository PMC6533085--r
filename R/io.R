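# Plain-text readers/writers: sweep containers (TSV with a commented
# header), spike rasters, feature tables, morphometry tables and JSON
# classification reports. All writers round-trip numeric values at full
# double precision ("%.17g").

#' @keywords internal
#' @noRd
fmt_num <- function(x) sprintf("%.17g", x)

#' Write and read the sweeps of one synapse as delimited text
#'
#' One file per synapse: commented header lines carry the stimulus times,
#' sampling rate and baseline window; the body is tab-separated with a
#' time column and one column per train. Values round-trip at full stored
#' precision.
#'
#' @param sweeps list of [sweep_recording()]s sharing time base and
#'   stimulus times.
#' @param path output file path.
#' @return `write_sweeps_tsv`: the path, invisibly. `read_sweeps_tsv`: the
#'   list of sweeps.
#' @export
write_sweeps_tsv <- function(sweeps, path) {
  if (!length(sweeps) || !all(vapply(sweeps, inherits, TRUE, "sweep_recording"))) {
    stop("'sweeps' must be a non-empty list of sweep_recording objects",
         call. = FALSE)
  }
  s1 <- sweeps[[1L]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("# stimulus_times:", paste(fmt_num(s1$stimulus_times), collapse = " ")),
    paste("# sampling_rate:", fmt_num(s1$sampling_rate)),
    paste("# baseline_window:", paste(fmt_num(s1$baseline_window), collapse = " ")),
    paste(c("time_ms", sprintf("train%d", seq_along(sweeps))), collapse = "\t")
  ), con)
  m <- cbind(s1$time_base, vapply(sweeps, `[[`, numeric(length(s1$time_base)),
                                  "current"))
  utils::write.table(matrix(fmt_num(m), nrow = nrow(m)), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_sweeps_tsv
#' @export
read_sweeps_tsv <- function(path) {
  lines <- readLines(path, n = 10L)
  header <- grep("^#", lines, value = TRUE)
  get_field <- function(name) {
    ln <- grep(paste0("^# ", name, ":"), header, value = TRUE)
    if (!length(ln)) {
      stop(sprintf("parse error in '%s': missing header field '%s'",
                   path, name), call. = FALSE)
    }
    as.numeric(strsplit(sub(paste0("^# ", name, ": *"), "", ln[1L]),
                        " +")[[1L]])
  }
  stim <- get_field("stimulus_times")
  sr <- get_field("sampling_rate")
  bw <- get_field("baseline_window")
  body <- utils::read.table(path, sep = "\t", header = TRUE,
                            comment.char = "#", check.names = FALSE)
  time_base <- body[[1L]]
  lapply(seq_len(ncol(body) - 1L), function(j) {
    sweep_recording(time_base, body[[j + 1L]], stim, sampling_rate = sr,
                    baseline_window = bw)
  })
}

#' Write and read spike rasters as delimited text
#'
#' One line per repeat, spike times (ms) comma-separated; an empty line is
#' an empty repeat.
#'
#' @param rasters list of numeric spike-time vectors.
#' @param path file path.
#' @return `write_rasters`: the path, invisibly. `read_rasters`: the list
#'   of spike-time vectors.
#' @export
write_rasters <- function(rasters, path) {
  writeLines(vapply(rasters, function(s) paste(fmt_num(s), collapse = ","),
                    ""), path)
  invisible(path)
}

#' @rdname write_rasters
#' @export
read_rasters <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(ln) {
    if (!nzchar(trimws(ln))) return(numeric(0))
    as.numeric(strsplit(ln, ",")[[1L]])
  })
}

#' Write per-synapse train features as CSV
#'
#' Long format, one row per synapse and stimulus: `synapse_id`,
#' `stimulus_index`, `mean_charge_fC`, `median_charge_fC`, `failure_rate`,
#' `ppr`, `success_rate_1`, `qc_codes`.
#'
#' @param features list of [compute_train_features()] results.
#' @param synapse_ids character vector of ids (same length).
#' @param path file path.
#' @param qc_codes optional character vector of QC codes per synapse.
#' @return the path, invisibly.
#' @export
write_features_csv <- function(features, synapse_ids, path, qc_codes = NULL) {
  stopifnot(length(features) == length(synapse_ids))
  if (is.null(qc_codes)) qc_codes <- rep("", length(features))
  rows <- do.call(rbind, lapply(seq_along(features), function(i) {
    f <- features[[i]]
    data.frame(
      synapse_id = synapse_ids[i],
      stimulus_index = seq_along(f$mean_charge),
      mean_charge_fC = f$mean_charge,
      median_charge_fC = f$median_charge,
      failure_rate = f$failure_rate,
      ppr = f$ppr,
      success_rate_1 = f$success_rate_1,
      qc_codes = qc_codes[i],
      stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read an STP profile matrix from a feature CSV
#'
#' Rebuilds the synapse x stimulus profile matrix from a file written by
#' [write_features_csv()].
#'
#' @param path file path.
#' @param value which charge column to use, `"median_charge_fC"` (default)
#'   or `"mean_charge_fC"`.
#' @return numeric matrix with synapse ids as row names.
#' @export
read_profile_csv <- function(path, value = "median_charge_fC") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("synapse_id", "stimulus_index", value)
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop(sprintf("parse error in '%s': missing field(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  ids <- unique(d$synapse_id)
  n_stim <- max(d$stimulus_index)
  m <- matrix(NA_real_, nrow = length(ids), ncol = n_stim,
              dimnames = list(ids, NULL))
  m[cbind(match(d$synapse_id, ids), d$stimulus_index)] <- d[[value]]
  if (anyNA(m)) stop(sprintf("incomplete profile matrix in '%s'", path),
                     call. = FALSE)
  m
}

#' Write and read morphometry tables
#'
#' Long CSV, one row per vesicle: `synapse_id`, `genotype`,
#' `az_length_nm`, `distance_nm` (a bouton without vesicles gets one row
#' with an empty distance).
#'
#' @param profiles list of [synapse_profile()]s.
#' @param path file path.
#' @return `write_morphometry_csv`: the path, invisibly.
#'   `read_morphometry_csv`: the list of profiles.
#' @export
write_morphometry_csv <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    d <- if (length(p$vesicle_distances)) p$vesicle_distances else NA_real_
    data.frame(synapse_id = p$synapse_id, genotype = p$genotype,
               az_length_nm = fmt_num(p$az_length),
               distance_nm = ifelse(is.na(d), "", fmt_num(d)),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_morphometry_csv
#' @export
read_morphometry_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("synapse_id", "genotype", "az_length_nm", "distance_nm")
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop(sprintf("parse error in '%s': missing field(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  lapply(split(d, factor(d$synapse_id, levels = unique(d$synapse_id))),
         function(g) {
           dist <- g$distance_nm[!is.na(g$distance_nm)]
           synapse_profile(g$synapse_id[1L], g$az_length_nm[1L], dist,
                           g$genotype[1L])
         })
}

#' Write a classification report as JSON
#'
#' Serializes the PCA model (center, loadings, explained variance),
#' per-synapse scores and labels for both cohorts, centroids, class mean
#' profiles and cohort proportions.
#'
#' @param result an `stp_classification`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_classification_json <- function(result, path) {
  stopifnot(inherits(result, "stp_classification"))
  report <- list(
    k = result$k,
    explained_variance = result$model$explained_variance,
    explained_variance_2 = result$explained_variance_2,
    center = result$model$center,
    loadings = result$model$loadings,
    centroids = result$centroids,
    reference = list(ids = rownames(result$scores),
                     scores = result$scores, labels = result$labels),
    test = if (is.null(result$test_scores)) NULL else
      list(ids = rownames(result$test_scores),
           scores = result$test_scores, labels = result$test_labels),
    proportions = result$proportions,
    class_profiles = result$class_profiles
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
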