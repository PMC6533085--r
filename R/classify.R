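# Normalization, PCA, k-means classification of STP profiles, and
# projection of a test (e.g. knockout) cohort into a reference PC space.

#' Min-max (vector space model) normalization of STP profiles
#'
#' Linearly rescales each observation so that its minimum maps to 0 and its
#' maximum to 1, making profiles shape-comparable independently of their
#' absolute charge. Per-feature (column) scaling is available as an
#' alternative. A constant row (max = min) is mapped to all 0.5 and flagged
#' in the `constant_rows` attribute rather than dropped.
#'
#' @param x numeric matrix, rows = observations (synapses), columns =
#'   per-stimulus charges. No missing values allowed.
#' @param method `"row"` (per-observation, default) or `"column"`
#'   (per-feature).
#' @return matrix of the same shape with values in \[0, 1\]; attribute
#'   `constant_rows` (or `constant_cols`) lists flagged indices.
#' @examples
#' vsm_normalize(rbind(a = c(2, 4, 6), b = c(1, 1, 2)))
#' @export
vsm_normalize <- function(x, method = c("row", "column")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("profile matrix has missing or non-finite values",
                               call. = FALSE)
  if (method == "column") x <- t(x)
  rng <- apply(x, 1L, range)
  span <- rng[2L, ] - rng[1L, ]
  const <- span == 0
  span[const] <- 1
  out <- (x - rng[1L, ]) / span
  out[const, ] <- 0.5
  if (method == "column") {
    out <- t(out)
    attr(out, "constant_cols") <- which(const)
  } else {
    attr(out, "constant_rows") <- which(const)
  }
  out
}

#' Fit a principal-component model on a reference cohort
#'
#' Centered (unscaled) principal-axis decomposition of the normalized
#' profile matrix. Components are ordered by explained variance; the sign of
#' each loading vector is fixed so its largest-magnitude element is
#' positive, for reproducibility.
#'
#' @param x normalized profile matrix (rows = observations).
#' @param n_components number of components to retain (default 2).
#' @return An object of class `stp_pca`: list with `center` (feature
#'   means), `loadings` (features x components, orthonormal),
#'   `explained_variance` (fractions over all feature-space variance, one
#'   per retained component) and `scores` (fit scores of the reference
#'   rows).
#' @export
fit_pca <- function(x, n_components = 2) {
  x <- as.matrix(x)
  check_scalar(n_components, "n_components", lower = 1, integer = TRUE)
  if (nrow(x) < n_components + 1) {
    stop("need at least n_components + 1 observations", call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  total <- sum(ev)
  if (total <= 0) {
    stop("zero total variance: all observations identical after normalization",
         call. = FALSE)
  }
  rank <- sum(ev > total * 1e-12)
  if (rank < n_components) {
    stop(sprintf("matrix rank %d is below n_components = %d", rank,
                 n_components), call. = FALSE)
  }
  loadings <- pc$rotation[, seq_len(n_components), drop = FALSE]
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(
    center = pc$center, loadings = loadings,
    explained_variance = ev[seq_len(n_components)] / total,
    scores = scores
  ), class = "stp_pca")
}

#' @export
print.stp_pca <- function(x, ...) {
  cat(sprintf("PCA model: %d features -> %d components (%.1f%% variance)\n",
              length(x$center), ncol(x$loadings),
              100 * sum(x$explained_variance)))
  invisible(x)
}

#' Project observations into a fitted principal-component space
#'
#' Computes `(rows - center) %*% loadings`. Observations that did not take
#' part in the fit (a test cohort) are thereby overlaid onto the reference
#' cloud of points; projecting the reference matrix itself reproduces the
#' fit scores exactly.
#'
#' @param model an `stp_pca` from [fit_pca()].
#' @param x normalized profile matrix with the model's feature count.
#' @return score matrix (rows x components).
#' @export
project_pca <- function(model, x) {
  stopifnot(inherits(model, "stp_pca"))
  x <- as.matrix(x)
  if (ncol(x) != length(model$center)) {
    stop(sprintf("feature count mismatch: model has %d, matrix has %d",
                 length(model$center), ncol(x)), call. = FALSE)
  }
  sweep(x, 2L, model$center) %*% model$loadings
}

#' Cluster PC scores with restarted k-means
#'
#' Best-of-`n_restarts` k-means (squared-Euclidean objective), deterministic
#' given the seed. Cluster labels are canonicalized by descending cluster
#' mean of the first score column (PC1), giving a stable reporting order.
#'
#' @param scores numeric score matrix (rows = observations).
#' @param k number of clusters (1 <= k <= rows).
#' @param seed integer seed.
#' @param n_restarts number of random restarts (default 50).
#' @return list with `labels` (1..k, canonical order), `centroids`
#'   (k x columns) and `tot_withinss`.
#' @export
cluster_kmeans <- function(scores, k, seed, n_restarts = 50) {
  scores <- as.matrix(scores)
  check_scalar(k, "k", lower = 1, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  if (k > nrow(scores)) stop("k exceeds the number of observations",
                             call. = FALSE)
  if (k == 1L) {
    cent <- matrix(colMeans(scores), nrow = 1L,
                   dimnames = list(NULL, colnames(scores)))
    return(list(labels = rep(1L, nrow(scores)), centroids = cent,
                tot_withinss = sum(sweep(scores, 2L, cent[1L, ])^2)))
  }
  km <- with_seed(seed,
    stats::kmeans(scores, centers = k, nstart = n_restarts, iter.max = 200)
  )
  ord <- order(km$centers[, 1L], decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  list(labels = relabel[km$cluster],
       centroids = km$centers[ord, , drop = FALSE],
       tot_withinss = km$tot.withinss)
}

# Nearest-centroid assignment; ties broken by the lowest centroid index.
#' @keywords internal
#' @noRd
assign_nearest_centroid <- function(scores, centroids) {
  d2 <- outer(rowSums(scores^2), rep(1, nrow(centroids))) -
    2 * scores %*% t(centroids) +
    outer(rep(1, nrow(scores)), rowSums(centroids^2))
  as.integer(apply(d2, 1L, which.min))
}

#' Classify STP profiles of a reference cohort and overlay a test cohort
#'
#' The full classification pipeline: min-max (VSM) normalization, PCA
#' fitted on the reference cohort only, projection of both cohorts into the
#' reference PC space, k-means clustering of the reference scores, and
#' nearest-centroid assignment of the test observations. Mirrors the
#' wild-type / knockout design in which test observations take no part in
#' the eigenvalue calculation and are overlaid on the reference cloud.
#'
#' @param reference profile matrix of the reference cohort (rows =
#'   synapses, columns = per-stimulus aggregated charges).
#' @param test optional profile matrix of a test cohort (same columns), or
#'   `NULL`.
#' @param k number of clusters (4 for 100 Hz train profiles, 3 for
#'   photostimulation time courses).
#' @param seed integer seed for k-means.
#' @param n_components number of PCs used for clustering (default 2).
#' @param n_restarts k-means restarts.
#' @param normalization `"row"` (default) or `"column"`, see
#'   [vsm_normalize()].
#' @param drop_first drop the first-stimulus feature before normalization
#'   (robustness control).
#'
#' @return An object of class `stp_classification`: list with `model`
#'   (`stp_pca`), `scores` / `labels` (reference), `test_scores` /
#'   `test_labels` (or `NULL`), `centroids`, `k`, `proportions` (named list
#'   per cohort, each summing to 1), `class_profiles` (k x features, mean
#'   normalized reference profile per class), `explained_variance_2`.
#' @export
classify_cohort <- function(reference, test = NULL, k = 4, seed = 1,
                            n_components = 2, n_restarts = 50,
                            normalization = c("row", "column"),
                            drop_first = FALSE) {
  normalization <- match.arg(normalization)
  reference <- as.matrix(reference)
  if (!nrow(reference)) stop("reference cohort is empty", call. = FALSE)
  take <- if (drop_first) -1L else seq_len(ncol(reference))
  ref_n <- vsm_normalize(reference[, take, drop = FALSE], normalization)
  model <- fit_pca(ref_n, n_components = n_components)
  scores <- model$scores
  rownames(scores) <- rownames(reference)
  cl <- cluster_kmeans(scores, k = k, seed = seed, n_restarts = n_restarts)
  class_profiles <- t(vapply(seq_len(k), function(g) {
    colMeans(ref_n[cl$labels == g, , drop = FALSE])
  }, numeric(ncol(ref_n))))
  rownames(class_profiles) <- paste0("class", seq_len(k))
  test_scores <- test_labels <- NULL
  proportions <- list(reference = tabulate(cl$labels, k) / length(cl$labels))
  if (!is.null(test)) {
    test <- as.matrix(test)
    test_n <- vsm_normalize(test[, take, drop = FALSE], normalization)
    test_scores <- project_pca(model, test_n)
    rownames(test_scores) <- rownames(test)
    test_labels <- assign_nearest_centroid(test_scores, cl$centroids)
    proportions$test <- tabulate(test_labels, k) / length(test_labels)
  }
  structure(list(
    model = model, scores = scores, labels = cl$labels,
    test_scores = test_scores, test_labels = test_labels,
    centroids = cl$centroids, k = k, proportions = proportions,
    class_profiles = class_profiles,
    explained_variance_2 = sum(model$explained_variance[seq_len(min(2, n_components))])
  ), class = "stp_classification")
}

#' @export
print.stp_classification <- function(x, ...) {
  cat(sprintf("STP classification: k = %d, first two PCs explain %.1f%% of variance\n",
              x$k, 100 * x$explained_variance_2))
  cat("  reference proportions:",
      paste(sprintf("%.1f%%", 100 * x$proportions$reference), collapse = " "),
      "\n")
  if (!is.null(x$proportions$test)) {
    cat("  test proportions:     ",
        paste(sprintf("%.1f%%", 100 * x$proportions$test), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' Per-class summary tables with descriptive ANOVA annotations
#'
#' Summarizes first-EPSC charge and paired-pulse ratio per recovered class,
#' with a one-way ANOVA and Tukey post-hoc annotations across classes.
#' The tests are descriptive reporting output, not confirmatory inference.
#'
#' @param result an `stp_classification`.
#' @param features data.frame aligned with the reference rows, with columns
#'   `epsc1_fC` and `ppr`.
#' @return list with `table` (per-class n, means, SEMs), `anova_p`
#'   (ANOVA p-value for EPSC1 across classes, `NA` when suppressed) and
#'   `tukey` (TukeyHSD table or `NULL`). Statistics are suppressed when
#'   fewer than two classes have at least two members.
#' @export
class_summaries <- function(result, features) {
  stopifnot(inherits(result, "stp_classification"))
  if (nrow(features) != length(result$labels)) {
    stop("'features' must have one row per reference synapse", call. = FALSE)
  }
  cls <- factor(result$labels, levels = seq_len(result$k))
  sem <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
  tab <- data.frame(
    class = paste0("class", seq_len(result$k)),
    n = as.integer(table(cls)),
    mean_epsc1_fC = as.numeric(tapply(features$epsc1_fC, cls, mean)),
    sem_epsc1_fC = as.numeric(tapply(features$epsc1_fC, cls, sem)),
    mean_ppr = as.numeric(tapply(features$ppr, cls, mean)),
    sem_ppr = as.numeric(tapply(features$ppr, cls, sem)),
    stringsAsFactors = FALSE
  )
  eligible <- sum(tab$n >= 2L)
  anova_p <- NA_real_
  tukey <- NULL
  if (eligible >= 2L && nlevels(droplevels(cls)) >= 2L) {
    keep <- cls %in% levels(cls)[tab$n >= 2L]
    fit <- stats::aov(features$epsc1_fC[keep] ~ droplevels(cls[keep]))
    anova_p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
    tukey <- stats::TukeyHSD(fit)[[1L]]
  }
  list(table = tab, anova_p = anova_p, tukey = tukey)
}

#' Best-match agreement between two cluster labelings
#'
#' Fraction of observations on which two labelings of the same rows agree,
#' maximized over all k! relabelings of the second one (cluster indices
#' from independent fits are only identified up to permutation). Used for
#' the drop-first-stimulus robustness control.
#'
#' @param a,b integer label vectors of equal length.
#' @param k number of clusters (small; the search is over k! permutations).
#' @return agreement fraction in \[0, 1\].
#' @export
label_agreement <- function(a, b, k = max(a, b)) {
  stopifnot(length(a) == length(b))
  perms <- permutations_of(seq_len(k))
  best <- 0
  for (p in perms) best <- max(best, mean(a == p[b]))
  best
}

#' @keywords internal
#' @noRd
permutations_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}
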