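# Normalization, PCA (against a brute-force eigendecomposition oracle),
# k-means recovery and the cohort classification pipeline.

test_that("min-max normalization maps rows to [0, 1] and is affine-invariant", {
  expect_equal(unname(vsm_normalize(rbind(c(2, 4, 6)))[1, ]), c(0, 0.5, 1))
  x <- rbind(c(0, 0.3, 1))
  expect_equal(unname(vsm_normalize(x)[1, ]), c(0, 0.3, 1))
  # positive scaling and offsets of a row leave its normalized form unchanged
  set.seed(11)
  for (i in 1:20) {
    row <- runif(10, 0, 200)
    a <- runif(1, 0.1, 10)
    b <- runif(1, -50, 50)
    expect_equal(vsm_normalize(rbind(a * row + b))[1, ],
                 vsm_normalize(rbind(row))[1, ], tolerance = 1e-10)
  }
  cn <- vsm_normalize(rbind(c(5, 5, 5), c(1, 2, 3)))
  expect_equal(unname(cn[1, ]), c(0.5, 0.5, 0.5))
  expect_identical(attr(cn, "constant_rows"), 1L)
  expect_error(vsm_normalize(rbind(c(1, NA, 3))), "missing")
})

test_that("PCA agrees with a covariance eigendecomposition oracle", {
  set.seed(42)
  for (rep in 1:50) {
    x <- matrix(rnorm(200), nrow = 20, ncol = 10)
    model <- fit_pca(x, n_components = 2)
    # oracle: eigendecomposition of the sample covariance matrix
    ev <- eigen(stats::cov(x), symmetric = TRUE)
    centered <- sweep(x, 2, colMeans(x))
    for (j in 1:2) {
      v <- ev$vectors[, j]
      if (v[which.max(abs(v))] < 0) v <- -v
      expect_equal(unname(model$loadings[, j]), v, tolerance = 1e-8)
      expect_equal(unname(model$scores[, j]), unname(drop(centered %*% v)),
                   tolerance = 1e-8)
    }
    expect_equal(model$explained_variance,
                 (ev$values / sum(ev$values))[1:2], tolerance = 1e-8)
  }
})

test_that("PCA handles degenerate inputs", {
  ident <- matrix(rep(c(1, 2, 3), each = 5), nrow = 5)
  expect_error(fit_pca(ident), "zero total variance|rank")
  # collinear 2-D data: first component explains everything
  line <- cbind(1:10, 2 * (1:10))
  m <- fit_pca(line, n_components = 1)
  expect_equal(m$explained_variance, 1, tolerance = 1e-12)
  expect_error(fit_pca(line, n_components = 2), "rank")
  expect_error(fit_pca(matrix(rnorm(4), 2, 2), n_components = 2),
               "observations")
})

test_that("projection is exact on the fit data, zero at the mean, and affine", {
  set.seed(7)
  x <- matrix(rnorm(120), nrow = 12)
  model <- fit_pca(x, 2)
  expect_equal(unname(project_pca(model, x)), unname(model$scores),
               tolerance = 1e-10)
  expect_equal(unname(drop(project_pca(model, rbind(model$center)))),
               c(0, 0), tolerance = 1e-12)
  for (i in 1:10) {
    a <- rnorm(10); b <- rnorm(10); alpha <- runif(1)
    lhs <- project_pca(model, rbind(alpha * a + (1 - alpha) * b))
    rhs <- alpha * project_pca(model, rbind(a)) +
      (1 - alpha) * project_pca(model, rbind(b))
    expect_equal(unname(lhs), unname(rhs), tolerance = 1e-10)
  }
  expect_error(project_pca(model, matrix(0, 2, 7)), "mismatch")
})

test_that("k-means recovers planted well-separated clouds exactly", {
  set.seed(3)
  cloud1 <- cbind(rnorm(30, 10, 0.5), rnorm(30, 0, 0.5))
  cloud2 <- cbind(rnorm(30, -10, 0.5), rnorm(30, 0, 0.5))
  res <- cluster_kmeans(rbind(cloud1, cloud2), k = 2, seed = 1)
  expect_equal(ari(rep(1:2, each = 30), res$labels), 1)
  # canonical order: cluster 1 has the larger PC1 centroid
  expect_gt(res$centroids[1, 1], res$centroids[2, 1])
  # k = 1: single label, centroid at the mean
  one <- cluster_kmeans(cloud1, k = 1, seed = 1)
  expect_true(all(one$labels == 1L))
  expect_equal(drop(one$centroids), colMeans(cloud1), tolerance = 1e-12)
  expect_error(cluster_kmeans(cloud1[1:3, ], k = 5, seed = 1), "exceeds")
})

test_that("canonical labels are invariant to row permutation", {
  wt <- make_cohort(c(C1 = 6, C2 = 6, C3 = 6, C4 = 6), seed = 31,
                    protocol = fast_protocol())
  wf <- cohort_features(wt)
  cls <- classify_cohort(wf$profiles, k = 4, seed = 5)
  set.seed(99)
  perm <- sample(nrow(wf$profiles))
  cls_p <- classify_cohort(wf$profiles[perm, ], k = 4, seed = 5)
  expect_identical(cls_p$labels, cls$labels[perm])
})

test_that("explained-variance fractions sum to one at full dimension", {
  set.seed(13)
  x <- matrix(rnorm(15 * 6), nrow = 15)
  m <- fit_pca(x, n_components = 6)
  expect_equal(sum(m$explained_variance), 1, tolerance = 1e-10)
  expect_true(all(diff(m$explained_variance) <= 1e-12))
  expect_equal(crossprod(m$loadings), diag(6), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("classifying the reference against itself reproduces proportions", {
  wt <- make_cohort(c(C1 = 5, C2 = 5, C3 = 5, C4 = 5), seed = 17,
                    protocol = fast_protocol())
  wf <- cohort_features(wt)
  cls <- classify_cohort(wf$profiles, test = wf$profiles, k = 4, seed = 2)
  expect_equal(cls$proportions$test, cls$proportions$reference)
  expect_identical(cls$test_labels, cls$labels)
  expect_error(classify_cohort(wf$profiles[0, , drop = FALSE]), "empty")
})

test_that("ARI degrades monotonically as class separation shrinks", {
  # shrink all profiles toward the grand mean profile before adding noise:
  # separation levels 1 (full) ... 0 (none), 10 seeds each
  # shrink normalized shapes toward the grand mean shape and add shape
  # noise: separation 1 (native) ... 0 (classes indistinguishable)
  wt <- make_cohort(c(C1 = 8, C2 = 8, C3 = 8, C4 = 8), seed = 53,
                    protocol = fast_protocol())
  wf <- cohort_features(wt)
  shapes <- vsm_normalize(wf$profiles)
  center <- colMeans(shapes)
  sep_levels <- c(1, 0.6, 0.35, 0.15, 0)
  mean_ari <- vapply(sep_levels, function(s) {
    mean(vapply(1:10, function(sd_i) {
      set.seed(1000 + sd_i)
      shrunk <- sweep(sweep(shapes, 2, center) * s, 2, center, "+") +
        matrix(rnorm(length(shapes), 0, 0.08), nrow = nrow(shapes))
      cls <- classify_cohort(shrunk, k = 4, seed = sd_i)
      ari(wf$truth, cls$labels)
    }, 0))
  }, 0)
  expect_true(all(diff(mean_ari) <= 0.05))   # monotone up to seed noise
  expect_gt(mean_ari[1], mean_ari[length(mean_ari)])
})

test_that("class summaries report means and suppress degenerate statistics", {
  wt <- make_cohort(c(C1 = 6, C2 = 6, C3 = 6, C4 = 6), seed = 19,
                    protocol = fast_protocol())
  wf <- cohort_features(wt)
  cls <- classify_cohort(wf$profiles, k = 4, seed = 3)
  s <- class_summaries(cls, wf$table)
  expect_identical(nrow(s$table), 4L)
  expect_identical(sum(s$table$n), 24L)
  expect_false(is.na(s$anova_p))
  # the C1 archetype cluster has the largest mean first-EPSC charge
  c1_cluster <- which.max(vapply(1:4, function(g) {
    mean(wf$table$epsc1_fC[cls$labels == g])
  }, 0))
  expect_gt(s$table$mean_epsc1_fC[c1_cluster], max(
    s$table$mean_epsc1_fC[-c1_cluster]))
  # single class: table emitted, tests suppressed
  one <- cluster_kmeans(cls$scores, k = 1, seed = 1)
  cls1 <- cls
  cls1$labels <- one$labels
  cls1$k <- 1L
  s1 <- class_summaries(cls1, wf$table)
  expect_identical(nrow(s1$table), 1L)
  expect_true(is.na(s1$anova_p))
})

test_that("summary ANOVA annotations control their type-I rate under the null", {
  # two recovered classes drawn from identical charge distributions: the
  # descriptive ANOVA should stay non-significant in >= 90% of draws
  skeleton <- structure(list(k = 2L, labels = rep(1:2, each = 20)),
                        class = "stp_classification")
  set.seed(77)
  p_vals <- vapply(seq_len(1000), function(i) {
    feats <- data.frame(epsc1_fC = rnorm(40, 120, 30),
                        ppr = rnorm(40, 1.5, 0.2))
    class_summaries(skeleton, feats)$anova_p
  }, 0)
  expect_gte(mean(p_vals > 0.05), 0.9)
})
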