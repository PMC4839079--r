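test_that("z-profiles: hand oracle, exclusions, normalization identity", {
  m <- rbind(
    lin = c(1, 1, 1, 2, 2, 2, 3, 3, 3),   # stage means (1, 2, 3)
    flat = rep(5, 9)
  )
  prof <- zscore_profiles(toy_expr(m))
  expect_equal(unname(prof$z["lin", ]), c(-1, 0, 1))  # sd(1,2,3) = 1
  expect_identical(prof$excluded, "flat")

  set.seed(2)
  m2 <- matrix(rexp(30 * 9, 0.1), ncol = 9)
  p2 <- zscore_profiles(toy_expr(m2))
  expect_true(all(abs(rowMeans(p2$z)) < 1e-9))
  expect_true(all(abs(apply(p2$z, 1, sd) - 1) < 1e-9))

  expect_error(zscore_profiles(toy_expr(m2), character(0)), "empty")
  expect_error(zscore_profiles(toy_expr(m2), "nope"), "not in matrix")
})

test_that("k-means recovers planted anticorrelated archetypes (ARI >= 0.9)", {
  arch <- rbind(c(-1, 0, 1), c(1, 0, -1), c(-1, 1.1, -0.4))
  aris <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    truth <- rep(1:3, each = 20)
    noisy <- arch[truth, ] + matrix(rnorm(180, sd = 0.15), ncol = 3)
    z <- t(scale(t(noisy)))  # z-profile normalization
    prof <- structure(list(z = `rownames<-`(z, paste0("f", 1:60)),
                           stage_order = c("S1", "S2", "S3"),
                           excluded = character(0)),
                      class = "profile_matrix")
    km <- kmeans_centered_correlation(prof, k = 3, restarts = 10,
                                      seed = 1000 + s)
    adjusted_rand_index(truth, km$assignments)
  }, 0)
  expect_true(all(aris >= 0.9))
})

test_that("k-means edge behavior: k = 1, duplicates, determinism, objective", {
  set.seed(9)
  z <- t(scale(t(matrix(rnorm(90), ncol = 3))))
  rownames(z) <- paste0("f", 1:30)
  prof <- structure(list(z = z, stage_order = c("S1", "S2", "S3"),
                         excluded = character(0)), class = "profile_matrix")

  km1 <- kmeans_centered_correlation(prof, k = 1, restarts = 3, seed = 1)
  expect_true(all(km1$assignments == 1L))
  expect_equal(unname(km1$centroids[1, ]), unname(colMeans(z)))

  # duplicates co-cluster at zero noise
  zdup <- z[rep(1:3, each = 10), ]
  rownames(zdup) <- paste0("g", 1:30)
  profdup <- structure(list(z = zdup, stage_order = c("S1", "S2", "S3"),
                            excluded = character(0)), class = "profile_matrix")
  kmd <- kmeans_centered_correlation(profdup, k = 3, restarts = 5, seed = 2)
  expect_identical(length(unique(kmd$assignments[1:10])), 1L)
  expect_identical(length(unique(kmd$assignments[11:20])), 1L)
  expect_identical(length(unique(kmd$assignments[21:30])), 1L)

  # determinism and non-increasing objective trace
  a <- kmeans_centered_correlation(prof, k = 4, restarts = 5, seed = 7)
  b <- kmeans_centered_correlation(prof, k = 4, restarts = 5, seed = 7)
  expect_identical(a$assignments, b$assignments)
  expect_true(all(diff(a$objective_trace) <= 1e-10))

  # all-identical profiles degenerate to one effective cluster
  zsame <- z[rep(1, 8), ]
  rownames(zsame) <- paste0("s", 1:8)
  profsame <- structure(list(z = zsame, stage_order = c("S1", "S2", "S3"),
                             excluded = character(0)),
                        class = "profile_matrix")
  expect_warning(kms <- kmeans_centered_correlation(profsame, 3, 2, 1),
                 "identical")
  expect_identical(length(unique(kms$assignments)), 1L)
})

test_that("PCA variance fractions: symmetry, eigen oracle, invariances", {
  # samples varying along one direction -> PC1 explains everything
  base <- matrix(rnorm(5), nrow = 1)
  X <- rbind(0 * base, 1 * base, 2 * base, 3 * base)
  pv <- pca_variance(X, 1)
  expect_equal(pv$variance_explained[1], 1)

  # hand eigen-decomposition oracle on a 3-sample toy
  Y <- matrix(c(1, 0, 2, 4, 3, 1), nrow = 3)
  ev <- eigen(cov(Y))$values
  pv2 <- pca_variance(Y, 2)
  expect_equal(pv2$variance_explained, (ev / sum(ev))[1:2])

  # feature permutation leaves fractions unchanged; order non-increasing
  set.seed(4)
  Z <- matrix(rnorm(9 * 20), nrow = 9)
  f1 <- pca_variance(Z, 5)$variance_explained
  f2 <- pca_variance(Z[, sample(20)], 5)$variance_explained
  expect_equal(f1, f2)
  expect_true(all(diff(f1) <= 1e-12))

  expect_warning(pca_variance(Y, 5), "truncated")
  expect_error(pca_variance(Y[1, , drop = FALSE], 1), "2 samples")
})

test_that("replicate dendrogram separates stage groups, hand-checked linkage", {
  set.seed(6)
  design <- toy_design(n_rep = 2L, stages = c("A", "B"))
  sig1 <- rexp(200, 0.05); sig2 <- rexp(200, 0.05)
  m <- cbind(sig1 + rnorm(200, sd = 2), sig1 + rnorm(200, sd = 2),
             sig2 + rnorm(200, sd = 2), sig2 + rnorm(200, sd = 2))
  m <- pmax(m, 0)
  dend <- replicate_dendrogram(toy_expr(m, design))
  # the two top clades must be the two stage groups
  cut <- cutree(dend$hclust, k = 2)
  expect_identical(length(unique(cut[c("Aa", "Ab")])), 1L)
  expect_identical(length(unique(cut[c("Ba", "Bb")])), 1L)
  expect_false(cut[["Aa"]] == cut[["Ba"]])
  expect_match(dend$newick, "^\\(.*\\);$")

  expect_true(isSymmetric(dend$dist))
  expect_true(all(diag(dend$dist) == 0))

  # identical replicate columns merge at height 0
  m2 <- cbind(m[, 1], m[, 1], m[, 3], m[, 4])
  d2 <- replicate_dendrogram(toy_expr(m2, design))
  expect_equal(min(d2$hclust$height), 0)

  m3 <- m; m3[, 2] <- 7
  expect_error(replicate_dendrogram(toy_expr(m3, design)), "Ab")
})
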