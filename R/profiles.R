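#' Z-normalized stage-mean expression profiles
#'
#' Per feature, replicate values are averaged within each stage and the
#' resulting stage-mean profile is centered and scaled by its sample
#' standard deviation (n-1). Features with zero variance across stages carry
#' no pattern information and are excluded (and reported).
#'
#' @param expr an [expression_matrix()].
#' @param features feature IDs to profile (default: all).
#' @return list of class `profile_matrix`: `z` (features x stages matrix),
#'   `stage_order`, `excluded` (zero-variance feature IDs).
#' @export
zscore_profiles <- function(expr, features = rownames(expr$values)) {
  if (!length(features)) stop("empty feature set")
  missing <- setdiff(features, rownames(expr$values))
  if (length(missing)) {
    stop("features not in matrix: ", paste(missing, collapse = ", "))
  }
  design <- expr$design
  means <- vapply(design$stage_order, function(st) {
    rowMeans(expr$values[features, stage_samples(design, st), drop = FALSE])
  }, numeric(length(features)))
  if (length(features) == 1L) means <- matrix(means, nrow = 1L)
  dimnames(means) <- list(features, design$stage_order)
  sds <- apply(means, 1L, stats::sd)
  keep <- sds > 0
  z <- (means[keep, , drop = FALSE] -
          rowMeans(means[keep, , drop = FALSE])) / sds[keep]
  structure(
    list(z = z, stage_order = design$stage_order,
         excluded = features[!keep]),
    class = "profile_matrix"
  )
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("profile_matrix:", nrow(x$z), "features x", ncol(x$z), "stages (",
      length(x$excluded), "zero-variance features excluded )\n")
  invisible(x)
}

# centered correlation dissimilarity of rows of X against rows of C:
# d = 1 - Pearson(x, c); zero-variance vectors get r = 0 (maximal d = 1)
centered_cor_dist <- function(X, C) {
  Xc <- X - rowMeans(X)
  Cc <- C - rowMeans(C)
  xs <- sqrt(rowSums(Xc^2))
  cs <- sqrt(rowSums(Cc^2))
  r <- tcrossprod(Xc, Cc) / outer(xs, cs)
  r[!is.finite(r)] <- 0
  1 - r
}

#' K-means clustering of expression profiles under centered correlation
#'
#' Lloyd-style k-means on z-normalized stage profiles with dissimilarity
#' d(x, c) = 1 - Pearson(x, c) (the "centered correlation" of the classic
#' Gene Cluster tools) and member means as centroids. The best of `restarts`
#' seeded random initializations by total within-cluster dissimilarity is
#' returned; an empty cluster is re-seeded from the point farthest from its
#' current centroid; iteration stops on stable assignments or after 100
#' rounds. Fully deterministic given `seed`.
#'
#' @param profiles a `profile_matrix` from [zscore_profiles()].
#' @param k number of clusters (default 12).
#' @param restarts random restarts (default 20).
#' @param seed RNG seed.
#' @return list with `assignments` (named integer vector), `centroids`
#'   (k x stages matrix), `objective` (total within-cluster dissimilarity),
#'   and `objective_trace` of the winning run.
#' @export
kmeans_centered_correlation <- function(profiles, k = 12L, restarts = 20L,
                                        seed = 1L) {
  X <- profiles$z
  n <- nrow(X)
  if (k < 1L) stop("k must be >= 1")
  if (n < k) stop("fewer profiles than clusters")
  if (n > 1L) {
    d0 <- centered_cor_dist(X, X[1L, , drop = FALSE])
    if (all(d0 < 1e-12) && k > 1L) {
      warning("all profiles identical; returning one effective cluster")
      return(list(
        assignments = stats::setNames(rep(1L, n), rownames(X)),
        centroids = X[rep(1L, k), , drop = FALSE],
        objective = 0, objective_trace = 0
      ))
    }
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(seed + r - 1L)
    centers <- X[sample.int(n, k), , drop = FALSE]
    assign_old <- rep(0L, n)
    trace <- numeric(0)
    for (iter in seq_len(100L)) {
      D <- centered_cor_dist(X, centers)
      assign_new <- max.col(-D, ties.method = "first")
      for (j in seq_len(k)) {
        if (!any(assign_new == j)) {
          # re-seed empty cluster from the worst-fit point
          worst <- which.max(D[cbind(seq_len(n), assign_new)])
          assign_new[worst] <- j
        }
      }
      centers <- rowsum(X, assign_new) / as.vector(table(assign_new))
      D2 <- centered_cor_dist(X, centers)
      trace <- c(trace, sum(D2[cbind(seq_len(n), assign_new)]))
      if (identical(assign_new, assign_old)) break
      assign_old <- assign_new
    }
    obj <- trace[length(trace)]
    if (is.null(best) || obj < best$objective) {
      best <- list(
        assignments = stats::setNames(assign_new, rownames(X)),
        centroids = centers, objective = obj, objective_trace = trace
      )
    }
  }
  best
}

#' Principal component analysis of z-normalized expression
#'
#' PCA with samples (replicates) as observations and features as variables,
#' applied to per-feature z-normalized data. Component signs are fixed by
#' making each component's largest-magnitude loading positive, so results
#' are reproducible across platforms.
#'
#' @param expr_z numeric matrix, samples x features (z-normalized columns).
#' @param n_components number of components to report.
#' @return list with `scores` (samples x components), `variance_explained`
#'   (fractions, non-increasing, summing to <= 1).
#' @export
pca_variance <- function(expr_z, n_components = 2L) {
  if (nrow(expr_z) < 2L) stop("PCA needs >= 2 samples")
  pc <- stats::prcomp(expr_z, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > 1e-12)
  if (n_components > rank) {
    warning("n_components exceeds rank; truncated to ", rank)
    n_components <- rank
  }
  flip <- vapply(seq_len(n_components), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, 0)
  scores <- sweep(pc$x[, seq_len(n_components), drop = FALSE], 2L, flip, "*")
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores,
       variance_explained = ve[seq_len(n_components)])
}

#' Replicate similarity dendrogram
#'
#' Samples are hierarchically clustered with complete linkage on the
#' distance 1 - Pearson correlation of their expression vectors; used to
#' verify that replicates of a stage group together and that stages
#' separate. The tree is returned as `hclust` plus a Newick string with
#' branch heights.
#'
#' @param expr an [expression_matrix()].
#' @return list with `hclust`, `newick`, and the `dist` matrix.
#' @export
replicate_dendrogram <- function(expr) {
  m <- expr$values
  if (ncol(m) < 2L) stop("need >= 2 samples")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance sample, correlation undefined: ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  }
  d <- stats::as.dist(1 - stats::cor(m))
  hc <- stats::hclust(d, method = "complete")
  phy <- ape::as.phylo(hc)
  list(hclust = hc, newick = ape::write.tree(phy), dist = as.matrix(d))
}
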