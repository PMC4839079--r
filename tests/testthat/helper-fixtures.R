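# shared fixture builders and independent oracles

toy_design <- function(n_rep = 3L, stages = c("S1", "S2", "S3")) {
  samples <- as.vector(t(outer(stages, letters[seq_len(n_rep)], paste0)))
  experiment_design(
    samples = samples,
    stage_of = setNames(rep(stages, each = n_rep), samples),
    stage_order = stages
  )
}

# expression matrix straight from a features x samples value matrix
toy_expr <- function(values, design = toy_design()) {
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("f", seq_len(nrow(values)))
  }
  colnames(values) <- design$samples
  expression_matrix(values, design)
}

toy_counts <- function(values, design = toy_design()) {
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("f", seq_len(nrow(values)))
  }
  colnames(values) <- design$samples
  count_matrix(values, design)
}

random_count_matrix <- function(n_features, design = toy_design(),
                                lambda = 30) {
  m <- matrix(rpois(n_features * length(design$samples), lambda),
              nrow = n_features)
  toy_counts(m, design)
}

# adjusted Rand index, direct from the contingency-table formula
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# brute-force DE oracle: per-feature loop, no vectorization shared with
# call_de; uses p.adjust as the independent BH route
brute_force_de <- function(expr, transition, cfg) {
  design <- expr$design
  tr <- design$transitions[[transition]]
  a_cols <- stage_samples(design, tr[1]); b_cols <- stage_samples(design, tr[2])
  ids <- rownames(expr$values)
  passed <- logical(length(ids)); p <- rep(NA_real_, length(ids))
  for (i in seq_along(ids)) {
    a <- expr$values[i, a_cols]; b <- expr$values[i, b_cols]
    ma <- mean(a); mb <- mean(b)
    if (ma == 0 && mb == 0) next
    hi <- max(ma, mb); lo <- min(ma, mb)
    fold <- if (lo == 0) Inf else hi / lo
    cva <- if (ma == 0) 0 else sd(a) / ma
    cvb <- if (mb == 0) 0 else sd(b) / mb
    if (hi >= cfg$de_min_rpmqn && fold >= cfg$de_min_fold &&
        cva <= cfg$de_max_cv && cvb <= cfg$de_max_cv) {
      passed[i] <- TRUE
      if (sd(a) == 0 && sd(b) == 0) {
        p[i] <- if (ma == mb) 1 else 0
      } else {
        p[i] <- t.test(a, b, var.equal = TRUE)$p.value
      }
    }
  }
  de <- logical(length(ids))
  idx <- which(passed)
  if (length(idx)) {
    de[idx] <- p.adjust(p[idx], method = "BH") <= cfg$de_fdr_alpha
  }
  list(passed = passed, p = p, de = de)
}
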