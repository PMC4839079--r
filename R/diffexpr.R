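#' Fold change between two stage means
#'
#' Always expressed as the larger mean over the smaller (>= 1); a zero
#' smaller mean gives +Inf. Direction is "up" when the later stage of the
#' transition has the higher mean, "down" otherwise; an exact tie is
#' reported as "down" by convention (fold 1 can never pass the filter, so
#' the choice is inert).
#'
#' @param mean_a mean of the earlier stage (>= 0).
#' @param mean_b mean of the later stage (>= 0).
#' @return list with `fold` and `direction`.
#' @export
fold_change <- function(mean_a, mean_b) {
  if (mean_a < 0 || mean_b < 0) stop("means must be >= 0")
  if (mean_a == 0 && mean_b == 0) {
    stop("fold change undefined for two zero means")
  }
  hi <- max(mean_a, mean_b)
  lo <- min(mean_a, mean_b)
  list(fold = if (lo == 0) Inf else hi / lo,
       direction = if (mean_b > mean_a) "up" else "down")
}

#' Replicate coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the mean. An
#' all-zero stage is defined to have CV 0.
#'
#' @param replicates numeric vector of >= 2 replicate values.
#' @return the coefficient of variation.
#' @export
stage_cv <- function(replicates) {
  if (length(replicates) < 2L) stop("stage_cv needs >= 2 replicates")
  m <- mean(replicates)
  if (m == 0) {
    if (all(replicates == 0)) return(0)
    stop("zero mean with non-zero replicates")  # impossible for rpmqn >= 0
  }
  stats::sd(replicates) / m
}

#' Two-sided pooled-variance Student's t-test p-value
#'
#' Equal-variance two-sample t with df = n_a + n_b - 2. Degenerate cases:
#' both groups have zero variance and equal means -> p = 1; zero variance
#' and unequal means -> p = 0.
#'
#' @param group_a,group_b numeric vectors of >= 2 values.
#' @return two-sided p-value.
#' @export
student_t_p <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("student_t_p needs >= 2 values per group")
  va <- stats::var(group_a); vb <- stats::var(group_b)
  ma <- mean(group_a); mb <- mean(group_b)
  if (va == 0 && vb == 0) return(if (ma == mb) 1 else 0)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  tval <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * stats::pt(-abs(tval), df = na + nb - 2)
}

#' Benjamini-Hochberg step-up rejections
#'
#' Standard step-up rule at level `alpha`: reject all hypotheses with rank
#' at or below the largest k such that p_(k) <= k * alpha / m.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @param alpha FDR level in (0, 1).
#' @return logical vector of rejections, aligned with `p_values`.
#' @export
bh_fdr <- function(p_values, alpha) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  if (!m) return(logical(0))
  o <- order(p_values)
  ok <- p_values[o] <= seq_len(m) * alpha / m
  kmax <- if (any(ok)) max(which(ok)) else 0L
  rej <- logical(m)
  if (kmax > 0L) rej[o[seq_len(kmax)]] <- TRUE
  rej
}

#' Differential expression filter cascade for one stage transition
#'
#' A feature passes the filters iff the higher stage mean is at least
#' `de_min_rpmqn`, the fold change is at least `de_min_fold`, and the
#' replicate CV is at most `de_max_cv` in both stages. Student's t-test
#' p-values are computed for filter-passing features only and
#' Benjamini-Hochberg correction is applied across that set at
#' `de_fdr_alpha`; a feature is differentially expressed iff it passes the
#' filters and survives FDR control.
#'
#' @param expr an [expression_matrix()] in rpmqn units.
#' @param transition length-2 character vector (from-stage, to-stage) or the
#'   name of a design transition (e.g. "T1").
#' @param cfg a [pipeline_config()].
#' @return data.frame with one row per feature: `feature_id`, `transition`,
#'   `mean_from`, `mean_to` (earlier/later stage means), `mean_low`,
#'   `mean_high` (smaller/larger of the two), `fold_change`,
#'   `direction`, `cv_low`, `cv_high`, `p_value` (NA unless filters passed),
#'   `q_significant`, `passed_filters`, `de`.
#' @export
call_de <- function(expr, transition, cfg = pipeline_config()) {
  design <- expr$design
  if (is.character(transition) && length(transition) == 1L) {
    if (!transition %in% names(design$transitions)) {
      stop("unknown transition: ", transition)
    }
    label <- transition
    transition <- design$transitions[[transition]]
  } else {
    label <- paste(transition, collapse = "->")
  }
  if (!all(transition %in% design$stage_order)) {
    stop("transition stages not in design")
  }
  check_replicated(design)
  a_cols <- stage_samples(design, transition[1L])
  b_cols <- stage_samples(design, transition[2L])
  A <- expr$values[, a_cols, drop = FALSE]
  B <- expr$values[, b_cols, drop = FALSE]
  ma <- rowMeans(A)
  mb <- rowMeans(B)
  hi <- pmax(ma, mb)
  lo <- pmin(ma, mb)
  fold <- ifelse(hi == 0, NA_real_, ifelse(lo == 0, Inf, hi / lo))
  direction <- ifelse(mb > ma, "up", "down")
  sda <- apply(A, 1L, stats::sd)
  sdb <- apply(B, 1L, stats::sd)
  cva <- ifelse(ma == 0, 0, sda / ma)
  cvb <- ifelse(mb == 0, 0, sdb / mb)
  passed <- !is.na(fold) &
    hi >= cfg$de_min_rpmqn &
    fold >= cfg$de_min_fold &
    cva <= cfg$de_max_cv & cvb <= cfg$de_max_cv
  p <- rep(NA_real_, nrow(expr$values))
  idx <- which(passed)
  p[idx] <- vapply(idx, function(i) student_t_p(A[i, ], B[i, ]), 0)
  q_sig <- rep(FALSE, nrow(expr$values))
  if (length(idx)) q_sig[idx] <- bh_fdr(p[idx], cfg$de_fdr_alpha)
  data.frame(
    feature_id = rownames(expr$values),
    transition = label,
    mean_from = ma, mean_to = mb,
    mean_low = lo, mean_high = hi,
    fold_change = fold, direction = direction,
    cv_low = cva, cv_high = cvb,
    p_value = p,
    q_significant = q_sig,
    passed_filters = passed,
    de = passed & q_sig,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Summarize DE calls as the field reports them
#'
#' Counts of DE features with up/down percentages (via [percent()]).
#'
#' @param calls data.frame from [call_de()].
#' @return list with `transition`, `n_de`, `n_up`, `n_down`, `pct_up`,
#'   `pct_down`.
#' @export
summarize_de <- function(calls) {
  de <- calls[calls$de, , drop = FALSE]
  n <- nrow(de)
  up <- sum(de$direction == "up")
  list(
    transition = calls$transition[[1]],
    n_de = n, n_up = up, n_down = n - up,
    pct_up = if (n) percent(up, n) else NA_real_,
    pct_down = if (n) percent(n - up, n) else NA_real_
  )
}
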