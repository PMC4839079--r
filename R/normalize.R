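#' Zero-preserving quantile normalization
#'
#' Classical quantile normalization equalizes the value distribution across
#' libraries: each column is sorted, a reference distribution is formed as
#' the positionwise mean of the sorted columns, and every entry is replaced
#' by the reference value at its within-column rank (ties receive the mean of
#' the reference values over the tied rank positions). Applied to sparse
#' count data this allocates positive expression to features with zero reads;
#' the modification here resets every entry whose raw count is zero back to
#' exactly zero afterwards, so unexpressed features never gain expression.
#'
#' @param counts a [count_matrix()] with at least 2 samples.
#' @return numeric matrix of normalized values (same dimnames), zeros
#'   preserved, not yet scaled to rpmqn.
#' @seealso [scale_rpmqn()], [normalize_rpmqn()]
#' @export
quantile_normalize_zero_preserving <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$values else as.matrix(counts)
  if (nrow(m) < 1L) stop("empty matrix")
  if (ncol(m) < 2L) stop("quantile normalization needs >= 2 samples")
  n <- nrow(m)
  sorted <- apply(m, 2L, sort, method = "radix")
  reference <- rowMeans(matrix(sorted, nrow = n))
  out <- apply(m, 2L, function(col) {
    o <- order(col, method = "radix")
    v <- col[o]
    # runs of equal values share the mean reference value over their ranks
    grp <- cumsum(c(TRUE, v[-1L] != v[-n]))
    res <- numeric(n)
    res[o] <- stats::ave(reference, grp)
    res
  })
  dimnames(out) <- dimnames(m)
  out[m == 0] <- 0
  out
}

#' Scale a normalized matrix to reads per million quantile-normalized reads
#'
#' Each column is multiplied by `1e6 / colsum`, so every library sums to one
#' million quantile-normalized reads (rpmqn). Zeros stay zero.
#'
#' @param normalized numeric matrix from
#'   [quantile_normalize_zero_preserving()].
#' @param design an [experiment_design()].
#' @return an [expression_matrix()] in rpmqn units.
#' @export
scale_rpmqn <- function(normalized, design) {
  m <- as.matrix(normalized)
  sums <- colSums(m)
  if (any(sums <= 0)) {
    stop("all-zero library cannot be scaled: ",
         paste(colnames(m)[sums <= 0], collapse = ", "))
  }
  m <- sweep(m, 2L, 1e6 / sums, "*")
  expression_matrix(m, design)
}

#' Normalize counts to rpmqn
#'
#' Convenience wrapper: zero-preserving quantile normalization followed by
#' per-library scaling to one million quantile-normalized reads.
#'
#' @param counts a [count_matrix()].
#' @return an [expression_matrix()] in rpmqn units.
#' @export
normalize_rpmqn <- function(counts) {
  scale_rpmqn(quantile_normalize_zero_preserving(counts), counts$design)
}
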