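#' Call expressed features per stage
#'
#' A feature counts as expressed in a stage if its rpmqn value is at or above
#' the threshold in ALL replicates of that stage; it is expressed overall if
#' that holds for at least one stage. The boundary is inclusive ("equal or
#' higher").
#'
#' @param expr an [expression_matrix()].
#' @param threshold minimum rpmqn (default 1).
#' @return object of class `expressed_sets`: list with `stages` (named list
#'   of feature-ID character vectors), `universe_size`, and `expressed`
#'   (union over stages).
#' @export
call_expressed <- function(expr, threshold = 1) {
  if (threshold <= 0) stop("threshold must be > 0")
  design <- expr$design
  check_replicated(design)
  sets <- lapply(design$stage_order, function(st) {
    cols <- stage_samples(design, st)
    sub <- expr$values[, cols, drop = FALSE]
    rownames(expr$values)[rowSums(sub >= threshold) == length(cols)]
  })
  names(sets) <- design$stage_order
  structure(
    list(stages = sets,
         universe_size = nrow(expr$values),
         expressed = sort(unique(unlist(sets, use.names = FALSE)))),
    class = "expressed_sets"
  )
}

#' @export
print.expressed_sets <- function(x, ...) {
  cat("expressed_sets over", x$universe_size, "features:\n")
  for (st in names(x$stages)) {
    cat(sprintf("  %s: %d (%s %%)\n", st, length(x$stages[[st]]),
                format_percent(percent(length(x$stages[[st]]),
                                       x$universe_size))))
  }
  invisible(x)
}

#' Three-set Venn partition of expressed sets
#'
#' Counts the 7 exclusive regions of three stage sets: each stage alone, each
#' pairwise-only overlap and the core expressed in all three. Regions are
#' disjoint and sum to the union size.
#'
#' @param sets an `expressed_sets` with exactly 3 stages.
#' @return named integer vector with elements `<S1>_only`, `<S2>_only`,
#'   `<S3>_only`, `<S1>_<S2>_only`, `<S1>_<S3>_only`, `<S2>_<S3>_only`,
#'   `core`, plus attribute `union_size`.
#' @export
venn_partition <- function(sets) {
  if (length(sets$stages) != 3L) stop("venn_partition needs exactly 3 stages")
  s <- sets$stages
  nm <- names(s)
  universe <- unique(unlist(s, use.names = FALSE))
  inset <- vapply(s, function(x) universe %in% x, logical(length(universe)))
  if (length(universe) == 1L) inset <- matrix(inset, nrow = 1L)
  code <- inset %*% c(1L, 2L, 4L)
  counts <- vapply(1:7, function(k) sum(code == k), 0L)
  out <- c(counts[1L], counts[2L], counts[4L],   # singles
           counts[3L], counts[5L], counts[6L],   # pairs
           counts[7L])                           # core
  names(out) <- c(paste0(nm, "_only"),
                  paste0(nm[1L], "_", nm[2L], "_only"),
                  paste0(nm[1L], "_", nm[3L], "_only"),
                  paste0(nm[2L], "_", nm[3L], "_only"),
                  "core")
  attr(out, "union_size") <- length(universe)
  out
}

#' Percentage with half-away-from-zero rounding
#'
#' `100 * count / total` rounded to `decimals` places with ties rounded away
#' from zero (the convention that reproduces the published percentages;
#' base R `round` rounds half to even).
#'
#' @param count numerator, `0 <= count <= total`.
#' @param total denominator, `> 0`.
#' @param decimals digits after the point (default 2).
#' @return the rounded percentage.
#' @examples
#' percent(14792, 20224)  # 73.14
#' @export
percent <- function(count, total, decimals = 2L) {
  if (length(total) != 1L || total <= 0) stop("total must be > 0")
  if (any(count < 0) || any(count > total)) {
    stop("count must lie in [0, total]")
  }
  x <- 100 * count / total
  f <- 10^decimals
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Format a percentage the way the field prints it (trailing zeros trimmed)
#' @param x value from [percent()].
#' @return character scalar, e.g. "74.3".
#' @export
format_percent <- function(x) {
  out <- sub("0+$", "", sprintf("%.2f", x))
  sub("\\.$", "", out)
}
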