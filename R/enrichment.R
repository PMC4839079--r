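#' Exact upper-tail binomial probability
#'
#' P(X >= observed) for X ~ Binomial(n, p). Serves as the closed-form oracle
#' for the with-replacement bootstrap: drawing a set of size n with
#' replacement from a universe in which a fraction p of features carry a
#' term makes the per-draw term count exactly Binomial(n, p).
#'
#' @param observed integer in [0, n].
#' @param n number of draws.
#' @param p per-draw success probability.
#' @return P(X >= observed).
#' @export
binomial_tail <- function(observed, n, p) {
  if (observed < 0 || observed > n) stop("observed must lie in [0, n]")
  if (observed == 0) return(1)
  stats::pbinom(observed - 1, size = n, prob = p, lower.tail = FALSE)
}

#' Bootstrap p-value for term over-representation
#'
#' Draws `runs` random feature sets of the observed set's size with
#' replacement from the annotated universe and counts, per run, how many
#' sampled features carry the term; the p-value is
#' `(1 + #\{run count >= observed\}) / (runs + 1)`, never exactly zero. Since
#' with-replacement draws make the run count Binomial(set_size,
#' term_frequency), the counts are drawn directly from that distribution,
#' which is the identical process executed in O(runs) time. A
#' without-replacement variant (hypergeometric run counts) is available via
#' `replace = FALSE`, for which `universe_size` must be supplied.
#'
#' @param observed observed number of set members carrying the term.
#' @param set_size size of the feature set.
#' @param term_frequency fraction of the annotated universe carrying the
#'   term, in [0, 1].
#' @param runs number of bootstrap runs.
#' @param seed RNG seed; the draw is deterministic given the seed.
#' @param replace sample with replacement (default TRUE).
#' @param universe_size annotated-universe size, needed when
#'   `replace = FALSE`.
#' @return bootstrap p-value in (0, 1].
#' @export
bootstrap_p <- function(observed, set_size, term_frequency, runs,
                        seed = 1L, replace = TRUE, universe_size = NULL) {
  if (runs < 1) stop("runs must be >= 1")
  if (term_frequency < 0 || term_frequency > 1) {
    stop("term_frequency must lie in [0, 1]")
  }
  if (observed > set_size) stop("observed exceeds set_size")
  set.seed(seed)
  if (replace) {
    counts <- stats::rbinom(runs, size = set_size, prob = term_frequency)
  } else {
    if (is.null(universe_size)) {
      stop("universe_size required for without-replacement sampling")
    }
    K <- round(term_frequency * universe_size)
    counts <- stats::rhyper(runs, m = K, n = universe_size - K, k = set_size)
  }
  (1 + sum(counts >= observed)) / (runs + 1)
}

#' GO term enrichment of a feature set by bootstrap
#'
#' Tests every term carried by at least `enrich_min_count` members of the
#' set (terms below the minimum are excluded BEFORE testing) against the
#' frequency of the term in the annotated universe, using [bootstrap_p()].
#' Benjamini-Hochberg correction is applied across the surviving terms of
#' this one set at `enrich_fdr_alpha`. The universe is restricted to
#' features carrying at least one term, since unannotated features cannot
#' inform term frequencies.
#'
#' @param features character vector, the feature set (subset of universe).
#' @param annotation named list: feature ID -> character vector of terms.
#' @param universe character vector of candidate features; defaults to all
#'   annotated features.
#' @param cfg a [pipeline_config()]; uses `boot_runs`, `enrich_min_count`,
#'   `enrich_fdr_alpha`, `rng_seed`.
#' @param replace passed to [bootstrap_p()].
#' @return data.frame sorted by p-value: `go_term`, `observed_count`,
#'   `set_size`, `universe_count`, `universe_frequency`, `p_value`,
#'   `q_significant`.
#' @export
enrich_set <- function(features, annotation, universe = names(annotation),
                       cfg = pipeline_config(), replace = TRUE) {
  universe <- intersect(universe, names(annotation))
  if (!length(universe)) stop("empty annotated universe")
  features <- intersect(features, universe)
  set_size <- length(features)
  uni_terms <- table(unlist(annotation[universe], use.names = FALSE))
  set_terms <- table(unlist(annotation[features], use.names = FALSE))
  set_terms <- set_terms[set_terms >= cfg$enrich_min_count]
  empty <- data.frame(go_term = character(0), observed_count = integer(0),
                      set_size = integer(0), universe_count = integer(0),
                      universe_frequency = numeric(0), p_value = numeric(0),
                      q_significant = logical(0))
  if (!length(set_terms)) return(empty)
  terms <- names(set_terms)
  freq <- as.numeric(uni_terms[terms]) / length(universe)
  p <- vapply(seq_along(terms), function(i) {
    bootstrap_p(as.integer(set_terms[[i]]), set_size, freq[[i]],
                runs = cfg$boot_runs, seed = cfg$rng_seed + i,
                replace = replace, universe_size = length(universe))
  }, 0)
  out <- data.frame(
    go_term = terms,
    observed_count = as.integer(set_terms),
    set_size = set_size,
    universe_count = as.integer(uni_terms[terms]),
    universe_frequency = freq,
    p_value = p,
    q_significant = bh_fdr(p, cfg$enrich_fdr_alpha),
    stringsAsFactors = FALSE
  )
  out[order(out$p_value, out$go_term), , drop = FALSE]
}
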