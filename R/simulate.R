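#' Simulation configuration
#'
#' The stated world for the synthetic datasets: a 3-stage x 3-replicate
#' design with overdispersed negative-binomial counts, planted fold changes
#' on the two stage transitions, planted GO enrichments, small-RNA libraries
#' with 21-nt and 24-nt abundance peaks, and planted negatively correlated
#' sRNA/target pairs. Defaults mirror the published experiment where it
#' states numbers (DE fractions 756/20224 and 5629/20224; down-regulated
#' fractions 66.67 % in T1 and 56.96 % in T2; sRNA length peaks) and use
#' field-realistic desk-scale values elsewhere (see the methods vignette).
#'
#' @param n_features number of transcript features (default 2000).
#' @param design an [experiment_design()] (default [default_design()]).
#' @param lib_size_mean expected total counts per library (default 6e6:
#'   scaling the study's ~20,000 transcripts at ~60 million reads down to
#'   2,000 features while preserving its ~3,000 reads-per-feature depth, so
#'   replicate CV reflects biological dispersion rather than shot noise).
#' @param nb_dispersion NB dispersion alpha (variance = mu + alpha mu^2);
#'   default 0.01, i.e. 10 % biological CV between replicates.
#' @param frac_de_t1,frac_de_t2 fractions of features differentially
#'   expressed on T1 / T2 (defaults 0.037 and 0.28).
#' @param down_prob_t1,down_prob_t2 probability a DE feature is
#'   down-regulated in the transition (defaults 2/3 and 0.57).
#' @param de_fold_range length-2 numeric, fold changes drawn log-uniformly
#'   from this interval (default c(2, 8); low end must be >= 1).
#' @param frac_zero fraction of count entries forced to zero (default 0.01).
#' @param n_go_terms number of GO terms in the simulated annotation
#'   (default 50).
#' @param go_base_rate_range per-term base annotation rates drawn uniformly
#'   from this interval (default c(0.01, 0.05)).
#' @param planted_enriched list of `list(archetype=, term=, factor=)`
#'   entries: features of that expression archetype get the term at base
#'   rate x factor (capped at 1). Default empty.
#' @param srna_n_distinct number of distinct sRNA sequences (default 3000).
#' @param srna_len_weights named numeric vector, sequence length (15-28) ->
#'   sampling weight; default has its mode at 24 nt and a secondary mode at
#'   21 nt.
#' @param frac_srna_trend fraction of sRNAs given a monotone stage trend
#'   (default 0.3), providing anticorrelation partners for target pairs.
#' @param n_planted_mirnas sRNAs copied verbatim into the mature-miRNA
#'   reference (default 20).
#' @param n_target_pairs candidate sRNA/target pairs (default 200).
#' @param frac_anticorrelated_pairs fraction of pairs planted as strongly
#'   anticorrelated, stage-mean Pearson r <= -0.95 (default 0.3).
#' @param seed integer RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_features = 2000L,
                       design = default_design(),
                       lib_size_mean = 6e6,
                       nb_dispersion = 0.01,
                       frac_de_t1 = 0.037,
                       frac_de_t2 = 0.28,
                       down_prob_t1 = 2 / 3,
                       down_prob_t2 = 0.57,
                       de_fold_range = c(2, 8),
                       frac_zero = 0.01,
                       n_go_terms = 50L,
                       go_base_rate_range = c(0.01, 0.05),
                       planted_enriched = list(),
                       srna_n_distinct = 3000L,
                       srna_len_weights = default_srna_len_weights(),
                       frac_srna_trend = 0.3,
                       n_planted_mirnas = 20L,
                       n_target_pairs = 200L,
                       frac_anticorrelated_pairs = 0.3,
                       seed = 1L) {
  cfg <- list(n_features = as.integer(n_features), design = design,
              lib_size_mean = lib_size_mean, nb_dispersion = nb_dispersion,
              frac_de_t1 = frac_de_t1, frac_de_t2 = frac_de_t2,
              down_prob_t1 = down_prob_t1, down_prob_t2 = down_prob_t2,
              de_fold_range = de_fold_range, frac_zero = frac_zero,
              n_go_terms = as.integer(n_go_terms),
              go_base_rate_range = go_base_rate_range,
              planted_enriched = planted_enriched,
              srna_n_distinct = as.integer(srna_n_distinct),
              srna_len_weights = srna_len_weights,
              frac_srna_trend = frac_srna_trend,
              n_planted_mirnas = as.integer(n_planted_mirnas),
              n_target_pairs = as.integer(n_target_pairs),
              frac_anticorrelated_pairs = frac_anticorrelated_pairs,
              seed = as.integer(seed))
  fracs <- c("frac_de_t1", "frac_de_t2", "down_prob_t1", "down_prob_t2",
             "frac_srna_trend", "frac_anticorrelated_pairs")
  for (f in fracs) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  }
  if (cfg$frac_zero < 0 || cfg$frac_zero >= 1) {
    stop("frac_zero must lie in [0, 1)")
  }
  if (length(cfg$de_fold_range) != 2L || cfg$de_fold_range[1] < 1) {
    stop("de_fold_range must be (low, high) with low >= 1")
  }
  if (cfg$de_fold_range[1] > cfg$de_fold_range[2]) {
    stop("de_fold_range low must be <= high")
  }
  w <- cfg$srna_len_weights
  if (is.null(names(w))) stop("srna_len_weights must be named by length")
  lens <- as.integer(names(w))
  if (any(lens < 15L | lens > 28L)) {
    stop("srna_len_weights lengths must lie in [15, 28]")
  }
  if (any(w < 0) || all(w == 0)) {
    stop("srna_len_weights must be non-negative and not all zero")
  }
  for (pe in cfg$planted_enriched) {
    if (!all(c("archetype", "term", "factor") %in% names(pe))) {
      stop("planted_enriched entries need archetype, term, factor")
    }
    if (pe$factor <= 0) stop("enrichment factor must be > 0")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' @describeIn sim_config Default sRNA length weights: dominant 24-nt siRNA
#'   peak, secondary 21-nt miRNA peak, low tails elsewhere.
#' @export
default_srna_len_weights <- function() {
  stats::setNames(c(1, 1, 1, 1.5, 2, 3, 8, 3, 2, 12, 2, 1, 1, 1),
                  as.character(15:28))
}

# archetype label for a DE pattern: direction on T1 and T2 ("flat" if not DE)
archetype_label <- function(d1, d2) paste(d1, d2, sep = "_")

#' Simulate a staged count matrix with planted differential expression
#'
#' Counts are negative binomial with per-feature log-normal baseline
#' abundances, per-library log-normal size factors around `lib_size_mean`,
#' and dispersion `nb_dispersion`. A fraction of features is planted as DE
#' on T1 and/or T2: their stage means are scaled by a fold drawn
#' log-uniformly from `de_fold_range` in a direction drawn with the
#' configured down-probability. `frac_zero` of entries are then forced to
#' zero. Fully deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `counts` (a [count_matrix()]) and `truth` (list:
#'   per-feature data.frame `features` with true fold/direction per
#'   transition and archetype, plus `de_t1`, `de_t2` ID vectors).
#' @export
simulate_counts <- function(cfg) {
  set.seed(cfg$seed)
  design <- cfg$design
  n <- cfg$n_features
  stages <- design$stage_order
  if (length(stages) != 3L) stop("simulate_counts assumes 3 stages")
  ids <- sprintf("transcript_%04d", seq_len(n))

  base <- stats::rlnorm(n, meanlog = log(40), sdlog = 1.3)
  sf <- stats::rlnorm(length(design$samples), meanlog = 0, sdlog = 0.1)
  names(sf) <- design$samples

  de1 <- stats::rbinom(n, 1L, cfg$frac_de_t1) == 1L
  de2 <- stats::rbinom(n, 1L, cfg$frac_de_t2) == 1L
  dir1 <- ifelse(de1,
                 ifelse(stats::runif(n) < cfg$down_prob_t1, "down", "up"),
                 "flat")
  dir2 <- ifelse(de2,
                 ifelse(stats::runif(n) < cfg$down_prob_t2, "down", "up"),
                 "flat")
  lr <- log(cfg$de_fold_range)
  fold1 <- ifelse(de1, exp(stats::runif(n, lr[1], lr[2])), 1)
  fold2 <- ifelse(de2, exp(stats::runif(n, lr[1], lr[2])), 1)

  mult <- matrix(1, nrow = n, ncol = 3L,
                 dimnames = list(ids, stages))
  step1 <- ifelse(dir1 == "up", fold1, ifelse(dir1 == "down", 1 / fold1, 1))
  step2 <- ifelse(dir2 == "up", fold2, ifelse(dir2 == "down", 1 / fold2, 1))
  mult[, 2L] <- step1
  mult[, 3L] <- step1 * step2

  rel <- base / sum(base)
  mu <- matrix(0, nrow = n, ncol = length(design$samples),
               dimnames = list(ids, design$samples))
  for (s in design$samples) {
    st <- design$stage_of[[s]]
    mu[, s] <- rel * mult[, st] * cfg$lib_size_mean * sf[[s]]
  }
  counts <- matrix(
    stats::rnbinom(length(mu), mu = as.vector(mu), size = 1 / cfg$nb_dispersion),
    nrow = n, dimnames = dimnames(mu)
  )
  if (cfg$frac_zero > 0) {
    nz <- round(cfg$frac_zero * length(counts))
    if (nz > 0) counts[sample.int(length(counts), nz)] <- 0L
  }
  truth <- data.frame(
    feature_id = ids,
    de_t1 = de1, de_t2 = de2,
    dir_t1 = dir1, dir_t2 = dir2,
    fold_t1 = fold1, fold_t2 = fold2,
    archetype = archetype_label(dir1, dir2),
    base_mean = rel * cfg$lib_size_mean,
    # expected stage means on the rpmqn scale (per-million), pre-noise
    mean_rpmqn_s1 = rel * 1e6 * mult[, 1L],
    mean_rpmqn_s2 = rel * 1e6 * mult[, 2L],
    mean_rpmqn_s3 = rel * 1e6 * mult[, 3L],
    stringsAsFactors = FALSE
  )
  list(
    counts = count_matrix(counts, design),
    truth = list(features = truth,
                 de_t1 = ids[de1], de_t2 = ids[de2])
  )
}

#' Simulate a GO annotation with planted enrichments
#'
#' Terms `GO:SIM0001..` are assigned to features independently at per-term
#' base rates; for each planted `(archetype, term, factor)` entry the
#' assignment rate within that archetype's features is base rate x factor
#' (capped at 1).
#'
#' @param truth the `truth` component of [simulate_counts()].
#' @param cfg the same [sim_config()].
#' @return named list: feature ID -> character vector of GO terms (features
#'   with no terms absent).
#' @export
simulate_go_annotation <- function(truth, cfg) {
  set.seed(cfg$seed + 104729L)  # fixed offset: independent sub-stream
  feats <- truth$features
  n <- nrow(feats)
  terms <- sprintf("GO:SIM%04d", seq_len(cfg$n_go_terms))
  rates <- stats::runif(cfg$n_go_terms, cfg$go_base_rate_range[1],
                        cfg$go_base_rate_range[2])
  names(rates) <- terms
  planted_terms <- vapply(cfg$planted_enriched, `[[`, "", "term")
  extra <- setdiff(planted_terms, terms)
  if (length(extra)) {
    rates[extra] <- mean(cfg$go_base_rate_range)
    terms <- c(terms, extra)
  }
  assign <- matrix(FALSE, nrow = n, ncol = length(terms),
                   dimnames = list(feats$feature_id, terms))
  for (j in seq_along(terms)) {
    p <- rep(rates[[terms[j]]], n)
    for (pe in cfg$planted_enriched) {
      if (pe$term == terms[j]) {
        hit <- feats$archetype == pe$archetype
        p[hit] <- pmin(1, p[hit] * pe$factor)
      }
    }
    assign[, j] <- stats::runif(n) < p
  }
  out <- apply(assign, 1L, function(row) terms[row], simplify = FALSE)
  out[lengths(out) > 0L]
}

#' Simulate small-RNA libraries with planted length peaks and miRNAs
#'
#' Draws `srna_n_distinct` distinct random sequences with lengths sampled
#' from `srna_len_weights` (24-nt siRNA peak, 21-nt miRNA peak by default),
#' gives each a log-normal baseline abundance, plants a monotone stage trend
#' on a fraction of sequences, and samples per-library NB counts. The first
#' `n_planted_mirnas` sequences are copied verbatim into the mature-miRNA
#' reference (plus decoy references absent from the libraries).
#'
#' @param cfg a [sim_config()].
#' @return list with `reads` (named list: sample -> character vector of read
#'   sequences, expanded to multiplicity), `libraries` (named list of
#'   [collapse_reads()] results), `mature` (named character vector, the
#'   mature-miRNA reference), and `truth` (list: `planted_mirna_seqs`,
#'   `trend` data.frame with per-sequence trend direction).
#' @export
simulate_srna_libraries <- function(cfg) {
  set.seed(cfg$seed + 224737L)
  design <- cfg$design
  w <- cfg$srna_len_weights
  lens <- as.integer(names(w))
  n <- cfg$srna_n_distinct

  draw_seq <- function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }
  seq_lens <- sample(lens, n, replace = TRUE, prob = w / sum(w))
  seqs <- vapply(seq_lens, draw_seq, "")
  while (anyDuplicated(seqs)) {
    dup <- which(duplicated(seqs))
    seqs[dup] <- vapply(seq_lens[dup], draw_seq, "")
  }

  base <- stats::rlnorm(n, meanlog = log(20), sdlog = 1)
  trend <- sample(c("flat", "up", "down"), n, replace = TRUE,
                  prob = c(1 - cfg$frac_srna_trend,
                           cfg$frac_srna_trend / 2, cfg$frac_srna_trend / 2))
  lr <- log(cfg$de_fold_range)
  tf <- exp(stats::runif(n, lr[1], lr[2]))
  stages <- design$stage_order
  mult <- matrix(1, nrow = n, ncol = length(stages),
                 dimnames = list(NULL, stages))
  # monotone trends across the 3 stages give clean +/- stage-mean slopes
  mult[trend == "up", ] <- cbind(1, sqrt(tf[trend == "up"]), tf[trend == "up"])
  mult[trend == "down", ] <- cbind(1, 1 / sqrt(tf[trend == "down"]),
                                   1 / tf[trend == "down"])
  sf <- stats::rlnorm(length(design$samples), 0, 0.1)
  names(sf) <- design$samples

  reads <- list()
  libs <- list()
  for (s in design$samples) {
    st <- design$stage_of[[s]]
    mu <- base * mult[, st] * sf[[s]]
    counts <- stats::rnbinom(n, mu = mu, size = 1 / cfg$nb_dispersion)
    reads[[s]] <- rep(seqs, counts)
    libs[[s]] <- collapse_reads(reads[[s]])
  }

  n_mir <- min(cfg$n_planted_mirnas, n)
  mir_idx <- seq_len(n_mir)
  mature <- seqs[mir_idx]
  names(mature) <- sprintf("sim-miR%03d", mir_idx)
  n_decoy <- max(3L, round(n_mir / 2))
  decoys <- vapply(rep(21L, n_decoy), draw_seq, "")
  decoys <- decoys[!decoys %in% seqs]
  if (length(decoys)) {
    names(decoys) <- sprintf("sim-decoy%03d", seq_along(decoys))
    mature <- c(mature, decoys)
  }
  list(
    reads = reads,
    libraries = libs,
    mature = mature,
    truth = list(
      planted_mirna_seqs = seqs[mir_idx],
      trend = data.frame(srna_seq = seqs, trend = trend, fold = tf,
                         stringsAsFactors = FALSE)
    )
  )
}

#' Simulate candidate sRNA/target pairs with planted anticorrelation
#'
#' A fraction `frac_anticorrelated_pairs` of the pairs links an sRNA and a
#' transcript whose stage-mean profiles have Pearson r <= -0.95 (drawn from
#' the opposite-trend features planted by the generators); the remaining
#' pairs link randomly chosen features. Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param srna_expr [expression_matrix()] over distinct sRNAs.
#' @param tx_expr [expression_matrix()] over transcripts.
#' @return list with `pairs` (data.frame `srna_seq`, `transcript_id`) and
#'   `truth` (logical vector `planted` aligned with pairs).
#' @export
simulate_target_pairs <- function(cfg, srna_expr, tx_expr) {
  if (!identical(srna_expr$design$stage_order,
                 tx_expr$design$stage_order)) {
    stop("sRNA and transcript designs must share stage labels")
  }
  set.seed(cfg$seed + 350377L)
  sp <- stage_mean_profiles(srna_expr)
  tp <- stage_mean_profiles(tx_expr)
  n_s <- nrow(sp); n_t <- nrow(tp)
  if (cfg$n_target_pairs > n_s * n_t) {
    stop("n_target_pairs exceeds available pairs")
  }
  n_anti <- round(cfg$frac_anticorrelated_pairs * cfg$n_target_pairs)
  pairs_s <- character(0); pairs_t <- character(0)
  planted <- logical(0)
  if (n_anti > 0) {
    found <- 0L
    attempts <- 0L
    max_attempts <- 2000L * n_anti
    while (found < n_anti) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("could not find enough anticorrelated pairs; ",
             "increase frac_srna_trend or frac_de fractions")
      }
      i <- sample.int(n_s, 1L); j <- sample.int(n_t, 1L)
      x <- sp[i, ]; y <- tp[j, ]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      if (stats::cor(x, y) <= -0.95) {
        pairs_s <- c(pairs_s, rownames(sp)[i])
        pairs_t <- c(pairs_t, rownames(tp)[j])
        planted <- c(planted, TRUE)
        found <- found + 1L
      }
    }
  }
  n_rand <- cfg$n_target_pairs - n_anti
  if (n_rand > 0) {
    pairs_s <- c(pairs_s, rownames(sp)[sample.int(n_s, n_rand, replace = TRUE)])
    pairs_t <- c(pairs_t, rownames(tp)[sample.int(n_t, n_rand, replace = TRUE)])
    planted <- c(planted, rep(FALSE, n_rand))
  }
  list(
    pairs = data.frame(srna_seq = pairs_s, transcript_id = pairs_t,
                       stringsAsFactors = FALSE),
    truth = list(planted = planted)
  )
}
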