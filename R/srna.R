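#' Collapse small-RNA reads to distinct sequences
#'
#' Identical reads are collapsed to one distinct sequence with its read
#' multiplicity as count. Reads of length at most `retain_gt_len` are
#' dropped first (the published rule: reads strictly longer than 15 nt are
#' retained). Total count over distinct sequences equals the number of
#' retained reads, and collapsing an already collapsed library is the
#' identity.
#'
#' @param reads character vector of read sequences (A/C/G/T/N, uppercase;
#'   RNA input should pass through [read_sequences()] first).
#' @param retain_gt_len retain reads with length strictly greater than this
#'   (default 15).
#' @return object of class `srna_library`: list with `counts` (named integer
#'   vector, distinct sequence -> read count, sorted by sequence) and
#'   `total`.
#' @export
collapse_reads <- function(reads, retain_gt_len = 15L) {
  if (length(reads) && any(grepl("[^ACGTN]", reads))) {
    stop("invalid sequence characters in reads")
  }
  reads <- reads[nchar(reads) > retain_gt_len]
  counts <- table(reads)
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(counts = counts, total = sum(counts)),
            class = "srna_library")
}

#' @export
print.srna_library <- function(x, ...) {
  cat("srna_library:", length(x$counts), "distinct sequences,",
      x$total, "reads\n")
  invisible(x)
}

#' Length profile of a small-RNA library
#'
#' Read counts (or distinct-sequence counts) per sequence length within a
#' window; the canonical windows are the full retained range and the 18-28
#' nt analysis window where 24-nt siRNAs and 21-nt miRNAs peak.
#'
#' @param lib an `srna_library` from [collapse_reads()].
#' @param min_len,max_len inclusive length window.
#' @param distinct count distinct sequences instead of reads (default FALSE).
#' @return named integer vector: length -> count (lengths with no sequences
#'   omitted).
#' @export
length_profile <- function(lib, min_len = 18L, max_len = 28L,
                           distinct = FALSE) {
  if (min_len > max_len) stop("min_len must be <= max_len")
  len <- nchar(names(lib$counts))
  keep <- len >= min_len & len <= max_len
  if (!any(keep)) return(stats::setNames(integer(0), character(0)))
  val <- if (distinct) rep(1L, sum(keep)) else lib$counts[keep]
  tab <- tapply(val, len[keep], sum)
  stats::setNames(as.integer(tab), names(tab))
}

#' Build a count matrix over distinct sRNA sequences
#'
#' Rows are the union of distinct sequences within the length window across
#' all libraries (one library per design sample); a sequence absent from a
#' library gets count 0. The result feeds [normalize_rpmqn()] and
#' [call_de()] unchanged.
#'
#' @param libs named list of `srna_library`, names matching design samples.
#' @param design an [experiment_design()].
#' @param min_len,max_len inclusive length window (defaults 18-28).
#' @return a [count_matrix()] with sequences as feature IDs.
#' @export
build_srna_count_matrix <- function(libs, design, min_len = 18L,
                                    max_len = 28L) {
  missing <- setdiff(design$samples, names(libs))
  if (length(missing)) {
    stop("library missing for sample: ", paste(missing, collapse = ", "))
  }
  seqs <- sort(unique(unlist(lapply(libs[design$samples], function(l) {
    s <- names(l$counts)
    s[nchar(s) >= min_len & nchar(s) <= max_len]
  }), use.names = FALSE)))
  if (!length(seqs)) {
    warning("length window excludes every sequence")
    m <- matrix(0, nrow = 0L, ncol = length(design$samples),
                dimnames = list(character(0), design$samples))
    return(count_matrix(m, design))
  }
  m <- vapply(design$samples, function(s) {
    v <- libs[[s]]$counts[seqs]
    v[is.na(v)] <- 0L
    as.numeric(v)
  }, numeric(length(seqs)))
  if (length(seqs) == 1L) m <- matrix(m, nrow = 1L)
  dimnames(m) <- list(seqs, design$samples)
  count_matrix(m, design)
}

#' Match distinct sRNAs to mature miRNAs without mismatches
#'
#' An sRNA is annotated as a known miRNA iff it is an exact, gap-free,
#' forward-orientation substring of a mature miRNA reference sequence
#' (equivalent to zero-mismatch ungapped read-to-reference alignment). All
#' matching reference IDs are reported.
#'
#' @param lib an `srna_library`.
#' @param mature named character vector of mature miRNA sequences (DNA
#'   alphabet; use [read_sequences()], which maps U to T).
#' @return named list: sRNA sequence -> character vector of matching miRNA
#'   IDs; unmatched sRNAs are absent.
#' @export
match_mature_mirna <- function(lib, mature) {
  srnas <- names(lib$counts)
  if (!length(srnas) || !length(mature)) {
    return(stats::setNames(list(), character(0)))
  }
  hits <- lapply(srnas, function(s) {
    names(mature)[grepl(s, mature, fixed = TRUE)]
  })
  names(hits) <- srnas
  hits[lengths(hits) > 0L]
}

# per-feature stage means of an expression matrix, features x stages
stage_mean_profiles <- function(expr, features = rownames(expr$values)) {
  design <- expr$design
  out <- vapply(design$stage_order, function(st) {
    rowMeans(expr$values[features, stage_samples(design, st), drop = FALSE])
  }, numeric(length(features)))
  if (length(features) == 1L) out <- matrix(out, nrow = 1L)
  dimnames(out) <- list(features, design$stage_order)
  out
}

#' Filter putative sRNA/target pairs by expression anticorrelation
#'
#' A regulating sRNA should suppress its target, so candidate pairs (from an
#' external target predictor) are retained only when sRNA and transcript
#' expression are strongly negatively correlated. Because sRNA and mRNA
#' libraries come from different isolation procedures, replicates cannot be
#' paired; the Pearson correlation is computed over the per-stage means
#' (3 points in the canonical design). A pair is retained iff
#' `stage_corr <= cfg$target_corr_max`; a zero-variance profile on either
#' side leaves the correlation undefined and the pair not retained
#' (flagged NA).
#'
#' @param pairs data.frame with columns `srna_seq`, `transcript_id`.
#' @param srna_expr [expression_matrix()] over distinct sRNA sequences.
#' @param tx_expr [expression_matrix()] over transcripts, same stage labels.
#' @param cfg a [pipeline_config()].
#' @param srna_de,tx_de character vectors of DE feature IDs used to annotate
#'   the pairs (optional).
#' @return data.frame: `srna_seq`, `transcript_id`, `stage_corr`, `srna_de`,
#'   `target_de`, `retained`.
#' @export
target_anticorrelation_filter <- function(pairs, srna_expr, tx_expr,
                                          cfg = pipeline_config(),
                                          srna_de = character(0),
                                          tx_de = character(0)) {
  if (!identical(srna_expr$design$stage_order, tx_expr$design$stage_order)) {
    stop("sRNA and transcript designs must share stage labels")
  }
  bad <- setdiff(pairs$srna_seq, rownames(srna_expr$values))
  if (length(bad)) stop("pair references unknown sRNA: ", bad[[1]])
  bad <- setdiff(pairs$transcript_id, rownames(tx_expr$values))
  if (length(bad)) stop("pair references unknown transcript: ", bad[[1]])
  sp <- stage_mean_profiles(srna_expr, unique(pairs$srna_seq))
  tp <- stage_mean_profiles(tx_expr, unique(pairs$transcript_id))
  corr <- vapply(seq_len(nrow(pairs)), function(i) {
    x <- sp[pairs$srna_seq[[i]], ]
    y <- tp[pairs$transcript_id[[i]], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, 0)
  data.frame(
    srna_seq = pairs$srna_seq,
    transcript_id = pairs$transcript_id,
    stage_corr = corr,
    srna_de = pairs$srna_seq %in% srna_de,
    target_de = pairs$transcript_id %in% tx_de,
    retained = !is.na(corr) & corr <= cfg$target_corr_max,
    stringsAsFactors = FALSE
  )
}
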