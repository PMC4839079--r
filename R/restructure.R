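#' Best cDNA hit per contig
#'
#' De novo assemblies of short reads fragment transcripts into multiple
#' contigs. Contigs are mapped to a reference cDNA set; per contig the best
#' surviving hit selects the cDNA its transcript unit will be named after.
#' Hits with e-value above `max_evalue` are dropped; among the rest the best
#' hit is chosen by highest bitscore, then lowest e-value, then
#' lexicographically smallest cDNA ID (a deterministic tie-break the
#' published pipeline leaves unstated).
#'
#' @param hits data.frame from [read_hits_table()].
#' @param max_evalue e-value cutoff (default 1e-10).
#' @return named character vector: contig ID -> cDNA ID. Contigs with no
#'   surviving hit are absent.
#' @export
assign_best_hit <- function(hits, max_evalue = 1e-10) {
  if (max_evalue <= 0) stop("max_evalue must be > 0")
  if (!nrow(hits)) return(stats::setNames(character(0), character(0)))
  keep <- hits$evalue <= max_evalue
  hits <- hits[keep, , drop = FALSE]
  if (!nrow(hits)) return(stats::setNames(character(0), character(0)))
  o <- order(hits$contig_id, -hits$bitscore, hits$evalue, hits$cdna_id,
             method = "radix")
  hits <- hits[o, , drop = FALSE]
  best <- hits[!duplicated(hits$contig_id), , drop = FALSE]
  stats::setNames(best$cdna_id, best$contig_id)
}

#' Cluster contigs into transcript units
#'
#' All contigs assigned to the same cDNA collapse to a single transcript
#' identifier (`source = "known-cDNA"`); each unassigned contig becomes its
#' own novel transcript (`source = "novel"`, ID `novel_<contig>`). The
#' clusters partition the contig universe.
#'
#' @param assignment named vector from [assign_best_hit()].
#' @param all_contigs character vector of every contig ID.
#' @return data.frame with columns `transcript_id`, `contig_id`, `source`,
#'   `cdna_id` (NA for novel transcripts); one row per contig.
#' @export
build_transcripts <- function(assignment, all_contigs) {
  if (anyDuplicated(all_contigs)) {
    stop("duplicate contig ID: ", all_contigs[duplicated(all_contigs)][1])
  }
  unknown <- setdiff(names(assignment), all_contigs)
  if (length(unknown)) {
    stop("assignment references unknown contigs: ",
         paste(unknown, collapse = ", "))
  }
  assigned <- all_contigs %in% names(assignment)
  cdna <- ifelse(assigned, unname(assignment[all_contigs]), NA_character_)
  data.frame(
    transcript_id = ifelse(assigned, paste0("tx_", cdna),
                           paste0("novel_", all_contigs)),
    contig_id = all_contigs,
    source = ifelse(assigned, "known-cDNA", "novel"),
    cdna_id = cdna,
    stringsAsFactors = FALSE
  )
}

#' Aggregate contig counts to transcript counts
#'
#' Transcript expression is estimated by counting all reads mapping to any
#' member contig of the transcript cluster: per sample, the transcript count
#' is the sum of its member contig counts, so per-library totals are
#' conserved.
#'
#' @param contig_counts a [count_matrix()] over contigs.
#' @param clusters data.frame from [build_transcripts()].
#' @return a [count_matrix()] over transcript IDs.
#' @export
aggregate_counts <- function(contig_counts, clusters) {
  missing <- setdiff(clusters$contig_id, rownames(contig_counts$values))
  if (length(missing)) {
    stop("cluster member missing from count matrix: ", missing[[1]])
  }
  m <- contig_counts$values[clusters$contig_id, , drop = FALSE]
  agg <- rowsum(m, group = clusters$transcript_id, reorder = FALSE)
  count_matrix(agg, contig_counts$design)
}

#' Merge GO terms of member contigs
#'
#' Annotation obtained on fragmented contigs is carried to the transcript
#' level as the deduplicated union over member contigs. Transcripts with no
#' annotated member are absent from the result.
#'
#' @param clusters data.frame from [build_transcripts()].
#' @param contig_go named list: contig ID -> character vector of GO terms.
#' @return named list: transcript ID -> sorted character vector of terms.
#' @export
merge_go_terms <- function(clusters, contig_go) {
  annotated <- clusters[clusters$contig_id %in% names(contig_go), ,
                        drop = FALSE]
  if (!nrow(annotated)) return(stats::setNames(list(), character(0)))
  terms <- lapply(split(annotated$contig_id, annotated$transcript_id),
                  function(ids) sort(unique(unlist(contig_go[ids]))))
  terms[order(names(terms))]
}

#' Read a feature-to-GO-term annotation table
#'
#' Two-column TSV (feature ID, GO term), one term per row, with header.
#'
#' @param path input TSV.
#' @return named list: feature ID -> character vector of terms.
#' @export
read_go_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(tab) < 2L) stop("GO table needs feature and term columns")
  split(tab[[2L]], tab[[1L]])
}

#' Write a feature-to-GO-term annotation table
#' @param go named list: feature ID -> character vector of terms.
#' @param path output TSV.
#' @export
write_go_table <- function(go, path) {
  tab <- data.frame(
    feature_id = rep(names(go), lengths(go)),
    go_term = unlist(go, use.names = FALSE)
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
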