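#' Experiment design: samples, stages and stage transitions
#'
#' Describes a staged time-course with replicated samples. The canonical
#' design for microspore embryogenesis induction is three stages (S1:
#' untreated uninucleate microspores, S2: after cold-stress induction, S3:
#' first nuclear division), three biological replicates each, and the two
#' transitions T1 = S1 to S2 and T2 = S2 to S3.
#'
#' @param samples character vector of sample IDs, in column order.
#' @param stage_of named character vector mapping sample ID to stage label.
#' @param stage_order character vector of stage labels in temporal order.
#' @param transitions named list of length-2 character vectors
#'   (from-stage, to-stage); defaults to consecutive stage pairs named
#'   T1, T2, ...
#' @return An object of class `experiment_design`.
#' @examples
#' default_design()
#' @export
experiment_design <- function(samples, stage_of, stage_order,
                              transitions = NULL) {
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample IDs in design")
  if (is.null(names(stage_of))) stop("stage_of must be named by sample ID")
  missing <- setdiff(samples, names(stage_of))
  if (length(missing)) {
    stop("samples without a stage: ", paste(missing, collapse = ", "))
  }
  stage_of <- stage_of[samples]
  bad <- setdiff(unique(stage_of), stage_order)
  if (length(bad)) {
    stop("stages not in stage_order: ", paste(bad, collapse = ", "))
  }
  if (is.null(transitions)) {
    transitions <- lapply(seq_len(max(length(stage_order) - 1L, 0L)),
                          function(i) c(stage_order[i], stage_order[i + 1L]))
    if (length(transitions)) {
      names(transitions) <- paste0("T", seq_along(transitions))
    }
  }
  for (tr in transitions) {
    if (length(tr) != 2L || !all(tr %in% stage_order)) {
      stop("transition stages must be a pair of stages in stage_order")
    }
  }
  structure(
    list(samples = samples, stage_of = stage_of,
         stage_order = stage_order, transitions = transitions),
    class = "experiment_design"
  )
}

#' @describeIn experiment_design The 3-stage, 3-replicate default design
#'   (samples S1a..S3c).
#' @export
default_design <- function() {
  stages <- c("S1", "S2", "S3")
  samples <- as.vector(t(outer(stages, c("a", "b", "c"), paste0)))
  experiment_design(
    samples = samples,
    stage_of = stats::setNames(rep(stages, each = 3L), samples),
    stage_order = stages
  )
}

#' Samples belonging to one stage
#' @param design an `experiment_design`.
#' @param stage a stage label.
#' @return character vector of sample IDs.
#' @export
stage_samples <- function(design, stage) {
  design$samples[design$stage_of[design$samples] == stage]
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("experiment_design:", length(x$samples), "samples,",
      length(x$stage_order), "stages (",
      paste(x$stage_order, collapse = " -> "), ")\n")
  invisible(x)
}

#' Read a sample-to-stage design table
#'
#' Sidecar TSV with columns `sample_id` and `stage`; samples are kept in file
#' order and transitions default to consecutive stage pairs.
#'
#' @param path path to a two-column TSV with header.
#' @return an `experiment_design`.
#' @export
read_design <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (!all(c("sample_id", "stage") %in% names(tab))) {
    stop("design file must have columns sample_id, stage: ", path)
  }
  experiment_design(
    samples = tab$sample_id,
    stage_of = stats::setNames(tab$stage, tab$sample_id),
    stage_order = unique(tab$stage)
  )
}

#' Write a design table
#' @param design an `experiment_design`.
#' @param path output TSV path.
#' @export
write_design <- function(design, path) {
  utils::write.table(
    data.frame(sample_id = design$samples,
               stage = unname(design$stage_of[design$samples])),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

# internal: require >= 2 replicates per stage for variance-based operations
check_replicated <- function(design) {
  n <- table(design$stage_of)
  short <- names(n)[n < 2L]
  if (length(short)) {
    stop("stages with fewer than 2 replicates: ",
         paste(short, collapse = ", "))
  }
  invisible(TRUE)
}
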