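#' Count and expression matrix containers
#'
#' `count_matrix` holds non-negative integer read counts, features x samples,
#' together with the experiment design; `expression_matrix` holds the
#' rpmqn-normalized real-valued counterpart. Columns are always in design
#' sample order.
#'
#' @param values numeric matrix with rownames (feature IDs) and colnames
#'   (sample IDs).
#' @param design an [experiment_design()].
#' @return a `count_matrix` / `expression_matrix`.
#' @export
count_matrix <- function(values, design) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) && nrow(values) > 0L) {
    stop("count matrix needs feature rownames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate feature IDs")
  missing <- setdiff(design$samples, colnames(values))
  if (length(missing)) {
    stop("design samples missing from matrix: ",
         paste(missing, collapse = ", "))
  }
  values <- values[, design$samples, drop = FALSE]
  if (any(values < 0)) stop("negative counts")
  if (any(values != round(values))) stop("non-integer counts")
  storage.mode(values) <- "double"   # avoids integer overflow on aggregation
  structure(list(values = values, design = design), class = "count_matrix")
}

#' @rdname count_matrix
#' @export
expression_matrix <- function(values, design) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("expression matrix needs feature rownames")
  if (anyDuplicated(rownames(values))) stop("duplicate feature IDs")
  values <- values[, design$samples, drop = FALSE]
  if (any(values < 0)) stop("negative expression values")
  structure(list(values = values, design = design),
            class = "expression_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$values), "features x",
      ncol(x$values), "samples\n")
  invisible(x)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix (rpmqn):", nrow(x$values), "features x",
      ncol(x$values), "samples\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read a feature-by-sample count table
#'
#' TSV with a header row of sample IDs and feature IDs in the first column.
#' Columns are reordered to match the design; malformed cells (non-integer,
#' negative) and duplicate feature IDs are errors, never silently coerced.
#'
#' @param path path to the TSV.
#' @param design an [experiment_design()]; every design sample must be
#'   present as a column.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path, design) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "#", quote = "")
  if (ncol(tab) < 2L) stop("count table needs a feature column and samples")
  ids <- tab[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate feature ID: ", dup[[1]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(as.numeric(vals))
  bad <- is.na(num) | num < 0 | num != floor(num)
  if (any(bad)) {
    idx <- which(bad)[1L]
    r <- (idx - 1L) %% nrow(vals) + 1L
    s <- (idx - 1L) %/% nrow(vals) + 1L
    stop(sprintf("malformed count '%s' at feature %s, sample %s in %s",
                 vals[r, s], ids[r], colnames(vals)[s], path))
  }
  m <- matrix(num, nrow = nrow(vals),
              dimnames = list(ids, colnames(vals)))
  count_matrix(m, design)
}

#' Write a count or expression matrix as TSV
#' @param x a `count_matrix` or `expression_matrix`.
#' @param path output path.
#' @export
write_matrix <- function(x, path) {
  tab <- data.frame(feature_id = rownames(x$values), x$values,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sequences from FASTA or FASTQ
#'
#' Format is auto-detected from the first non-empty line (`>` FASTA, `@`
#' FASTQ). Sequences are uppercased and RNA `U` is mapped to `T`; record IDs
#' are taken up to the first whitespace. FASTQ qualities are discarded.
#' Multi-line FASTA sequences are supported; mixing formats is an error.
#'
#' @param path input path.
#' @return named character vector of sequences (names are record IDs); an
#'   empty file yields an empty vector.
#' @export
read_sequences <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(stats::setNames(character(0), character(0)))
  first <- substr(lines[[1]], 1L, 1L)
  if (first == ">") {
    hdr <- grepl("^>", lines)
    if (any(grepl("^@", lines[!hdr]))) {
      # sequence lines never start with '@' in valid FASTA over ACGTUN
      stop("mixed FASTA/FASTQ records in ", path)
    }
    ids <- sub("^>\\s*", "", lines[hdr])
    ids <- sub("\\s.*$", "", ids)
    grp <- cumsum(hdr)
    if (any(grp[!hdr] == 0L)) stop("sequence before first FASTA header")
    seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0, "", collapse = "")
    out <- character(sum(hdr))
    names(out) <- ids
    out[as.integer(names(seqs))] <- seqs
  } else if (first == "@") {
    if (length(lines) %% 4L != 0L) {
      stop("FASTQ record count not a multiple of 4 in ", path)
    }
    ids <- lines[seq(1L, length(lines), by = 4L)]
    plus <- lines[seq(3L, length(lines), by = 4L)]
    if (!all(grepl("^@", ids)) || !all(grepl("^\\+", plus))) {
      stop("invalid FASTQ record structure in ", path)
    }
    out <- lines[seq(2L, length(lines), by = 4L)]
    names(out) <- sub("\\s.*$", "", sub("^@", "", ids))
  } else {
    stop("cannot detect FASTA/FASTQ format in ", path)
  }
  out <- chartr("u", "t", out)
  out <- toupper(out)
  out <- chartr("U", "T", out)
  bad <- grepl("[^ACGTN]", out)
  if (any(bad)) {
    stop("invalid sequence characters in record ", names(out)[bad][1])
  }
  out
}

#' Write sequences as FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  invisible(path)
}

#' Write reads as FASTQ (constant quality, for simulated libraries)
#' @param seqs character vector of read sequences.
#' @param ids read IDs; defaults to read_1..n.
#' @param path output path.
#' @export
write_fastq <- function(seqs, path, ids = paste0("read_", seq_along(seqs))) {
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), "")
  writeLines(as.vector(rbind(paste0("@", ids), unname(seqs), "+", qual)), path)
  invisible(path)
}

#' Read a 12-column tabular alignment hits table
#'
#' The standard tabular alignment layout: query, subject, percent identity,
#' alignment length, mismatches, gap opens, qstart, qend, sstart, send,
#' e-value, bitscore. Rows are kept in file order.
#'
#' @param path input TSV (no header).
#' @return data.frame of hits with typed columns; empty file gives zero rows.
#' @export
read_hits_table <- function(path) {
  cols <- c("contig_id", "cdna_id", "percent_identity", "length",
            "mismatches", "gapopens", "qstart", "qend", "sstart", "send",
            "evalue", "bitscore")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  empty <- as.data.frame(stats::setNames(
    c(list(character(0), character(0)), rep(list(numeric(0)), 10L)), cols))
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf != 12L)) {
    stop(sprintf("expected 12 columns, got %d at line %d of %s",
                 nf[nf != 12L][1L], which(nf != 12L)[1L], path))
  }
  m <- do.call(rbind, fields)
  out <- data.frame(contig_id = m[, 1L], cdna_id = m[, 2L],
                    check.names = FALSE)
  for (j in 3:12) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) {
      stop(sprintf("non-numeric field in column %d at line %d of %s",
                   j, which(is.na(v))[1L], path))
    }
    out[[cols[j]]] <- v
  }
  out
}

#' Write a pipeline result to disk
#'
#' Matrices go to TSV via [write_matrix()]; data.frames (DE calls, enrichment
#' results, target pairs, length profiles) go to TSV with a `#`-prefixed
#' header comment naming the columns; lists go to JSON. Output is
#' byte-stable given identical inputs.
#'
#' @param results a pipeline product.
#' @param path output path.
#' @export
write_report <- function(results, path) {
  if (inherits(results, "count_matrix") ||
      inherits(results, "expression_matrix")) {
    return(write_matrix(results, path))
  }
  if (is.data.frame(results)) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(paste0("# columns: ", paste(names(results), collapse = ", ")),
               con)
    utils::write.table(results, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
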