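#' Pipeline configuration
#'
#' All scalar thresholds of the analysis in one place. Defaults follow the
#' published analysis: expressed means >= 1 rpmqn in all replicates of at
#' least one stage; differential expression requires >= 2 rpmqn in the higher
#' expressed stage, a two-fold change, a replicate standard deviation of at
#' most 25 % of the stage mean, and a Benjamini-Hochberg FDR of 5 % on
#' Student's t-test p-values. GO enrichment uses a bootstrap with one million
#' runs, a minimum of 5 set members per term and FDR 5 %. sRNA reads longer
#' than 15 nt are retained; the count-matrix window is 18-28 nt; target pairs
#' are kept at a stage-mean Pearson correlation of at most -0.9.
#'
#' @param expressed_min_rpmqn minimum rpmqn in every replicate of a stage for
#'   a feature to count as expressed there (default 1).
#' @param de_min_rpmqn minimum mean rpmqn in the higher expressed stage
#'   (default 2; the methods wording "1 rpmqn" is available by overriding).
#' @param de_min_fold minimum fold change, higher/lower stage mean (default 2).
#' @param de_max_cv maximum replicate coefficient of variation (sd/mean) in
#'   both stages (default 0.25).
#' @param de_fdr_alpha FDR level for the t-test (default 0.05).
#' @param kmeans_k number of expression-pattern clusters (default 12).
#' @param kmeans_restarts random restarts, best objective kept (default 20).
#' @param boot_runs bootstrap resamples for enrichment (default 1e6).
#' @param enrich_min_count minimum set members carrying a term (default 5).
#' @param enrich_fdr_alpha FDR level for enrichment (default 0.05).
#' @param srna_min_len,srna_max_len length window for the sRNA count matrix
#'   (defaults 18 and 28 nt).
#' @param srna_retain_gt_len collapse keeps reads strictly longer than this
#'   (default 15 nt).
#' @param target_corr_max maximum stage-mean Pearson correlation for a
#'   retained sRNA/target pair (default -0.9; must lie in [-1, 0)).
#' @param rng_seed integer seed used by seeded operations (default 1).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(expressed_min_rpmqn = 1,
                            de_min_rpmqn = 2,
                            de_min_fold = 2,
                            de_max_cv = 0.25,
                            de_fdr_alpha = 0.05,
                            kmeans_k = 12L,
                            kmeans_restarts = 20L,
                            boot_runs = 1e6,
                            enrich_min_count = 5L,
                            enrich_fdr_alpha = 0.05,
                            srna_min_len = 18L,
                            srna_max_len = 28L,
                            srna_retain_gt_len = 15L,
                            target_corr_max = -0.9,
                            rng_seed = 1L) {
  cfg <- list(
    expressed_min_rpmqn = as.numeric(expressed_min_rpmqn),
    de_min_rpmqn = as.numeric(de_min_rpmqn),
    de_min_fold = as.numeric(de_min_fold),
    de_max_cv = as.numeric(de_max_cv),
    de_fdr_alpha = as.numeric(de_fdr_alpha),
    kmeans_k = as.integer(kmeans_k),
    kmeans_restarts = as.integer(kmeans_restarts),
    boot_runs = as.numeric(boot_runs),
    enrich_min_count = as.integer(enrich_min_count),
    enrich_fdr_alpha = as.numeric(enrich_fdr_alpha),
    srna_min_len = as.integer(srna_min_len),
    srna_max_len = as.integer(srna_max_len),
    srna_retain_gt_len = as.integer(srna_retain_gt_len),
    target_corr_max = as.numeric(target_corr_max),
    rng_seed = as.integer(rng_seed)
  )
  pos <- c("expressed_min_rpmqn", "de_min_rpmqn", "de_min_fold", "de_max_cv",
           "de_fdr_alpha", "kmeans_k", "kmeans_restarts", "enrich_min_count",
           "enrich_fdr_alpha")
  for (f in pos) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0) stop(f, " must be > 0")
  }
  if (cfg$boot_runs < 1) stop("boot_runs must be >= 1")
  if (cfg$target_corr_max < -1 || cfg$target_corr_max >= 0) {
    stop("target_corr_max must lie in [-1, 0)")
  }
  if (cfg$srna_min_len > cfg$srna_max_len) {
    stop("srna_min_len must be <= srna_max_len")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration file
#'
#' Flat `key: value` text (YAML-style scalars only). Every key must be a
#' [pipeline_config()] field; unknown keys raise an error so typos cannot
#' silently fall back to defaults. Blank lines and `#` comments are ignored.
#'
#' @param path path to the config file.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(pipeline_config())
  parts <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.+)$", lines))
  bad <- lines[vapply(parts, length, 1L) != 3L]
  if (length(bad)) stop("malformed config line: ", bad[[1]])
  keys <- vapply(parts, `[[`, "", 2L)
  vals <- vapply(parts, `[[`, "", 3L)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(keys, known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(keys)) stop("duplicate config keys")
  num <- suppressWarnings(as.numeric(vals))
  if (anyNA(num)) stop("non-numeric config value for: ", keys[is.na(num)][1])
  do.call(pipeline_config, as.list(stats::setNames(num, keys)))
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (k in names(x)) cat(sprintf("  %s: %s\n", k, format(x[[k]])))
  invisible(x)
}
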