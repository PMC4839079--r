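test_that("count simulation is deterministic and honors null configs", {
  cfg <- sim_config(n_features = 200, seed = 33)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts$values, b$counts$values)
  expect_identical(a$truth$features, b$truth$features)

  null_cfg <- sim_config(n_features = 200, frac_de_t1 = 0, frac_de_t2 = 0,
                         seed = 34)
  null_sim <- simulate_counts(null_cfg)
  expect_true(all(null_sim$truth$features$fold_t1 == 1))
  expect_true(all(null_sim$truth$features$fold_t2 == 1))
  expect_true(all(null_sim$truth$features$archetype == "flat_flat"))
})

test_that("planted fold changes are realized within 25 %", {
  ok <- 0L; tested <- 0L
  for (s in 1:5) {
    cfg <- sim_config(n_features = 500, frac_zero = 0, seed = 400 + s)
    sim <- simulate_counts(cfg)
    tr <- sim$truth$features
    design <- sim$counts$design
    m <- sim$counts$values
    s2 <- rowMeans(m[, stage_samples(design, "S2"), drop = FALSE])
    s3 <- rowMeans(m[, stage_samples(design, "S3"), drop = FALSE])
    sel <- tr$de_t2 & !tr$de_t1 & pmin(s2, s3) >= 10
    emp_fold <- ifelse(tr$dir_t2 == "up", s3 / s2, s2 / s3)[sel]
    rel_err <- abs(emp_fold - tr$fold_t2[sel]) / tr$fold_t2[sel]
    ok <- ok + sum(rel_err <= 0.25)
    tested <- tested + sum(sel)
  }
  expect_gt(tested, 100L)
  expect_gte(ok / tested, 0.95)
})

test_that("GO assignment at factor 1 stays within 3 binomial SDs of base", {
  scfg <- sim_config(n_features = 2000, seed = 55,
                     go_base_rate_range = c(0.03, 0.03),
                     planted_enriched = list(list(archetype = "flat_up",
                                                  term = "GO:SIM0001",
                                                  factor = 1)))
  sim <- simulate_counts(scfg)
  go <- simulate_go_annotation(sim$truth, scfg)
  cluster <- sim$truth$features$feature_id[
    sim$truth$features$archetype == "flat_up"]
  n <- length(cluster)
  obs <- sum(vapply(cluster,
                    function(f) "GO:SIM0001" %in% go[[f]], TRUE))
  expect_lte(abs(obs - n * 0.03), 3 * sqrt(n * 0.03 * 0.97) + 1)
})

test_that("sRNA libraries: length mode, planted miRNAs, determinism", {
  cfg <- sim_config(srna_n_distinct = 800, seed = 66)
  sim <- simulate_srna_libraries(cfg)
  expect_identical(names(sim$libraries), cfg$design$samples)

  # read-weighted length histogram peaks at 24 nt (the max-weight length)
  lib <- sim$libraries[[1]]
  prof <- length_profile(lib, 15, 28)
  expect_identical(names(prof)[which.max(prof)], "24")

  # distinct count bounded by configuration
  expect_lte(length(lib$counts), cfg$srna_n_distinct)

  # planted miRNAs are substrings (here: exact copies) of reference records
  expect_true(all(sim$truth$planted_mirna_seqs %in% sim$mature))
  hits <- match_mature_mirna(lib, sim$mature)
  present <- intersect(sim$truth$planted_mirna_seqs, names(lib$counts))
  expect_true(all(present %in% names(hits)))

  again <- simulate_srna_libraries(cfg)
  expect_identical(again$libraries[[3]]$counts, sim$libraries[[3]]$counts)
})

test_that("target pair generator plants r <= -0.95 pairs; null rate matches", {
  cfg <- sim_config(n_features = 600, srna_n_distinct = 600,
                    n_target_pairs = 100, seed = 77)
  tx <- normalize_rpmqn(simulate_counts(cfg)$counts)
  sr <- simulate_srna_libraries(cfg)
  srna <- normalize_rpmqn(build_srna_count_matrix(sr$libraries, cfg$design))
  tp <- simulate_target_pairs(cfg, srna, tx)
  expect_identical(nrow(tp$pairs), 100L)
  expect_identical(sum(tp$truth$planted), 30L)

  res <- target_anticorrelation_filter(tp$pairs, srna, tx,
                                       pipeline_config(target_corr_max = -0.95))
  expect_true(all(res$retained[tp$truth$planted]))

  tp2 <- simulate_target_pairs(cfg, srna, tx)
  expect_identical(tp2$pairs, tp$pairs)

  # all-random pairs retained at about the Monte-Carlo null rate of
  # r <= -0.9 among random 3-point stage profiles
  null_cfg <- sim_config(n_features = 600, srna_n_distinct = 600,
                         n_target_pairs = 400,
                         frac_anticorrelated_pairs = 0, seed = 78)
  tp0 <- simulate_target_pairs(null_cfg, srna, tx)
  res0 <- target_anticorrelation_filter(tp0$pairs, srna, tx,
                                        pipeline_config())
  # null-rate oracle: correlations of random profile pairs drawn the same way
  set.seed(979)
  i <- sample(nrow(srna$values), 4000, replace = TRUE)
  j <- sample(nrow(tx$values), 4000, replace = TRUE)
  sp <- andromics:::stage_mean_profiles(srna)
  tpm <- andromics:::stage_mean_profiles(tx)
  r_null <- vapply(1:4000, function(k) {
    x <- sp[i[k], ]; y <- tpm[j[k], ]
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)
  }, 0)
  p_null <- mean(r_null <= -0.9, na.rm = TRUE)
  se <- sqrt(p_null * (1 - p_null) / 400)
  expect_lte(mean(res0$retained), p_null + 3 * se + 0.005)
})

test_that("simulate errors on invalid stated worlds", {
  expect_error(sim_config(frac_zero = 1), "frac_zero")
  expect_error(sim_config(de_fold_range = c(0.5, 2)), "de_fold_range")
  expect_error(sim_config(srna_len_weights = c(`12` = 1)), "15")
  expect_error(sim_config(planted_enriched = list(list(archetype = "a",
                                                       term = "t",
                                                       factor = 0))),
               "factor")
  expect_error(
    simulate_target_pairs(sim_config(n_target_pairs = 1e9),
                          toy_expr(matrix(1:9 + 0, 1,
                                          dimnames = list("a", NULL))),
                          toy_expr(matrix(9:1 + 0, 1,
                                          dimnames = list("b", NULL)))),
    "exceeds")
})
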