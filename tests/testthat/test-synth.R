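test_that("default config mirrors the 21-sample study design", {
  cfg <- synth_config()
  b <- simulate_study(cfg)
  expect_identical(nrow(b$design), 21L)
  expect_identical(length(unique(b$design$site)), 7L)
  expect_identical(nrow(b$ground_truth$features), 43L)
  expect_identical(sort(unique(b$ground_truth$samples$chemogroup)),
                   paste0("CG", 1:5))
  expect_identical(ncol(b$sequences$cox1), 660L)
  expect_identical(ncol(b$sequences$rbcL), 890L)
  # injected exceptions present
  gt <- b$ground_truth$samples
  expect_identical(gt$chemogroup[gt$sample_id == "1B"], "CG2")
  expect_identical(gt$chemogroup[gt$sample_id == "6C"], "CG5")
  expect_identical(gt$phylogroup_cox1[gt$sample_id == "6A"], "B")
  expect_identical(gt$phylogroup_rbcL[gt$sample_id == "6A"], "A")
})

test_that("identical seed and config reproduce the bundle byte for byte", {
  cfg <- synth_config(seed = 99)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  b1 <- simulate_study(cfg, dir = d1)
  b2 <- simulate_study(cfg, dir = d2)
  expect_identical(b1$peaks, b2$peaks)
  expect_identical(b1$sequences, b2$sequences)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  b3 <- simulate_study(synth_config(seed = 100))
  expect_false(identical(b1$peaks$height, b3$peaks$height))
})

test_that("profile templates meet the similarity targets", {
  degenerate <- function(cfg, templates) {
    100 * (1 - bray_curtis(templates[1, ], templates[2, ]))
  }
  # disjoint support: between-group similarity 0
  cfg0 <- synth_config(shared_features = 0L, feature_pool_size = 40L)
  t0 <- simulate_profiles(cfg0)
  expect_equal(degenerate(cfg0, t0), 0)
  # identical templates: 100 (degenerate control, bypassing the check)
  t1 <- t0; t1[2, ] <- t1[1, ]
  expect_equal(degenerate(cfg0, t1), 100)

  for (seed in 1:25) {
    tm <- simulate_profiles(synth_config(seed = seed))
    between <- attr(tm, "realized_between")
    off <- between[upper.tri(between)]
    expect_lte(max(off), 40)
    expect_gte(attr(tm, "expected_within"), 70)
  }
})

test_that("infeasible template targets raise a config error", {
  cfg <- synth_config(shared_features = 30L, feature_pool_size = 43L)
  expect_error(simulate_profiles(cfg), "infeasible")
  cfg <- synth_config(noise_sigma = 1.5)
  expect_error(simulate_profiles(cfg), "noise")
})

test_that("replicate noise lands within-site similarity above target", {
  sims <- vapply(1:25, function(seed) {
    cfg <- synth_config(seed = seed)
    pk <- simulate_peak_tables(cfg, simulate_profiles(cfg))
    ft <- match_features(preprocess_peaks(pk))
    sim <- similarity_matrix(resemblance_matrix(ft))
    cg <- synth_chemogroup_of(cfg)
    within <- c()
    for (g in unique(cg)) {
      ids <- names(cg)[cg == g]
      sub <- sim[ids, ids]
      within <- c(within, sub[upper.tri(sub)])
    }
    min(within)
  }, numeric(1))
  expect_true(all(sims > 50))       # every pair stays in its chemogroup
  expect_gt(mean(sims), 70)         # and the bulk sits above the target
})

test_that("zero noise collapses replicates to identical profiles", {
  cfg <- synth_config(seed = 2, noise_sigma = 0, rt_jitter_sd = 0)
  pk <- simulate_peak_tables(cfg, simulate_profiles(cfg))
  ft <- match_features(preprocess_peaks(pk))
  sim <- similarity_matrix(resemblance_matrix(ft))
  cg <- synth_chemogroup_of(cfg)
  for (g in unique(cg)) {
    ids <- names(cg)[cg == g]
    expect_equal(unname(sim[ids[1], ids[-1]]),
                 rep(100, length(ids) - 1L), tolerance = 1e-9)
  }
})

test_that("sequence sets honor the configured divergence structure", {
  for (seed in 1:10) {
    cfg <- synth_config(seed = seed)
    for (m in c("cox1", "rbcL")) {
      aln <- simulate_sequences(cfg, m)
      pd <- as.matrix(p_distance_matrix(aln))
      pg <- attr(aln, "phylogroup")
      within_max <- 0; between <- c()
      ids <- rownames(aln)
      for (i in seq_along(ids)[-1]) for (j in seq_len(i - 1)) {
        if (pg[[ids[i]]] == pg[[ids[j]]])
          within_max <- max(within_max, pd[i, j])
        else between <- c(between, pd[i, j])
      }
      expect_lte(within_max, cfg$within_clade_p)
      expect_lte(max(between), cfg$between_clade_p[[m]])
      # realized between-clade divergence within 20% of the target
      expect_gte(mean(between), 0.8 * cfg$between_clade_p[[m]] - 2 / ncol(aln))
    }
  }
})

test_that("generator exceptions propagate to the recovered site purities", {
  cfg <- synth_config(seed = 17)
  b <- simulate_study(cfg)
  res <- run_pipeline(b$peaks, fasta = b$sequences, design = b$design)
  purity <- res$report$site_purity
  expect_equal(purity$purity[purity$site %in% c("1", "6")], rep(2 / 3, 2))
  expect_equal(purity$purity[!purity$site %in% c("1", "6")], rep(1, 5))
})

test_that("written bundle is consumed identically to the in-memory bundle", {
  cfg <- synth_config(seed = 23)
  dir <- withr::local_tempdir()
  b <- simulate_study(cfg, dir = dir)
  res_file <- run_pipeline(file.path(dir, "peaks.csv"),
                           fasta = list(cox1 = file.path(dir, "cox1.fasta"),
                                        rbcL = file.path(dir, "rbcL.fasta")),
                           design = file.path(dir, "design.csv"))
  res_mem <- run_pipeline(b$peaks, fasta = b$sequences, design = b$design)
  expect_equal(res_file$chemogroups, res_mem$chemogroups)
  for (m in c("cox1", "rbcL"))
    expect_equal(as_partition_vector(res_file$phylo[[m]]$phylogroups),
                 as_partition_vector(res_mem$phylo[[m]]$phylogroups))
})
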