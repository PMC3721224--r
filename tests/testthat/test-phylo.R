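test_that("p-distance applies pairwise deletion of gaps and Ns", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("ACGT", "ACGA"), 0.25)
  expect_equal(p_distance("AC-T", "ACGT"), 0)     # 3 compared sites
  expect_equal(p_distance("ACNT", "ACGA"), 1 / 3) # N excluded
  expect_equal(p_distance("ACRT", "ACGT"), 0)     # other ambiguity -> N
  expect_equal(p_distance("AC-T", "ACGT"), p_distance("ACGT", "AC-T"))
  expect_error(p_distance("----", "ACGT"), "no comparable sites")
  expect_error(p_distance("ACG", "ACGT"), "equal length")
})

test_that("p-distance matrix agrees with ape raw distances", {
  skip_if_not_installed("ape")
  cfg <- synth_config(seed = 13)
  aln <- simulate_sequences(cfg, "cox1")
  ours <- as.matrix(p_distance_matrix(aln))
  bin <- ape::as.DNAbin(apply(aln, 1, tolower, simplify = FALSE))
  ref <- as.matrix(ape::dist.dna(bin, model = "raw",
                                 pairwise.deletion = TRUE))
  expect_equal(ours, ref[rownames(ours), colnames(ours)], tolerance = 1e-12)
})

test_that("Jukes-Cantor correction matches its closed form", {
  expect_equal(jc_distance(0), 0)
  expect_equal(jc_distance(0.0210), 0.02130, tolerance = 1e-4)
  expect_error(jc_distance(0.75), "saturation")
})

test_that("NJ recovers an additive four-taxon tree exactly", {
  # tree ((A:1,B:2):1,(C:3,D:4)) -> path distances
  dm <- matrix(c(0, 3, 5, 6,
                 3, 0, 6, 7,
                 5, 6, 0, 7,
                 6, 7, 7, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(as.dist(dm))
  expect_equal(tree_distances(tr, LETTERS[1:4]), dm, tolerance = 1e-9)
  pg <- assign_phylogroups(tr, k = 2)
  grp <- setNames(pg$group, pg$sample_id)
  expect_identical(unname(grp["A"]), unname(grp["B"]))
  expect_identical(unname(grp["C"]), unname(grp["D"]))
  expect_false(grp[["A"]] == grp[["C"]])
})

test_that("three-taxon NJ solves the closed-form star", {
  dm <- matrix(c(0, 2, 3,
                 2, 0, 5,
                 3, 5, 0), 3, 3, dimnames = list(c("x", "y", "z"),
                                                 c("x", "y", "z")))
  tr <- neighbor_joining(as.dist(dm))
  expect_equal(tree_distances(tr, c("x", "y", "z")), dm, tolerance = 1e-12)
  expect_error(neighbor_joining(as.dist(dm[1:2, 1:2])), "at least 3")
})

test_that("identical rows join first with zero-length terminal pair", {
  dm <- matrix(c(0, 0, 4, 5,
                 0, 0, 4, 5,
                 4, 4, 0, 3,
                 5, 5, 3, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(as.dist(dm))
  D <- tree_distances(tr, letters[1:4])
  expect_equal(unname(D["a", "b"]), 0, tolerance = 1e-12)
  expect_true(all(tr$edge.length >= 0))
})

test_that("NJ matches ape::nj on random additive matrices", {
  skip_if_not_installed("ape")
  set.seed(53)
  for (trial in 1:10) {
    gen <- random_additive_tree(sample(4:8, 1))
    ours <- neighbor_joining(as.dist(gen$D))
    ref <- ape::nj(as.dist(gen$D))
    expect_equal(tree_distances(ours, rownames(gen$D)),
                 tree_distances(ref, rownames(gen$D)), tolerance = 1e-8)
  }
})

test_that("phylogroup labels follow size then smallest leaf id", {
  # 5 tips: {t1,t2} vs {t3,t4,t5}; bigger group gets A
  tr <- ape::read.tree(text = "((t1:1,t2:1):5,(t3:1,(t4:1,t5:1):1):5);")
  tr <- ape::unroot(tr)
  pg <- assign_phylogroups(tr, k = 2)
  grp <- setNames(pg$group, pg$sample_id)
  expect_identical(unname(grp[c("t3", "t4", "t5")]), rep("A", 3))
  expect_identical(unname(grp[c("t1", "t2")]), rep("B", 3)[1:2])
  one <- assign_phylogroups(tr, k = 1)
  expect_identical(unique(one$group), "A")
  star <- ape::read.tree(text = "(a:1,b:1,c:1);")
  expect_error(assign_phylogroups(star, k = 2), "star")
})

test_that("phylogroup assignment is label-invariant under leaf permutation", {
  set.seed(59)
  cfg <- synth_config(seed = 59)
  aln <- simulate_sequences(cfg, "cox1")
  d <- p_distance_matrix(aln)
  ref <- as_partition_vector(
    assign_phylogroups(neighbor_joining(d), k = 2))
  dm <- as.matrix(d)
  for (trial in 1:3) {
    perm <- sample(nrow(dm))
    got <- as_partition_vector(
      assign_phylogroups(neighbor_joining(as.dist(dm[perm, perm])), k = 2))
    expect_equal(pair_count_ari(ref, got), 1)
  }
})

test_that("divergence report tallies coverage and bounds", {
  aln <- rbind(s1 = strsplit("ACGTACGT", "")[[1]],
               s2 = strsplit("ACGTACGT", "")[[1]],
               s3 = strsplit("ACGTACGT", "")[[1]])
  rep0 <- divergence_report(p_distance_matrix(aln), marker = "cox1")
  expect_equal(rep0$max_overall_pct, 0)
  expect_true(rep0$conspecific)
  expect_identical(rep0$n_samples, 3L)

  cfg <- synth_config(seed = 61)
  for (m in c("cox1", "rbcL")) {
    aln <- simulate_sequences(cfg, m)
    pd <- p_distance_matrix(aln)
    truth <- partition(rownames(aln), attr(aln, "phylogroup")[rownames(aln)])
    repm <- divergence_report(pd, truth, marker = m)
    expect_lte(repm$max_overall_pct, 100 * cfg$between_clade_p[[m]])
    expect_true(all(repm$max_within_pct <= 100 * cfg$within_clade_p))
    expect_true(repm$conspecific)
  }
})

test_that("alignment reader rejects ragged FASTA input", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGTACGT", ">s2", "ACGTA"), path)
  expect_error(read_alignment(path), "not aligned")
  writeLines(c(">s1", "ACGTACGT", ">s2", "ACGAACGT"), path)
  aln <- read_alignment(path, marker = "cox1")
  expect_identical(dim(aln), c(2L, 8L))
  expect_equal(p_distance(aln[1, ], aln[2, ]), 1 / 8)
})
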