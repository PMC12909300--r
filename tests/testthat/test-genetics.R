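test_that("adaptive permutation p-values honor the sequential formula", {
  set.seed(59)
  trait <- rnorm(50)
  # statistic far above anything permutable: zero exceedances at the cap
  res <- adaptive_permutation_p(1e9, function(y) sum(y), trait,
                                max_perm = 200, seed = 5)
  expect_equal(res$p, 1 / 201)
  expect_equal(res$n_used, 200)
  # a contrast statistic at its null median stops early near p = 0.5
  w <- rep(c(1, -1), 25)
  stat <- function(y) sum(w * y)
  res2 <- adaptive_permutation_p(0, stat, trait, max_perm = 1000,
                                 target_exceed = 10, seed = 5)
  expect_lt(res2$n_used, 100)
  expect_gt(res2$p, 0.25)
  expect_lt(res2$p, 0.75)
  # determinism under the seed
  res3 <- adaptive_permutation_p(0, stat, trait, max_perm = 1000,
                                 target_exceed = 10, seed = 5)
  expect_identical(res2, res3)
})

test_that("the founder scan finds a planted additive effect", {
  set.seed(61)
  n <- 200
  geno <- simulate_founder_genotypes(n, 12, seed = 7)
  trait <- rnorm(n)
  cfg <- sim_config(n_markers = 12, planted_marker = 4,
                    planted_founder = 8, planted_effect = 1.2)
  trait <- apply_planted_effect(trait, geno, cfg)
  scan <- founder_scan(trait, geno, max_perm = 500, seed = 9)
  expect_equal(scan$marker_id[which.min(scan$p_perm)], "m0004")
  expect_equal(scan$marker_id[which.max(scan$lod)], "m0004")
  # lod/LRT relationship is exact
  expect_equal(scan$lod, scan$lrt_stat / (2 * log(10)), tolerance = 1e-9)
  # constant trait: zero statistics, p-values 1
  scan0 <- founder_scan(rep(3, n), geno[1:3], max_perm = 200, seed = 2)
  expect_equal(scan0$lrt_stat, rep(0, 3))
  expect_equal(scan0$p_perm, rep(1, 3))
})

test_that("covariates are absorbed before testing founder effects", {
  set.seed(67)
  n <- 150
  geno <- simulate_founder_genotypes(n, 5, seed = 3)
  diet <- rep(c(0, 1), length.out = n)
  trait <- 2 * diet + rnorm(n, 0, 0.5)
  scan <- founder_scan(trait, geno, covariates = cbind(diet = diet),
                       max_perm = 300, seed = 4)
  # diet-driven variance does not masquerade as genetic signal
  expect_true(all(scan$p_perm > 0.01))
})

test_that("singleton clusters reduce the FDR procedure to textbook BH", {
  set.seed(71)
  m <- 500
  p <- c(runif(20, 1e-6, 1e-4), runif(m - 20))
  thr <- cluster_fdr_threshold(matrix(p, ncol = 1), clusters = "c1",
                               alpha = 0.05, seed = 1)
  # independent BH oracle
  srt <- sort(p)
  pass <- srt <= 0.05 * seq_len(m) / m
  bh_cut <- if (any(pass)) max(srt[seq_len(max(which(pass)))]) else 0
  expect_equal(thr$study_threshold, bh_cut)
  # all-null matrix: nothing passes, threshold collapses to zero
  pn <- matrix(runif(200, 0.5, 1), ncol = 2)
  thr0 <- cluster_fdr_threshold(pn, clusters = c("c1", "c1"), seed = 1)
  expect_equal(thr0$study_threshold, 0)
})

test_that("the study threshold is the minimum across clusters", {
  set.seed(73)
  P <- cbind(c(runif(10, 1e-8, 1e-6), runif(490)),
             runif(500), runif(500), runif(500))
  thr <- cluster_fdr_threshold(P, clusters = c("a", "a", "b", "b"),
                               seed = 2)
  expect_equal(thr$study_threshold, min(thr$cluster_thresholds))
  expect_length(thr$cluster_thresholds, 2)
})

test_that("FAP grouping partitions variants and ranks by peak LOD", {
  v <- data.frame(
    variant_id = paste0("v", 1:3), pos_bp = c(100, 200, 300),
    lod = c(6.0, 5.1, 4.2),
    founders_alt = c("WSB", "WSB", "NOD/CAST"),
    stringsAsFactors = FALSE)
  g <- fap_group_variants(v)
  expect_equal(g$pattern[g$rank == 1], "WSB")
  expect_equal(g$max_lod[g$rank == 1], 6.0)
  expect_equal(g$pattern[g$rank == 2], "NOD/CAST")
  expect_equal(g$n_variants[g$rank == 1], 2)
  # the larger founder set flips to its complement as the minor allele
  v2 <- data.frame(variant_id = "v9", pos_bp = 10, lod = 3,
                   founders_alt = "AJ/B6/129/NOD/NZO/CAST/PWK")
  g2 <- fap_group_variants(v2)
  expect_equal(g2$pattern, "WSB")
  # 4-vs-4 split: lexicographically smaller set wins
  v3 <- data.frame(variant_id = "v10", pos_bp = 20, lod = 2,
                   founders_alt = "NZO/CAST/PWK/WSB")
  g3 <- fap_group_variants(v3)
  expect_equal(g3$pattern, "AJ/B6/129/NOD")  # canonical founder order
  # non-segregating variants are dropped
  v4 <- data.frame(variant_id = "v11", pos_bp = 1, lod = 9,
                   founders_alt = "AJ/B6/129/NOD/NZO/CAST/PWK/WSB")
  expect_equal(nrow(fap_group_variants(v4)), 0)
})

test_that("a ten-variant constructed locus groups and ranks correctly", {
  v <- data.frame(
    variant_id = paste0("v", 1:10),
    pos_bp = seq(1e6, by = 1e5, length.out = 10),
    lod = c(6.2, 3.1, 5.8, 2.2, 6.9, 1.0, 4.4, 4.5, 2.8, 3.3),
    founders_alt = c("WSB", "NOD/CAST", "WSB", "AJ", "WSB", "NOD/CAST",
                     "AJ", "NOD/CAST", "AJ", "PWK/WSB"),
    stringsAsFactors = FALSE)
  g <- fap_group_variants(v)
  expect_equal(nrow(g), 4)
  expect_equal(g$rank, 1:4)
  expect_equal(g$pattern[1], "WSB")       # max lod 6.9
  expect_equal(g$pattern[2], "NOD/CAST")  # max lod 4.5
  expect_equal(g$pattern[3], "AJ")        # max lod 4.4
  expect_equal(g$pattern[4], "PWK/WSB")   # max lod 3.3
  expect_equal(sum(g$n_variants), 10)
  expect_equal(g$top_variant[1], "v5")
})

test_that("phenotype clustering splits correlated blocks", {
  set.seed(79)
  base1 <- rnorm(100)
  base2 <- rnorm(100)
  tm <- cbind(base1 + rnorm(100, 0, 0.3), base1 + rnorm(100, 0, 0.3),
              base2 + rnorm(100, 0, 0.3), base2 + rnorm(100, 0, 0.3))
  cl <- cluster_phenotypes(tm, k = 2)
  expect_equal(cl[1], cl[2])
  expect_equal(cl[3], cl[4])
  expect_false(cl[1] == cl[3])
})
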