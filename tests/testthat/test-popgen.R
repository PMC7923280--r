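test_that("allele frequencies count ALT copies among non-missing calls", {
  m <- make_geno(c(2, 2, 2,  0, 1, 2,  0, 0, 0), 3, 3)
  p <- allele_frequency(m)
  expect_equal(unname(p), c(1, 0.5, 0))
  m[1, 1] <- NA
  expect_equal(unname(allele_frequency(m))[1], 1)
  expect_error(allele_frequency(matrix(3, 1, 1)), "codes")
})

test_that("GRM matches hand-computed single-SNP relationships", {
  # one SNP at p = 0.5: both heterozygous -> centred terms vanish
  m <- make_geno(c(1, 1, 0, 2), 2, 2)  # SNP2 codes 0/2 keep p at 0.5
  g <- compute_grm(m, p = c(0.5, 0.5))
  # pair term SNP1: (1-1)(1-1)/0.5 = 0; SNP2: (0-1)(2-1)/0.5 = -2; mean -1
  expect_equal(unname(g[1, 2]), -1)
  g1 <- compute_grm(make_geno(c(1, 1), 2, 1), p = 0.5)
  expect_equal(unname(g1[1, 2]), 0)
  g2 <- compute_grm(make_geno(c(2, 0), 2, 1), p = 0.5)
  expect_equal(unname(g2[1, 2]), -2)
})

test_that("GRM is symmetric with near-zero off-diagonals for unrelated samples", {
  cfg <- sim_config(n_scaffolds = 3, n_founders = 60, n_trios = 0,
                    n_sites = 10000, n_subpopulations = 1, divergence = 0,
                    seed = 14)
  pop <- simulate_population(cfg, simulate_scaffolds(cfg))
  g <- compute_grm(filter_polymorphic(pop$genotypes, min_maf = 0.05))
  expect_equal(unclass(g), t(unclass(g)))
  off <- g[upper.tri(g)]
  expect_lt(abs(mean(off)), 3 * stats::sd(off) / sqrt(length(off)) + 0.02)
  # HWE population: mean diagonal near 1 + mean F
  f <- inbreeding_f3(filter_polymorphic(pop$genotypes, min_maf = 0.05))
  expect_lt(abs(mean(diag(g)) - (1 + mean(f))), 0.05)
})

test_that("missing genotypes are skipped pairwise in the GRM", {
  m <- make_geno(c(0, 1, 2, NA,  2, 0, NA, 1,  1, 1, 1, 1), 4, 3)
  g <- compute_grm(m)
  p <- allele_frequency(m)
  # pair (1,2) by direct evaluation over their shared non-missing SNPs
  shared <- which(!is.na(m[1, ]) & !is.na(m[2, ]) & p > 0 & p < 1)
  direct <- mean((m[1, shared] - 2 * p[shared]) * (m[2, shared] - 2 * p[shared]) /
                   (2 * p[shared] * (1 - p[shared])))
  expect_equal(unname(g[1, 2]), direct)
  expect_error(compute_grm(matrix(2, 3, 2)), "polymorphic")
})

test_that("trio classification recovers simulated pedigree structure", {
  cfg <- sim_config(n_scaffolds = 3, n_founders = 60, n_trios = 15,
                    n_sites = 10000, n_subpopulations = 1, divergence = 0,
                    seed = 15)
  pop <- simulate_population(cfg, simulate_scaffolds(cfg))
  g <- compute_grm(filter_polymorphic(pop$genotypes, min_maf = 0.05))
  trios <- classify_trios(g, pop$pedigree)
  expect_true(all(trios$trio_concordant))
  expect_lt(abs(mean(c(trios$g_sire, trios$g_dam)) - 0.5), 0.05)

  # shuffled pedigree: unrelated "parents" are discordant
  shuffled <- pop$pedigree
  shuffled$sire_id <- sprintf("founder_%03d", 31:45)  # never used as parents
  trios_bad <- classify_trios(g, shuffled)
  expect_gt(mean(!trios_bad$sire_concordant), 0.9)

  # a sample posing as its own parent exceeds the window and is flagged
  self_ped <- data.frame(progeny_id = "founder_001",
                         sire_id = "founder_001", dam_id = "founder_002")
  self_check <- classify_trios(g, self_ped)
  expect_false(self_check$sire_concordant)

  expect_error(classify_trios(g, data.frame(progeny_id = "ghost",
                                            sire_id = "founder_001",
                                            dam_id = "founder_002")),
               "not genotyped")
})

test_that("half-sib pairs sit in the quarter-relationship window", {
  cfg <- sim_config(n_scaffolds = 3, n_founders = 90, n_trios = 30,
                    n_sites = 10000, n_subpopulations = 1, divergence = 0,
                    seed = 16)
  sires <- rep(1:15, each = 2)
  pop <- simulate_population(cfg, simulate_scaffolds(cfg), sire_assignment = sires)
  g <- compute_grm(filter_polymorphic(pop$genotypes, min_maf = 0.05))
  hs <- classify_half_sibs(g, pop$pedigree)
  expect_equal(nrow(hs), 15)
  expect_lt(abs(mean(hs$g) - 0.25), 0.05)
  expect_gt(mean(hs$concordant), 0.8)
})

test_that("inbreeding estimator matches hand-computed single-SNP values", {
  # p = 0.5: heterozygote -> (1 - 2 + 0.5)/0.5 = -1; homozygote ref -> +1
  expect_equal(unname(inbreeding_f3(make_geno(1, 1, 1), p = 0.5)), -1)
  expect_equal(unname(inbreeding_f3(make_geno(0, 1, 1), p = 0.5)), 1)
  expect_equal(unname(inbreeding_f3(make_geno(2, 1, 1), p = 0.5)), 1)
})

test_that("heterozygosity counts heterozygous calls per genotyped locus", {
  expect_equal(unname(heterozygosity(make_geno(rep(1, 10), 1, 10))$per_sample), 1)
  expect_equal(unname(heterozygosity(make_geno(rep(c(0, 2), 5), 1, 10))$per_sample), 0)
  m <- make_geno(c(1, 1, 0, 2, NA), 1, 5)
  expect_equal(unname(heterozygosity(m)$per_sample), 0.5)
})

test_that("concordance scores comparable calls under the depth rule", {
  a <- make_geno(sample(0:2, 50, replace = TRUE), 5, 10)
  expect_equal(genotype_concordance(a, a)$overall, 1)

  b <- a
  b[1, 1] <- (a[1, 1] + 1) %% 3  # one mismatch for sample 1
  cc <- genotype_concordance(a, b)
  expect_equal(cc$per_sample$concordance[1], 0.9)

  d <- matrix(5, 5, 10, dimnames = dimnames(a))
  expect_equal(genotype_concordance(a, b, depth_a = d, min_depth = 3)$pooled,
               49 / 50)
  d0 <- matrix(1, 5, 10, dimnames = dimnames(a))
  expect_warning(res <- genotype_concordance(a, b, depth_a = d0, min_depth = 3),
                 "no comparable")
  expect_true(is.na(res$pooled))
  disjoint <- matrix(0L, 2, 3, dimnames = list(c("x1", "x2"),
                                               c("other1", "other2", "other3")))
  expect_error(genotype_concordance(a, disjoint), "overlapping")
})

test_that("LD pruning drops one of each correlated pair, deterministically", {
  set.seed(31)
  base <- make_geno(sample(0:2, 500 * 20, replace = TRUE, prob = c(.25, .5, .25)),
                    500, 20)
  dup <- cbind(base, base[, 3, drop = FALSE])
  colnames(dup) <- c(colnames(base), "snp_dup")
  kept <- ld_prune(dup, r2_max = 0.5)
  expect_true("snp0003" %in% kept)
  expect_false("snp_dup" %in% kept)    # later member of the r2 = 1 pair
  # independent SNPs at n = 500 stay
  expect_equal(ld_prune(base, r2_max = 0.5), colnames(base))
  expect_equal(ld_prune(dup, r2_max = 1.0), colnames(dup))
  expect_identical(ld_prune(dup, r2_max = 0.5), kept)
})

test_that("Weir-Cockerham FST hits its known limits and the null", {
  set.seed(41)
  # null: one panmictic population split arbitrarily in two
  m <- make_geno(stats::rbinom(100 * 2000, 2, 0.3), 100, 2000)
  groups <- rep(c("a", "b"), each = 50)
  null_fst <- fst_pairwise(m, groups)$fst
  expect_lt(abs(null_fst), 0.01)

  # fixed opposite alleles: FST -> 1
  fixed <- make_geno(c(rep(0, 20), rep(2, 20)), 40, 50)
  fixed[21:40, ] <- 2; fixed[1:20, ] <- 0
  expect_equal(fst_pairwise(fixed, rep(c("a", "b"), each = 20))$fst, 1,
               tolerance = 1e-6)

  expect_error(fst_pairwise(m, c("a", rep("b", 99))), "fewer than 2")
  expect_error(fst_pairwise(m, rep("a", 100)), "two groups")

  # invariance to sample order; labels permute with the samples
  ord <- sample(nrow(m))
  reordered <- fst_pairwise(m[ord, ], groups[ord])
  expect_equal(reordered$fst, null_fst)
})

test_that("principal components separate diverged groups deterministically", {
  cfg <- sim_config(n_scaffolds = 3, n_founders = 60, n_trios = 0,
                    n_sites = 4000, n_subpopulations = 2, divergence = 0.2,
                    seed = 18)
  pop <- simulate_population(cfg, simulate_scaffolds(cfg))
  g <- compute_grm(filter_polymorphic(pop$genotypes, min_maf = 0.05))
  pcs <- pca_structure(g, k = 2)
  grp <- pop$groups[rownames(pcs)]
  r1 <- range(pcs[grp == "pop1", 1]); r2 <- range(pcs[grp == "pop2", 1])
  expect_true(r1[2] < r2[1] || r2[2] < r1[1])  # no overlap on PC1
  expect_identical(pcs, pca_structure(g, k = 2))
  expect_error(pca_structure(g, k = nrow(g) + 1), "exceeds")
})
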