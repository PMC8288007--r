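test_that("cohort simulation respects the design and is deterministic", {
  cohort <- fixture_cohort(seed = 11L)
  expect_equal(nrow(cohort), 20L)
  expect_equal(as.vector(table(cohort$site)), c(10L, 10L))
  expect_equal(sum(cohort$sex == "F"), 10L)
  expect_equal(sum(cohort$sex == "M"), 10L)
  tab <- table(cohort$site, cohort$sex)
  expect_equal(tab["control", "F"], 6L)
  expect_equal(tab["seep", "F"], 4L)
  expect_true(all(cohort$body_length_mm > 0))
  expect_identical(cohort, fixture_cohort(seed = 11L))
  expect_false(identical(cohort$body_length_mm,
                         fixture_cohort(seed = 12L)$body_length_mm))
  expect_error(cohort_config(n_seep = 0L), "positive")
  expect_error(cohort_config(sex_split = list(control = c(F = 9L, M = 4L),
                                              seep = c(F = 4L, M = 6L))),
               "sum")
})

test_that("count simulator matches its mean model", {
  cohort <- fixture_cohort()
  ## dispersion 0, no effects: Poisson(50); per-gene sample mean within 3 SE
  eff <- gene_effects(sprintf("g%03d", 1:200), baseline_mean = 50,
                      dispersion = 0)
  sim <- simulate_counts(cohort, eff, seed = 5L)
  depth <- sim$truth$depth_factors
  scaled <- sweep(sim$counts, 2L, depth, "/")
  se <- sqrt(50 / ncol(sim$counts))
  expect_true(mean(abs(rowMeans(scaled) - 50) < 3 * se) > 0.95)
  ## log2fc_ph = 1 doubles the seep group mean at large baseline
  eff2 <- gene_effects(sprintf("h%03d", 1:300), baseline_mean = 5000,
                       dispersion = 0, log2fc_ph = 1)
  sim2 <- simulate_counts(cohort, eff2, seed = 6L)
  scaled2 <- sweep(sim2$counts, 2L, sim2$truth$depth_factors, "/")
  seep <- cohort$site == "seep"
  ratios <- rowMeans(scaled2[, seep]) / rowMeans(scaled2[, !seep])
  expect_equal(mean(ratios), 2, tolerance = 0.02)
  expect_error(simulate_counts(cohort, transform(eff, dispersion = -1)),
               "dispersion")
})

test_that("NB counts obey the variance identity var = mu + alpha mu^2", {
  cohort <- fixture_cohort()
  eff <- gene_effects(sprintf("v%04d", 1:2000), baseline_mean = 100,
                      dispersion = 0.5)
  sim <- simulate_counts(cohort, eff, seed = 7L)
  scaled <- sweep(sim$counts, 2L, sim$truth$depth_factors, "/")
  ## pool across genes: each gene contributes n = 20 draws at mu = 100
  pooled_var <- mean(apply(scaled, 1L, var))
  expect_equal(pooled_var, 100 + 0.5 * 100^2, tolerance = 0.05)
  ## and at alpha = 0 the mean/variance ratio tends to 1
  eff0 <- gene_effects(sprintf("p%04d", 1:2000), baseline_mean = 100,
                       dispersion = 0)
  sim0 <- simulate_counts(cohort, eff0, seed = 8L)
  scaled0 <- sweep(sim0$counts, 2L, sim0$truth$depth_factors, "/")
  expect_equal(mean(apply(scaled0, 1L, var)) / 100, 1, tolerance = 0.05)
})

test_that("genotype simulator respects HWE and the spectrum contrast", {
  ref <- paste(rep("ACGT", 250), collapse = "")
  ## fixed frequency 0.5 via balanced spectrum with huge shape: check the
  ## heterozygote fraction is ~0.5 instead through a direct HWE draw
  gt <- simulate_genotypes("g1", spectrum_spec("balanced", 400), 20L, ref,
                           seed = 2L)
  expect_equal(nrow(gt), 400L)
  expect_true(all(gt$ref != gt$alt))
  expect_false(anyDuplicated(gt$pos) > 0L)
  tot <- rowSums(gt$geno)
  expect_true(all(tot > 0L & tot < 40L))  # every SNP segregates
  ## balanced mean MAF exceeds neutral mean MAF at matched 2N
  nt <- simulate_genotypes("g2", spectrum_spec("neutral", 400), 20L, ref,
                           seed = 3L)
  maf <- function(g) {
    c <- rowSums(g$geno)
    pmin(c, 40 - c) / 40
  }
  expect_gt(mean(maf(gt)), mean(maf(nt)))
  ## empty spec and oversized spec
  empty <- simulate_genotypes("g3", spectrum_spec("neutral", 0), 20L, ref)
  expect_equal(nrow(empty), 0L)
  expect_error(simulate_genotypes("g4", spectrum_spec("neutral", 2000), 20L,
                                  ref),
               "exceeds")
})

test_that("balanced spectrum stochastically dominates the neutral one", {
  ## spec-level separation property: one-sided K-S at 1e4 SNPs
  ref <- strrep("ACGT", 2600)
  bal <- simulate_genotypes("b", spectrum_spec("balanced", 10000L), 20L, ref,
                            seed = 4L)
  neu <- simulate_genotypes("n", spectrum_spec("neutral", 10000L), 20L, ref,
                            seed = 5L)
  ks <- ks_compare(folded_sfs(bal$geno, label = "balanced"),
                   folded_sfs(neu$geno, label = "neutral"))
  expect_lt(ks$p_value, 1e-6)
})

test_that("pileup simulator has the stated marginal behaviour", {
  ref <- strrep("ACGT", 75)
  gt <- simulate_genotypes("g1", spectrum_spec("balanced", 10), 4L, ref,
                           seed = 9L)
  ## error-free, hom-alt individuals carry only the alt base at the SNP
  pl <- simulate_pileups(gt, ref, coverage_mean = 60, error_rate = 0,
                         seed = 10L)
  for (j in seq_len(4L)) {
    hom <- which(gt$geno[, j] == 2L)
    for (s in hom) {
      cnt <- pl[[j]]$counts[gt$pos[s] + 1L, ]
      expect_equal(sum(cnt) , cnt[[gt$alt[s]]])
    }
  }
  ## heterozygote allele balance at deep coverage
  gt1 <- gt[1L, , drop = FALSE]
  gt1$geno <- matrix(1L, 1L, 4L, dimnames = list(NULL, colnames(gt$geno)))
  deep <- simulate_pileups(gt1, ref, coverage_mean = 1000, error_rate = 0,
                           seed = 11L)
  cnt <- deep[[1L]]$counts[gt1$pos + 1L, ]
  expect_equal(cnt[[gt1$alt]] / sum(cnt), 0.5, tolerance = 0.05)
  ## zero-depth fraction ~ exp(-coverage_mean)
  shallow <- simulate_pileups(gt1, strrep("ACGT", 2500), coverage_mean = 5,
                              error_rate = 0, seed = 12L)
  frac0 <- mean(rowSums(shallow[[1L]]$counts) == 0L)
  p0 <- exp(-5)
  expect_lt(abs(frac0 - p0), 3 * sqrt(p0 * (1 - p0) / 10000))
  expect_error(simulate_pileups(gt, ref, error_rate = 0.3), "error_rate")
})

test_that("haplotype transcripts collapse heterozygotes plausibly", {
  ref <- strrep("ACGT", 30)
  gt <- simulate_genotypes("g1", spectrum_spec("neutral", 6), 20L, ref,
                           seed = 13L)
  ## all-homozygous individual: emitted sequence equals substituted reference
  gt$geno[, 1L] <- 2L * (rowSums(gt$geno[, -1L, drop = FALSE]) > 20L)
  tx <- emit_haplotype_transcripts(gt, ref, seed = 14L)
  expected <- strsplit(ref, "")[[1L]]
  expected[gt$pos[gt$geno[, 1L] == 2L] + 1L] <- gt$alt[gt$geno[, 1L] == 2L]
  expect_identical(tx[[1L]], paste(expected, collapse = ""))
  expect_identical(tx, emit_haplotype_transcripts(gt, ref, seed = 14L))
  ## a p = 0.5 site yields ~10 minor bases across 20 collapsed haplotypes
  gt2 <- gt[1L, , drop = FALSE]
  counts <- replicate(100, {
    gt2$geno <- matrix(rbinom(20L, 2L, 0.5), 1L, 20L,
                       dimnames = list(NULL, colnames(gt$geno)))
    tx <- emit_haplotype_transcripts(gt2, ref, seed = NULL)
    sum(substring(tx, gt2$pos + 1L, gt2$pos + 1L) == gt2$alt)
  })
  expect_lt(abs(mean(counts) - 10), 3 * sd(counts) / sqrt(100))
})

test_that("hit-table simulator reproduces its own ground truth", {
  sim <- simulate_hit_table(30L, n_ref_species = 3L, redundancy = 3L,
                            seed = 15L)
  expect_equal(nrow(sim$truth), 10L)
  merged <- merge_across_species(best_per_reference(filter_hits(sim$hits)),
                                 sim$ortholog_map)
  expect_equal(merged$anchor_gene_id, sim$truth$anchor_gene_id)
  expect_equal(merged$chosen_transcript_id, sim$truth$chosen_transcript_id)
  expect_equal(merged$n_species_support, sim$truth$n_species_support)
  expect_equal(merged$pct_recovered, sim$truth$pct_recovered)
  ## redundancy 1, one species: one merged gene per transcript
  sim1 <- simulate_hit_table(12L, n_ref_species = 1L, redundancy = 1L,
                             seed = 16L)
  merged1 <- merge_across_species(best_per_reference(filter_hits(sim1$hits)),
                                  sim1$ortholog_map)
  expect_equal(nrow(merged1), 12L)
  expect_identical(sim$hits, simulate_hit_table(30L, 3L, 3L, seed = 15L)$hits)
})
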