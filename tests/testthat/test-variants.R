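test_that("pileup caller applies the screening thresholds literally", {
  ref <- strrep("A", 10L)
  mk <- function(...) toy_pileup(..., ref = ref, L = 10L)
  pus <- list(
    mk("i1", overrides = list(`5` = c(A = 4L, G = 5L))),          # depth 9
    mk("i2", overrides = list(`5` = c(A = 80L, G = 20L))),        # het 0.20
    mk("i3", overrides = list(`5` = c(A = 20L, G = 80L))),        # hom 0.80
    mk("i4", overrides = list(`5` = c(A = 96L, G = 4L))))         # 0.04 < minfreq
  snps <- pileup_call(pus, ref)
  expect_equal(nrow(snps), 1L)
  expect_equal(snps$pos, 4L)
  expect_equal(snps$alt, "G")
  expect_identical(unname(snps$geno[1L, ]), c(NA, 1L, 2L, 0L))
  ## quality below threshold suppresses the variant call
  lowq <- list(mk("i1", overrides = list(`5` = c(A = 80L, G = 20L)),
                  qual = 10))
  expect_equal(nrow(pileup_call(lowq, ref)), 0L)
  ## alt reads below min_alt_reads never become variants
  few <- list(mk("i1", overrides = list(`5` = c(A = 98L, G = 2L))))
  expect_equal(nrow(pileup_call(few, ref)), 0L)
  expect_error(pileup_call(pus, strrep("N", 10L)), "outside")
})

test_that("anchor alignment projects onto reference coordinates", {
  ref <- "ATGGCCAAATTTGGGCCCAAATTTGGGCCCAAATTTGGGCCCAAATTTGGGCCCAAATTT"
  ## identity
  al <- anchor_align(ref, ref)
  expect_true(al$alignable)
  expect_equal(al$identity, 100)
  expect_identical(paste(al$projection, collapse = ""), ref)
  ## one substitution: exactly one mismatched column
  mut <- ref
  substring(mut, 30L, 30L) <- "T"
  al2 <- anchor_align(mut, ref)
  expect_equal(sum(al2$projection != strsplit(ref, "")[[1L]]), 1L)
  expect_equal(al2$projection[30L], "T")
  ## 5' truncation: leading positions project to gap, remainder identity
  al3 <- anchor_align(substring(ref, 11L), ref)
  expect_identical(al3$projection[1:10], rep("-", 10L))
  expect_identical(paste(al3$projection[11:60], collapse = ""),
                   substring(ref, 11L))
  ## diverged sequence flagged unalignable
  al4 <- anchor_align(strrep("TATA", 15L), ref)
  expect_false(al4$alignable)
})

test_that("column counting calls SNPs above the minor-count floor", {
  ## 20 individuals x 3 positions: 18A+2G, 18A+2G, 19A+1G
  m <- matrix("A", 20L, 3L)
  m[19:20, 1L] <- "G"
  m[19:20, 2L] <- "G"
  m[20L, 3L] <- "G"
  snps <- column_call(m)
  expect_equal(snps$pos, c(0L, 1L))
  expect_equal(snps$minor_count, c(2L, 2L))
  ## gap entries are excluded from the column
  m2 <- matrix("A", 20L, 1L)
  m2[1:10, 1L] <- "-"
  m2[19:20, 1L] <- "G"
  snps2 <- column_call(m2)
  expect_equal(snps2$n_seq, 10L)
  expect_equal(snps2$minor_count, 2L)
})

test_that("reconciliation keeps complete biallelic sites and flags confirmation", {
  geno <- matrix(c(0L, 1L, 2L, 0L,
                   0L, NA, 1L, 0L,
                   1L, 1L, 0L, 2L), 3L, 4L, byrow = TRUE,
                 dimnames = list(NULL, paste0("i", 1:4)))
  pu <- data.frame(gene_id = "g1", pos = c(3L, 7L, 11L), ref = "A",
                   alt = c("G", "C", "T"), n_alt_alleles = c(1L, 1L, 2L),
                   callers = "pileup", stringsAsFactors = FALSE)
  pu$geno <- geno
  al <- data.frame(gene_id = "g1", pos = 3L, major = "A", minor = "G",
                   stringsAsFactors = FALSE)
  out <- reconcile_and_filter(pu, al, 4L)
  ## pos 7 dropped (missing genotype), pos 11 dropped (triallelic)
  expect_equal(out$pos, 3L)
  expect_equal(out$callers, "both")
  expect_equal(out$maf, 3 / 8)
  ## mismatched gene universes abort
  al_bad <- transform(al, gene_id = "g9")
  expect_error(reconcile_and_filter(pu, al_bad, 4L), "universes")
})

test_that("coding-effect classification matches the worked substitutions", {
  ## GGA -> GGG: four-fold degenerate glycine site
  cds <- "ATGGGATAA"
  syn <- classify_coding_effect(5L, "G", cds)
  expect_equal(syn$effect, "synonymous")
  ## CAA -> CGA at codon position 2: Gln -> Arg
  cds2 <- "ATGCAATAA"
  ns <- classify_coding_effect(4L, "G", cds2)
  expect_equal(ns$effect, "nonsynonymous")
  expect_equal(ns$aa_ref, "Q")
  expect_equal(ns$aa_alt, "R")
  ## TAC -> TAA: stop gain
  cds3 <- "ATGTACTAA"
  sg <- classify_coding_effect(5L, "A", cds3)
  expect_equal(sg$effect, "nonsynonymous")
  expect_equal(sg$subtype, "stop_gain")
  ## ambiguous base -> unknown
  cds4 <- "ATGNNATAA"
  expect_equal(classify_coding_effect(4L, "G", cds4)$effect, "unknown")
})

test_that("error-free calling recovers planted genotypes and nests callers", {
  set.seed(55)
  refs <- replicate(3L, {
    paste0("ATG", paste(sample(c("GCT", "GGA", "CCA", "ACT", "TTC"), 99L,
                               replace = TRUE), collapse = ""))
  })
  for (k in 1:3) {
    ref <- refs[k]
    gt <- simulate_genotypes("g", spectrum_spec("balanced", 6L), 20L, ref,
                             seed = 60L + k)
    pl <- simulate_pileups(gt, ref, coverage_mean = 50, error_rate = 0,
                           seed = 70L + k)
    called <- pileup_call(pl, ref)
    ## every planted position recovered with the planted genotype wherever
    ## depth allowed a call
    m <- match(gt$pos, called$pos)
    expect_false(anyNA(m))
    planted <- gt$geno
    got <- called$geno[m, , drop = FALSE]
    comparable <- !is.na(got)
    expect_identical(got[comparable], planted[comparable])
    ## alignment-route SNPs are a subset of pileup SNPs
    tx <- emit_haplotype_transcripts(gt, ref, seed = 80L + k)
    proj <- lapply(tx, anchor_align, reference_cds = ref)
    cc <- column_call(lapply(proj, `[[`, "projection"))
    expect_true(all(cc$pos %in% called$pos))
  }
})

test_that("calling sensitivity for rare SNPs is not expression-biased", {
  ## equal coverage, different notional expression groups: the caller sees
  ## only the pileups, so sensitivity for low-frequency SNPs must match
  set.seed(66)
  ref <- paste0("ATG", paste(sample(c("GCT", "GGA", "CCA", "ACT"), 99L,
                                    replace = TRUE), collapse = ""))
  recover_rate <- function(seed) {
    gt <- simulate_genotypes("g", spectrum_spec("neutral", 15L), 20L, ref,
                             seed = seed)
    sample_maf <- pmin(rowSums(gt$geno), 40L - rowSums(gt$geno)) / 40
    rare <- which(sample_maf < 0.10)
    if (!length(rare)) return(NA_real_)
    pl <- simulate_pileups(gt, ref, coverage_mean = 50, error_rate = 0,
                           seed = seed + 1L)
    called <- pileup_call(pl, ref)
    mean(gt$pos[rare] %in% called$pos)
  }
  rates_a <- vapply(101:110, recover_rate, 0)
  rates_b <- vapply(201:210, recover_rate, 0)
  expect_gte(mean(rates_a, na.rm = TRUE), 0.99)
  expect_gte(mean(rates_b, na.rm = TRUE), 0.99)
})
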