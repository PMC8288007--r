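## Shared fixture builders and independent oracles. Oracles are deliberately
## naive (enumeration / brute force / closed form) and never reuse package
## internals beyond plain accessors.

fixture_cohort <- function(seed = 1L) simulate_cohort(cohort_config(seed = seed))

## A minimal pileup object for one individual: counts given as a list of
## per-position named vectors, e.g. list(`5` = c(A = 80, G = 20)).
toy_pileup <- function(individual_id, L, overrides = list(), ref = NULL,
                       depth = 50L, qual = 30, gene_id = "g1") {
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, L, 4L, dimnames = list(NULL, bases))
  if (!is.null(ref)) {
    refv <- strsplit(ref, "")[[1L]]
    counts[cbind(seq_len(L), match(refv, bases))] <- depth
  }
  for (pos in names(overrides)) {
    counts[as.integer(pos), ] <- 0L
    v <- overrides[[pos]]
    counts[as.integer(pos), names(v)] <- as.integer(v)
  }
  list(individual_id = individual_id, gene_id = gene_id, counts = counts,
       mean_qual = rep(qual, L))
}

## Two-sided Fisher p by exhaustive hypergeometric enumeration over one
## margin; the sum of all table probabilities not exceeding the observed one.
fisher_oracle <- function(n_in_set, n_set, n_in_genome, n_genome) {
  k <- max(0L, n_in_genome - (n_genome - n_set)):min(n_set, n_in_genome)
  pr <- dhyper(k, n_in_genome, n_genome - n_in_genome, n_set)
  obs <- dhyper(n_in_set, n_in_genome, n_genome - n_in_genome, n_set)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

## Quadratic brute-force version of the homology merge: for every anchor
## gene, scan all mapped hits and apply the selection rules directly.
merge_oracle <- function(best_hits, ortholog_map) {
  key <- paste(best_hits$ref_species, best_hits$ref_protein_id)
  mkey <- paste(ortholog_map$ref_species, ortholog_map$ref_protein_id)
  anchor <- ortholog_map$anchor_gene_id[match(key, mkey)]
  hits <- best_hits[!is.na(anchor), , drop = FALSE]
  anchor <- anchor[!is.na(anchor)]
  out <- NULL
  for (g in sort(unique(anchor))) {
    sub <- hits[anchor == g, , drop = FALSE]
    rec <- 100 * sub$ref_aln_length / sub$ref_protein_length
    best <- NULL
    for (i in seq_len(nrow(sub))) {
      if (is.null(best)) {
        best <- i
        next
      }
      a <- c(rec[i], sub$pct_identity[i], -sub$evalue[i])
      b <- c(rec[best], sub$pct_identity[best], -sub$evalue[best])
      cmp <- (a > b) - (a < b)
      nz <- which(cmp != 0)
      better <- if (length(nz)) {
        cmp[nz[1L]] > 0
      } else {
        sub$query_transcript_id[i] < sub$query_transcript_id[best]
      }
      if (better) best <- i
    }
    out <- rbind(out, data.frame(
      anchor_gene_id = g,
      chosen_transcript_id = sub$query_transcript_id[best],
      n_species_support = length(unique(sub$ref_species)),
      pct_recovered = rec[best], stringsAsFactors = FALSE))
  }
  if (is.null(out)) {
    out <- data.frame(anchor_gene_id = character(),
                      chosen_transcript_id = character(),
                      n_species_support = integer(),
                      pct_recovered = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

## Full-translation oracle for coding-effect classification: translate the
## whole CDS before and after each substitution and compare protein strings.
## Vectorised over substitutions (one batched translate call).
translation_oracle <- function(pos, alt, reference_cds) {
  trim <- 3L * (nchar(reference_cds) %/% 3L)
  mutated <- vapply(seq_along(pos), function(i) {
    s <- reference_cds
    substring(s, pos[i] + 1L, pos[i] + 1L) <- alt[i]
    s
  }, "")
  ## no.init.codon: plain codon-table translation (otherwise a mutated first
  ## codon like CTG would be rendered as initiator Met)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(substr(c(reference_cds, mutated), 1L, trim)),
    if.fuzzy.codon = "solve", no.init.codon = TRUE))
  ifelse(aa[-1L] == aa[1L], "synonymous", "nonsynonymous")
}

## Wrap a bare genotype matrix as a minimal SNP table.
toy_snps <- function(geno, gene = "g1") {
  out <- data.frame(gene_id = gene, pos = seq_len(nrow(geno)) - 1L,
                    ref = "A", alt = "G",
                    maf = NA_real_, callers = "both",
                    stringsAsFactors = FALSE)
  out$geno <- geno
  out
}

## Draw a genotype dosage matrix for n_snps SNPs at HWE given frequencies.
hwe_genotypes <- function(freqs, n_individuals) {
  t(vapply(freqs, function(p) rbinom(n_individuals, 2L, p),
           integer(n_individuals)))
}
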