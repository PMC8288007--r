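## Dual-route SNP calling within coding sequences.
##
## Route 1 (pileup thresholding): per-individual per-position nucleotide
## counts are screened with coverage / alt-read / frequency / quality
## thresholds, VarScan-style. Route 2 (alignment column counting): each
## individual's assembled transcript is globally aligned to the gene's
## reference CDS with free end gaps, and nucleotide columns are counted
## across individuals. Route 2 cannot see low-frequency variants (one
## collapsed haplotype per individual) but is robust to sequencing error, so
## it serves to confirm the intermediate-frequency calls of route 1.

#' Pileup-caller thresholds
#'
#' Defaults are the conventional mpileup2snp screening values: minimum depth
#' 10, at least 3 alternative reads, mean base quality 15, variant-allele
#' frequency at least 0.05, and homozygous call at frequency 0.75 or above.
#'
#' @param min_coverage Minimum read depth for any call.
#' @param min_alt_reads Minimum reads supporting the alternative allele.
#' @param min_avg_qual Minimum mean base quality at the position.
#' @param min_var_freq Minimum alternative-allele read frequency.
#' @param min_hom_freq Frequency at or above which a variant call is
#'   homozygous-alternative.
#' @return A validated `caller_params` list.
#' @export
caller_params <- function(min_coverage = 10L, min_alt_reads = 3L,
                          min_avg_qual = 15, min_var_freq = 0.05,
                          min_hom_freq = 0.75) {
  if (!(min_var_freq > 0 && min_var_freq < min_hom_freq && min_hom_freq <= 1)) {
    stop_input("need 0 < min_var_freq < min_hom_freq <= 1")
  }
  structure(list(min_coverage = min_coverage, min_alt_reads = min_alt_reads,
                 min_avg_qual = min_avg_qual, min_var_freq = min_var_freq,
                 min_hom_freq = min_hom_freq), class = "caller_params")
}

#' Call SNPs from per-individual pileups of one gene
#'
#' Per individual and position: positions below `min_coverage` are missing;
#' the alternative allele is the most frequent non-reference base; a variant
#' is called when the alternative reads, their frequency and the mean base
#' quality all pass the thresholds, and is homozygous-alternative at
#' frequency `min_hom_freq` or above, heterozygous otherwise. Positions
#' variant in at least one individual become candidate SNPs, at which every
#' individual is genotyped (homozygous-reference when covered but not
#' variant, missing when depth is insufficient).
#'
#' @param pileups List of pileups for one gene, one per individual (see
#'   [simulate_pileups()] for the structure).
#' @param reference_cds Reference coding sequence (single string, ACGT only).
#' @param params A [caller_params()].
#' @return Data frame of candidate SNPs: `gene_id`, `pos` (0-based), `ref`,
#'   `alt`, `n_alt_alleles` (distinct alternative alleles called across
#'   individuals; 1 = biallelic), `callers = "pileup"`, and genotype dosage
#'   matrix `geno` (0/1/2, `NA` missing; `NA` also for an individual whose
#'   variant call disagrees with the site's majority alternative allele).
#' @export
pileup_call <- function(pileups, reference_cds, params = caller_params()) {
  bases <- c("A", "C", "G", "T")
  refv <- strsplit(toupper(reference_cds), "")[[1L]]
  if (!all(refv %in% bases)) {
    stop_input("reference contains a base outside A/C/G/T: ",
               paste(unique(setdiff(refv, bases)), collapse = ", "))
  }
  L <- length(refv)
  ref_idx <- match(refv, bases)
  ids <- vapply(pileups, function(p) p$individual_id, "")
  gene <- pileups[[1L]]$gene_id
  n <- length(pileups)
  alt_of <- matrix(NA_integer_, L, n)     # per-individual alt base index
  variant <- matrix(FALSE, L, n)
  hom <- matrix(FALSE, L, n)
  covered <- matrix(FALSE, L, n)
  for (j in seq_len(n)) {
    cnt <- pileups[[j]]$counts
    if (!identical(colnames(cnt), bases)) {
      stop_input("pileup counts for ", ids[j],
                 " must have columns A, C, G, T")
    }
    if (nrow(cnt) != L) {
      stop_input("pileup for ", ids[j], " does not cover the reference length")
    }
    depth <- rowSums(cnt)
    covered[, j] <- depth >= params$min_coverage
    nonref <- cnt
    nonref[cbind(seq_len(L), ref_idx)] <- -1L
    ai <- max.col(nonref, ties.method = "first")
    ac <- nonref[cbind(seq_len(L), ai)]
    af <- ifelse(depth > 0, ac / depth, 0)
    mq <- pileups[[j]]$mean_qual
    isvar <- covered[, j] & ac >= params$min_alt_reads &
      af >= params$min_var_freq & !is.na(mq) & mq >= params$min_avg_qual
    variant[, j] <- isvar
    alt_of[isvar, j] <- ai[isvar]
    hom[, j] <- isvar & af >= params$min_hom_freq
  }
  cand <- which(rowSums(variant) > 0L)
  out <- data.frame(gene_id = character(), pos = integer(), ref = character(),
                    alt = character(), n_alt_alleles = integer(),
                    callers = character(), stringsAsFactors = FALSE)
  out$geno <- matrix(integer(), 0L, n, dimnames = list(NULL, ids))
  if (length(cand) == 0L) return(out)
  rows <- vector("list", length(cand))
  geno <- matrix(NA_integer_, length(cand), n, dimnames = list(NULL, ids))
  for (k in seq_along(cand)) {
    p <- cand[k]
    alts <- alt_of[p, ][variant[p, ]]
    ualt <- unique(alts)
    ## site alternative allele: the most supported one (ties: alphabetical)
    site_alt <- ualt[which.max(tabulate(match(alts, ualt)))]
    g <- rep(NA_integer_, n)
    g[covered[p, ] & !variant[p, ]] <- 0L
    agree <- variant[p, ] & alt_of[p, ] == site_alt
    g[agree] <- ifelse(hom[p, agree], 2L, 1L)
    ## a variant call for a different alternative allele stays missing
    geno[k, ] <- g
    rows[[k]] <- data.frame(gene_id = gene, pos = p - 1L, ref = refv[p],
                            alt = bases[site_alt],
                            n_alt_alleles = length(ualt),
                            callers = "pileup", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$geno <- geno
  out
}

## Substitution scores for transcript-to-reference alignment: match +2,
## mismatch -3, N neutral; affine gaps scored so that a first gap position
## costs 5 and each extension 2.
align_submat <- function() {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(-3, 5L, 5L, dimnames = list(b, b))
  diag(m) <- 2
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

#' Align an individual's transcript to the gene's reference CDS
#'
#' Global alignment with free end gaps (overlap alignment), so 5' or 3'
#' truncation of the assembled transcript is not penalised. Every reference
#' position is projected to the aligned transcript base, or to `"-"` where
#' the transcript has a gap (including the unaligned ends). Transcripts whose
#' alignment identity falls below `min_identity`, or whose aligned columns
#' cover less than `min_coverage_frac` of the shorter sequence (an unrelated
#' sequence can still produce a short high-identity island), are flagged
#' unalignable.
#'
#' @param transcript Transcript sequence (single string over A/C/G/T/N).
#' @param reference_cds Reference coding sequence (single string).
#' @param min_identity Minimum percent identity (default 80).
#' @param min_coverage_frac Minimum fraction of the shorter sequence aligned
#'   (default 0.5).
#' @return List with `projection` (character vector, one entry per reference
#'   position), `score`, `identity` (percent), `coverage`, and `alignable`.
#' @export
anchor_align <- function(transcript, reference_cds, min_identity = 80,
                         min_coverage_frac = 0.5) {
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(transcript),
    subject = Biostrings::DNAString(reference_cds),
    type = "overlap", substitutionMatrix = align_submat(),
    gapOpening = 3, gapExtension = 2)
  L <- nchar(reference_cds)
  proj <- rep("-", L)
  tx <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
  rf <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
  refpos <- Biostrings::start(Biostrings::subject(al)) - 1L
  for (i in seq_along(rf)) {
    if (rf[i] != "-") {
      refpos <- refpos + 1L
      proj[refpos] <- tx[i]
    }
  }
  both <- rf != "-" & tx != "-"
  identity <- if (any(both)) 100 * mean(tx[both] == rf[both]) else 0
  coverage <- sum(both) / min(nchar(transcript), L)
  list(projection = proj, score = Biostrings::score(al),
       identity = identity, coverage = coverage,
       alignable = identity >= min_identity && coverage >= min_coverage_frac)
}

#' Call SNPs from aligned transcript columns
#'
#' Counts the A/C/G/T composition of every reference-anchored alignment
#' column across the per-individual haplotype transcripts. A column is a SNP
#' when at least two distinct bases are observed and the second most frequent
#' base occurs at least `min_minor` times; gap and N entries are ignored, so
#' a column is evaluated over the individuals actually aligned there (at
#' least two required).
#'
#' @param projections List (or matrix rows) of per-individual projections
#'   from [anchor_align()]; unalignable individuals should be excluded by the
#'   caller.
#' @param min_minor Minimum minor-base count to call a SNP (default 2;
#'   singletons are indistinguishable from assembly error).
#' @return Data frame of SNP columns: `pos` (0-based), base counts `A`, `C`,
#'   `G`, `T`, `n_seq` (non-gap entries), `n_alleles`, `major`, `minor`,
#'   `minor_count`. Attribute `"column_counts"` holds the full L x 4 count
#'   matrix.
#' @export
column_call <- function(projections, min_minor = 2L) {
  if (is.list(projections)) projections <- do.call(rbind, projections)
  bases <- c("A", "C", "G", "T")
  L <- ncol(projections)
  counts <- sapply(bases, function(b) colSums(projections == b))
  if (L == 1L) counts <- matrix(counts, 1L, 4L, dimnames = list(NULL, bases))
  rows <- list()
  for (p in seq_len(L)) {
    cnt <- counts[p, ]
    nz <- sum(cnt > 0L)
    if (sum(cnt) < 2L || nz < 2L) next
    ord <- order(cnt, decreasing = TRUE)
    if (cnt[ord[2L]] < min_minor) next
    rows[[length(rows) + 1L]] <- data.frame(
      pos = p - 1L, A = cnt[["A"]], C = cnt[["C"]], G = cnt[["G"]],
      T = cnt[["T"]], n_seq = sum(cnt), n_alleles = nz,
      major = bases[ord[1L]], minor = bases[ord[2L]],
      minor_count = cnt[[ord[2L]]], stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(pos = integer(), A = integer(), C = integer(), G = integer(),
               T = integer(), n_seq = integer(), n_alleles = integer(),
               major = character(), minor = character(),
               minor_count = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "column_counts") <- counts
  out
}

#' Reconcile the two callers and apply the complete-data biallelic filter
#'
#' Keeps pileup SNPs that are biallelic (a single alternative allele across
#' individuals), genotyped in all `n_individuals`, and polymorphic in the
#' sample. A SNP is annotated `callers = "both"` when the alignment route
#' reports a SNP at the same gene and position whose observed major/minor
#' bases are contained in the pileup alleles; otherwise it stays `"pileup"`.
#' Only `"both"` SNPs enter the intermediate-frequency summaries downstream.
#'
#' @param pileup_snps Row-bound [pileup_call()] output across genes.
#' @param alignment_snps Row-bound [column_call()] output with a `gene_id`
#'   column added per gene.
#' @param n_individuals Required number of genotyped individuals.
#' @return SNP table (`gene_id`, `pos`, `ref`, `alt`, `maf`, `callers`,
#'   genotype matrix `geno`) sorted by (gene, pos).
#' @export
reconcile_and_filter <- function(pileup_snps, alignment_snps, n_individuals) {
  if (nrow(alignment_snps) > 0L && is.null(alignment_snps$gene_id)) {
    stop_input("alignment_snps must carry a gene_id column")
  }
  pu <- sort(unique(pileup_snps$gene_id))
  au <- sort(unique(alignment_snps$gene_id))
  if (length(au) > 0L && length(setdiff(au, pu)) > 0L) {
    stop_input("caller outputs cover different gene universes: ",
               paste(head(setdiff(au, pu), 5L), collapse = ", "),
               " absent from the pileup calls")
  }
  geno <- snp_genotypes(pileup_snps)
  if (nrow(pileup_snps) > 0L && ncol(geno) != n_individuals) {
    stop_input("genotype matrix has ", ncol(geno), " individuals, expected ",
               n_individuals)
  }
  complete <- rowSums(!is.na(geno)) == n_individuals
  alt_total <- rowSums(geno)
  two_n <- 2L * n_individuals
  keep <- pileup_snps$n_alt_alleles == 1L & complete &
    !is.na(alt_total) & alt_total > 0L & alt_total < two_n
  out <- pileup_snps[keep, , drop = FALSE]
  geno <- geno[keep, , drop = FALSE]
  alt_total <- alt_total[keep]
  out$maf <- pmin(alt_total, two_n - alt_total) / two_n
  out$callers <- "pileup"
  if (nrow(out) > 0L && nrow(alignment_snps) > 0L) {
    akey <- paste(alignment_snps$gene_id, alignment_snps$pos)
    m <- match(paste(out$gene_id, out$pos), akey)
    confirmed <- !is.na(m) &
      mapply(function(i, ref, alt) {
        i_ok <- alignment_snps$major[i] %in% c(ref, alt) &&
          alignment_snps$minor[i] %in% c(ref, alt)
        i_ok
      }, m, out$ref, out$alt, USE.NAMES = FALSE) %in% TRUE
    out$callers[confirmed] <- "both"
  }
  ord <- order(out$gene_id, out$pos)
  out <- out[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  out$geno <- geno
  rownames(out) <- NULL
  out
}

#' Classify a coding substitution as synonymous or nonsynonymous
#'
#' Substitutes the alternative base into its codon (standard genetic code,
#' reading frame starting at `frame_offset`) and compares the encoded amino
#' acids. Stop gain/loss is nonsynonymous with the subtype noted. Positions
#' whose codon is incomplete or contains an ambiguous base classify as
#' `"unknown"`.
#'
#' @param pos 0-based position of the SNP within the coding sequence.
#' @param alt Alternative base.
#' @param reference_cds Reference coding sequence.
#' @param frame_offset 0-based offset of the first codon (default 0).
#' @return List with `effect` (`"synonymous"`, `"nonsynonymous"`,
#'   `"unknown"`), `subtype` (`NA`, `"stop_gain"`, `"stop_loss"`),
#'   `codon_ref`, `codon_alt`, `aa_ref`, `aa_alt`.
#' @export
classify_coding_effect <- function(pos, alt, reference_cds, frame_offset = 0L) {
  L <- nchar(reference_cds)
  if (pos < 0L || pos >= L) stop_input("pos outside the coding sequence")
  if (L < frame_offset + 3L) stop_input("coding sequence shorter than one codon")
  unknown <- list(effect = "unknown", subtype = NA_character_,
                  codon_ref = NA_character_, codon_alt = NA_character_,
                  aa_ref = NA_character_, aa_alt = NA_character_)
  if (pos < frame_offset) return(unknown)
  codon_idx <- (pos - frame_offset) %/% 3L
  start <- frame_offset + 3L * codon_idx        # 0-based codon start
  if (start + 3L > L) return(unknown)
  codon <- toupper(substring(reference_cds, start + 1L, start + 3L))
  within <- pos - start + 1L
  codon_alt <- codon
  substring(codon_alt, within, within) <- toupper(alt)
  gc <- Biostrings::GENETIC_CODE
  if (!(codon %in% names(gc)) || !(codon_alt %in% names(gc))) return(unknown)
  aa_ref <- unname(gc[[codon]])
  aa_alt <- unname(gc[[codon_alt]])
  if (aa_ref == aa_alt) {
    effect <- "synonymous"
    subtype <- NA_character_
  } else {
    effect <- "nonsynonymous"
    subtype <- if (aa_alt == "*") "stop_gain" else if (aa_ref == "*") "stop_loss" else NA_character_
  }
  list(effect = effect, subtype = subtype, codon_ref = codon,
       codon_alt = codon_alt, aa_ref = aa_ref, aa_alt = aa_alt)
}

#' Add coding-effect classifications to a SNP table
#'
#' @param snps SNP table with `gene_id`, `pos`, `alt`.
#' @param references Named character vector of reference coding sequences.
#' @param frame_offset Reading-frame offset shared by all genes.
#' @return `snps` with `effect` and `effect_subtype` columns appended.
#' @export
add_coding_effects <- function(snps, references, frame_offset = 0L) {
  eff <- character(nrow(snps))
  sub <- character(nrow(snps))
  for (i in seq_len(nrow(snps))) {
    ref <- references[[snps$gene_id[i]]]
    if (is.null(ref) || is.na(ref)) stop_input("no reference sequence for gene ",
                                               snps$gene_id[i])
    cl <- classify_coding_effect(snps$pos[i], snps$alt[i], ref, frame_offset)
    eff[i] <- cl$effect
    sub[i] <- cl$subtype
  }
  snps$effect <- eff
  snps$effect_subtype <- sub
  snps
}
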