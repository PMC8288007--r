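## Synthetic cohorts with known ground truth: the study design emulated is a
## 20-fish sample (10 seep / 10 control; sexes 6F+4M control, 4F+6M seep),
## negative-binomial expression counts with pH / sex / body-length effects,
## Hardy-Weinberg genotypes under a neutral or an intermediate-frequency-
## enriched allele-frequency spectrum, Poisson-coverage pileups with uniform
## sequencing error, and one collapsed haplotype transcript per individual.

#' Cohort configuration for the synthetic-data generator
#'
#' Defaults reproduce the study design: ten fish per site with sexes split
#' 6 female + 4 male at control and 4 female + 6 male at seeps.
#'
#' @param n_seep,n_control Number of individuals per site (> 0).
#' @param sex_split Named list `list(control = c(F =, M =), seep = c(F =, M =))`;
#'   each split must sum to its site size.
#' @param body_length_mean,body_length_sd Total body length distribution (mm);
#'   draws are truncated at zero.
#' @param seed Integer seed.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_seep = 10L, n_control = 10L,
                          sex_split = list(control = c(F = 6L, M = 4L),
                                           seep = c(F = 4L, M = 6L)),
                          body_length_mean = 55, body_length_sd = 6,
                          seed = 1L) {
  if (n_seep <= 0L || n_control <= 0L) {
    stop_input("group sizes must be positive (n_seep = ", n_seep,
               ", n_control = ", n_control, ")")
  }
  if (body_length_sd < 0) stop_input("body_length_sd must be >= 0")
  sizes <- c(control = n_control, seep = n_seep)
  for (site in names(sizes)) {
    sp <- sex_split[[site]]
    if (is.null(sp) || !all(c("F", "M") %in% names(sp))) {
      stop_input("sex_split must give F and M counts for site '", site, "'")
    }
    if (sum(sp[c("F", "M")]) != sizes[[site]]) {
      stop_input("sex split for site '", site, "' must sum to ", sizes[[site]])
    }
  }
  structure(list(n_seep = as.integer(n_seep), n_control = as.integer(n_control),
                 sex_split = sex_split, body_length_mean = body_length_mean,
                 body_length_sd = body_length_sd, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a cohort of individuals
#'
#' @param config A [cohort_config()].
#' @return Sample-sheet data frame with columns `individual_id`, `site`,
#'   `sex`, `body_length_mm`. Deterministic for a fixed seed.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    rows <- list()
    for (site in c("control", "seep")) {
      n <- if (site == "seep") config$n_seep else config$n_control
      sp <- config$sex_split[[site]]
      sexes <- c(rep("F", sp[["F"]]), rep("M", sp[["M"]]))
      len <- numeric(n)
      for (i in seq_len(n)) {
        repeat {
          l <- rnorm(1L, config$body_length_mean, config$body_length_sd)
          if (l > 0) break
        }
        len[i] <- l
      }
      rows[[site]] <- data.frame(
        individual_id = sprintf("%s_%02d", site, seq_len(n)),
        site = site, sex = sexes, body_length_mm = len,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}

#' Per-gene effect specification for the count simulator
#'
#' @param gene_id Gene identifiers.
#' @param baseline_mean Expected count at control/female/average-length (> 0).
#' @param dispersion Negative-binomial dispersion alpha (>= 0; 0 = Poisson).
#' @param log2fc_ph Log2 fold change of seep versus control.
#' @param log2fc_sex Log2 fold change of male versus female.
#' @param slope_length Per-mm effect on the log2 mean (applied to centred
#'   body length).
#' @param is_marker_female Flag for female-biased zona-pellucida-like marker
#'   genes; marker genes default to a strong female excess
#'   (`log2fc_sex = -7`, i.e. 128-fold) unless an explicit value is given.
#' @return Data frame of per-gene effects (the ground-truth table).
#' @export
gene_effects <- function(gene_id, baseline_mean = 100, dispersion = 0.3,
                         log2fc_ph = 0, log2fc_sex = NULL, slope_length = 0,
                         is_marker_female = FALSE) {
  n <- length(gene_id)
  if (anyDuplicated(gene_id)) stop_input("duplicate gene id(s)")
  df <- data.frame(gene_id = as.character(gene_id),
                   baseline_mean = rep_len(baseline_mean, n),
                   dispersion = rep_len(dispersion, n),
                   log2fc_ph = rep_len(log2fc_ph, n),
                   slope_length = rep_len(slope_length, n),
                   is_marker_female = rep_len(is_marker_female, n),
                   stringsAsFactors = FALSE)
  df$log2fc_sex <- if (is.null(log2fc_sex)) {
    ifelse(df$is_marker_female, -7, 0)
  } else rep_len(log2fc_sex, n)
  if (any(df$baseline_mean <= 0)) stop_input("baseline_mean must be > 0")
  if (any(df$dispersion < 0)) stop_input("dispersion must be >= 0")
  df[c("gene_id", "baseline_mean", "dispersion", "log2fc_ph", "log2fc_sex",
       "slope_length", "is_marker_female")]
}

#' Simulate a count matrix from per-gene effects
#'
#' The mean model is
#' `mu = baseline * 2^(log2fc_ph * I(seep) + log2fc_sex * I(male) +
#' slope_length * (length - mean length)) * depth_factor`,
#' with counts drawn negative-binomially at the gene's dispersion (Poisson
#' when the dispersion is zero). Per-individual depth factors (log-normal,
#' sdlog 0.15) emulate library-size variation and are recorded in the ground
#' truth.
#'
#' @param individuals Sample sheet as from [simulate_cohort()].
#' @param effects Effect table from [gene_effects()].
#' @param seed Integer seed.
#' @return List with `counts` (integer matrix genes x individuals) and
#'   `truth` (effects, depth factors, expected means).
#' @export
simulate_counts <- function(individuals, effects, seed = 1L) {
  if (nrow(effects) < 1L) stop_input("need at least one gene")
  if (nrow(individuals) < 2L) stop_input("need at least two individuals")
  if (any(effects$dispersion < 0)) stop_input("dispersion must be >= 0")
  with_seed(seed, {
    n <- nrow(individuals)
    seep <- as.numeric(individuals$site == "seep")
    male <- as.numeric(individuals$sex == "M")
    lenc <- individuals$body_length_mm - mean(individuals$body_length_mm)
    depth <- exp(rnorm(n, 0, 0.15))
    counts <- matrix(0L, nrow(effects), n,
                     dimnames = list(effects$gene_id, individuals$individual_id))
    mu_all <- matrix(0, nrow(effects), n, dimnames = dimnames(counts))
    for (g in seq_len(nrow(effects))) {
      e <- effects[g, ]
      mu <- e$baseline_mean *
        2^(e$log2fc_ph * seep + e$log2fc_sex * male + e$slope_length * lenc) *
        depth
      mu_all[g, ] <- mu
      counts[g, ] <- if (e$dispersion < 1e-12) {
        rpois(n, mu)
      } else {
        rnbinom(n, mu = mu, size = 1 / e$dispersion)
      }
    }
    list(counts = counts,
         truth = list(effects = effects,
                      depth_factors = setNames(depth, individuals$individual_id),
                      mu = mu_all))
  })
}

#' Allele-frequency spectrum specification
#'
#' `neutral` draws the minor-allele count class i (of 2N chromosomes) with
#' weight `1/i + 1/(2N - i)` (folded standard neutral expectation for a
#' constant-size population); `balanced` draws the allele frequency from a
#' symmetric `Beta(a, a)` with `a > 1`, which enriches intermediate
#' frequencies — the footprint of balancing selection.
#'
#' @param kind `"neutral"` or `"balanced"`.
#' @param n_snps Number of SNPs to plant (>= 0).
#' @param beta_shape Shape parameter of the balanced spectrum (default 5).
#' @return A `spectrum_spec` list.
#' @export
spectrum_spec <- function(kind = c("neutral", "balanced"), n_snps,
                          beta_shape = 5) {
  kind <- match.arg(kind)
  if (n_snps < 0L) stop_input("n_snps must be >= 0")
  if (kind == "balanced" && beta_shape <= 1) {
    stop_input("balanced spectrum requires beta_shape > 1")
  }
  structure(list(kind = kind, n_snps = as.integer(n_snps),
                 beta_shape = beta_shape), class = "spectrum_spec")
}

#' Simulate SNP genotypes for one gene under a spectrum specification
#'
#' Allele frequencies are drawn from the spectrum, then each individual's
#' genotype is drawn under Hardy-Weinberg equilibrium; a draw leaving the
#' sample monomorphic is rejected and redrawn, so every planted SNP
#' segregates in the sample. Positions are unique and uniform over the coding
#' sequence; the reference allele is the base of `reference_cds` at the
#' position and the alternative allele is uniform over the other three bases.
#'
#' @param gene_id Gene identifier.
#' @param spec A [spectrum_spec()].
#' @param n_individuals Number of diploid individuals (>= 2).
#' @param reference_cds Reference coding sequence (single character string).
#' @param seed Integer seed.
#' @param individual_ids Optional individual ids for the genotype columns.
#' @return Data frame with columns `gene_id`, `pos` (0-based), `ref`, `alt`,
#'   `true_freq` (population frequency of the alt allele) and a genotype
#'   dosage matrix column `geno` (0/1/2 alt copies per individual).
#' @export
simulate_genotypes <- function(gene_id, spec, n_individuals, reference_cds,
                               seed = 1L, individual_ids = NULL) {
  stopifnot(inherits(spec, "spectrum_spec"))
  if (n_individuals < 2L) stop_input("need >= 2 individuals")
  L <- nchar(reference_cds)
  if (spec$n_snps > L) {
    stop_input("n_snps (", spec$n_snps, ") exceeds CDS length (", L, ")")
  }
  ids <- individual_ids %||% sprintf("ind_%02d", seq_len(n_individuals))
  empty <- data.frame(gene_id = character(), pos = integer(),
                      ref = character(), alt = character(),
                      true_freq = numeric(), stringsAsFactors = FALSE)
  empty$geno <- matrix(integer(), 0L, n_individuals, dimnames = list(NULL, ids))
  if (spec$n_snps == 0L) return(empty)
  with_seed(seed, {
    pos <- sort(sample.int(L, spec$n_snps)) - 1L
    refs <- substring(reference_cds, pos + 1L, pos + 1L)
    bases <- c("A", "C", "G", "T")
    alts <- vapply(refs, function(r) sample(setdiff(bases, r), 1L), "")
    two_n <- 2L * n_individuals
    geno <- matrix(0L, spec$n_snps, n_individuals, dimnames = list(NULL, ids))
    freqs <- numeric(spec$n_snps)
    fold_classes <- seq_len(floor(two_n / 2))
    w <- 1 / fold_classes + 1 / (two_n - fold_classes)
    w[fold_classes == two_n - fold_classes] <-
      1 / fold_classes[fold_classes == two_n - fold_classes]
    for (s in seq_len(spec$n_snps)) {
      repeat {
        p <- if (spec$kind == "neutral") {
          i <- sample(fold_classes, 1L, prob = w)
          if (runif(1L) < 0.5) i / two_n else (two_n - i) / two_n
        } else {
          rbeta(1L, spec$beta_shape, spec$beta_shape)
        }
        g <- rbinom(n_individuals, 2L, p)
        tot <- sum(g)
        if (tot > 0L && tot < two_n) break
      }
      geno[s, ] <- g
      freqs[s] <- p
    }
    out <- data.frame(gene_id = gene_id, pos = pos, ref = unname(refs),
                      alt = unname(alts), true_freq = freqs,
                      stringsAsFactors = FALSE)
    out$geno <- geno
    out
  })
}

#' Simulate per-individual sequencing pileups over a coding sequence
#'
#' Depth is Poisson per position; at a heterozygous site each read carries
#' either allele with probability one half before error; a sequencing error
#' substitutes a read's base uniformly among the other three. Per-base
#' qualities are Normal(`qual_mean`, 3) clamped to `[2, 41]` and reported as
#' a per-position mean.
#'
#' @param genotypes Genotype table from [simulate_genotypes()].
#' @param reference_cds Reference coding sequence (single string).
#' @param coverage_mean Mean depth (> 0).
#' @param error_rate Per-base error probability (`0 <= e < 0.25`).
#' @param qual_mean Mean base quality.
#' @param seed Integer seed.
#' @return Named list (one element per individual) of pileups: each a list
#'   with `individual_id`, `gene_id`, `counts` (positions x A,C,G,T matrix)
#'   and `mean_qual`.
#' @export
simulate_pileups <- function(genotypes, reference_cds, coverage_mean = 50,
                             error_rate = 0.001, qual_mean = 35, seed = 1L) {
  if (coverage_mean <= 0) stop_input("coverage_mean must be > 0")
  if (error_rate < 0 || error_rate >= 0.25) {
    stop_input("error_rate must be in [0, 0.25)")
  }
  L <- nchar(reference_cds)
  bases <- c("A", "C", "G", "T")
  refv <- strsplit(toupper(reference_cds), "")[[1L]]
  ref_idx <- match(refv, bases)
  if (anyNA(ref_idx)) stop_input("reference contains a non-ACGT base")
  geno <- snp_genotypes(genotypes)
  ids <- colnames(geno)
  gene <- if (nrow(genotypes) > 0L) genotypes$gene_id[1L] else NA_character_
  with_seed(seed, {
    out <- vector("list", length(ids))
    names(out) <- ids
    for (j in seq_along(ids)) {
      depth <- rpois(L, coverage_mean)
      counts <- matrix(0L, L, 4L, dimnames = list(NULL, bases))
      ## true base composition before error: reference everywhere, overridden
      ## at planted SNP positions by the individual's genotype
      true_major <- ref_idx           # index of the dominant true base
      alt_reads <- integer(L)         # reads carrying a second true base
      alt_base <- integer(L)
      if (nrow(genotypes) > 0L) {
        p1 <- genotypes$pos + 1L
        ai <- match(genotypes$alt, bases)
        g <- geno[, j]
        hom_alt <- which(g == 2L)
        true_major[p1[hom_alt]] <- ai[hom_alt]
        het <- which(g == 1L)
        if (length(het)) {
          alt_base[p1[het]] <- ai[het]
          alt_reads[p1[het]] <- rbinom(length(het), depth[p1[het]], 0.5)
        }
      }
      major_reads <- depth - alt_reads
      counts[cbind(seq_len(L), true_major)] <- major_reads
      hetpos <- which(alt_reads > 0L)
      if (length(hetpos)) {
        idx <- cbind(hetpos, alt_base[hetpos])
        counts[idx] <- counts[idx] + alt_reads[hetpos]
      }
      if (error_rate > 0) {
        n_err <- rbinom(L, depth, error_rate)
        for (p in which(n_err > 0L)) {
          for (k in seq_len(n_err[p])) {
            ## pick an erroring read proportional to current true composition
            src <- sample.int(4L, 1L, prob = counts[p, ])
            dst <- sample(setdiff(1:4, src), 1L)
            counts[p, src] <- counts[p, src] - 1L
            counts[p, dst] <- counts[p, dst] + 1L
          }
        }
      }
      tot <- sum(depth)
      mq <- rep(NA_real_, L)
      if (tot > 0L) {
        q <- pmin(pmax(rnorm(tot, qual_mean, 3), 2), 41)
        sums <- rowsum(q, rep(seq_len(L), depth))
        pos_idx <- as.integer(rownames(sums))
        mq[pos_idx] <- sums[, 1L] / depth[pos_idx]
      }
      out[[j]] <- list(individual_id = ids[j], gene_id = gene,
                       counts = counts, mean_qual = mq)
    }
    out
  })
}

#' Emit one collapsed haplotype transcript per individual
#'
#' Models what a de novo assembler reports for a diploid individual: at each
#' heterozygous site one of the two alleles is chosen uniformly at random
#' (haplotype collapsing); homozygous sites emit the genotype allele.
#' Optionally each end of the transcript is truncated by a random 0-5% of the
#' sequence length to exercise free-end-gap alignment.
#'
#' @param genotypes Genotype table from [simulate_genotypes()].
#' @param reference_cds Reference coding sequence (single string).
#' @param seed Integer seed.
#' @param truncate Logically, randomly truncate both ends (default `FALSE`).
#' @return Named character vector: one sequence per individual.
#' @export
emit_haplotype_transcripts <- function(genotypes, reference_cds, seed = 1L,
                                       truncate = FALSE) {
  geno <- snp_genotypes(genotypes)
  ids <- colnames(geno)
  refv <- strsplit(toupper(reference_cds), "")[[1L]]
  L <- length(refv)
  with_seed(seed, {
    out <- character(length(ids))
    names(out) <- ids
    for (j in seq_along(ids)) {
      s <- refv
      if (nrow(genotypes) > 0L) {
        g <- geno[, j]
        p1 <- genotypes$pos + 1L
        s[p1[g == 2L]] <- genotypes$alt[g == 2L]
        het <- which(g == 1L)
        if (length(het)) {
          pick_alt <- runif(length(het)) < 0.5
          s[p1[het[pick_alt]]] <- genotypes$alt[het[pick_alt]]
        }
      }
      from <- 1L; to <- L
      if (truncate) {
        from <- 1L + floor(runif(1L, 0, 0.05) * L)
        to <- L - floor(runif(1L, 0, 0.05) * L)
      }
      out[j] <- paste(s[from:to], collapse = "")
    }
    out
  })
}

#' Simulate a protein-homology hit table with known merged truth
#'
#' Builds `n_transcripts / redundancy` anchor genes, each represented by
#' `redundancy` alternative transcripts hit in `n_ref_species` reference
#' species. One designated transcript per gene recovers the full reference
#' protein in the first species (100% coverage); the alternatives cover at
#' most 90%, so the ground-truth merged assembly is known by construction.
#'
#' @param n_transcripts Total transcripts (must be a multiple of `redundancy`).
#' @param n_ref_species Number of reference species (>= 1).
#' @param redundancy Alternative transcripts per gene (>= 1).
#' @param seed Integer seed.
#' @return List with `hits` (canonical hit table), `ortholog_map`
#'   (`ref_species`, `ref_protein_id`, `anchor_gene_id`) and `truth`
#'   (expected [merge_across_species()] output).
#' @export
simulate_hit_table <- function(n_transcripts, n_ref_species = 4L,
                               redundancy = 1L, seed = 1L) {
  if (n_ref_species < 1L) stop_input("n_ref_species must be >= 1")
  if (redundancy < 1L || n_transcripts %% redundancy != 0L) {
    stop_input("n_transcripts must be a positive multiple of redundancy")
  }
  n_genes <- n_transcripts %/% redundancy
  species <- sprintf("species_%d", seq_len(n_ref_species))
  samples <- sprintf("assembly_%d", 1:4)
  with_seed(seed, {
    rows <- vector("list", n_genes * n_ref_species * redundancy)
    k <- 0L
    truth <- data.frame(anchor_gene_id = sprintf("ANCH%04d", seq_len(n_genes)),
                        chosen_transcript_id = NA_character_,
                        n_species_support = n_ref_species,
                        pct_recovered = 100, stringsAsFactors = FALSE)
    omap <- expand.grid(ref_species = species,
                        gene = seq_len(n_genes), stringsAsFactors = FALSE)
    omap$ref_protein_id <- sprintf("%s_P%04d", omap$ref_species, omap$gene)
    omap$anchor_gene_id <- sprintf("ANCH%04d", omap$gene)
    omap <- omap[c("ref_species", "ref_protein_id", "anchor_gene_id")]
    for (g in seq_len(n_genes)) {
      tx <- sprintf("TR%04d_t%d", g, seq_len(redundancy))
      chosen <- sample(tx, 1L)
      truth$chosen_transcript_id[g] <- chosen
      slen <- sample(200:600, n_ref_species, replace = TRUE)
      for (sp in seq_len(n_ref_species)) {
        for (t in seq_len(redundancy)) {
          k <- k + 1L
          full <- tx[t] == chosen && sp == 1L
          aln <- if (full) slen[sp] else {
            max(1L, as.integer(floor(runif(1L, 0.40, 0.90) * slen[sp])))
          }
          rows[[k]] <- data.frame(
            query_transcript_id = tx[t],
            sample_id = sample(samples, 1L),
            ref_species = species[sp],
            ref_protein_id = sprintf("%s_P%04d", species[sp], g),
            evalue = 10^-runif(1L, 10, 60),
            pct_identity = runif(1L, 75, 99),
            ref_aln_length = aln,
            ref_protein_length = slen[sp],
            stringsAsFactors = FALSE)
        }
      }
    }
    hits <- do.call(rbind, rows)
    rownames(hits) <- NULL
    list(hits = hits, ortholog_map = omap, truth = truth)
  })
}
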