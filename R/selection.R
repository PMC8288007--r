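## Folded site-frequency spectra and the tests built on them. The folded
## spectrum (fSFS) records per-SNP minor-allele frequencies; balancing
## selection leaves an excess of intermediate frequencies relative to the
## neutral expectation, detected here with a one-sided two-sample
## Kolmogorov-Smirnov test on the raw MAF values.

#' Folded site-frequency spectrum of a SNP set
#'
#' Per SNP, the minor-allele frequency is `min(c, 2N - c) / 2N`, where `c`
#' counts alternative alleles over the chromosomes of the chosen individuals
#' (missing genotypes are excluded from the denominator). Sites monomorphic
#' within the chosen individuals carry no frequency information and are
#' dropped. The binned spectrum counts SNPs per minor-allele-count class
#' `1..N`.
#'
#' @param snps SNP table with genotype matrix (see [reconcile_and_filter()]),
#'   or a bare genotype dosage matrix (SNPs x individuals).
#' @param gene_set Optional gene ids to restrict to.
#' @param individuals Optional individual ids (or column indices) defining a
#'   subpopulation; all individuals by default.
#' @param label Label carried in the result.
#' @return Object of class `folded_sfs`: list with `label`, `maf` (per-SNP
#'   minor-allele frequencies in `(0, 0.5]`), `binned` (named counts over
#'   minor-count classes), `n_chromosomes`.
#' @export
folded_sfs <- function(snps, gene_set = NULL, individuals = NULL, label = "") {
  geno <- if (is.matrix(snps)) snps else snp_genotypes(snps)
  if (!is.matrix(snps) && !is.null(gene_set)) {
    geno <- geno[snps$gene_id %in% gene_set, , drop = FALSE]
  }
  if (!is.null(individuals)) geno <- geno[, individuals, drop = FALSE]
  two_n <- 2L * ncol(geno)
  called <- 2L * rowSums(!is.na(geno))
  alt <- rowSums(geno, na.rm = TRUE)
  minor <- pmin(alt, called - alt)
  keep <- called > 0L & minor > 0L
  maf <- minor[keep] / called[keep]
  classes <- seq_len(floor(two_n / 2))
  binned <- setNames(tabulate(minor[keep], nbins = max(classes)), classes)
  structure(list(label = label, maf = unname(maf), binned = binned,
                 n_chromosomes = two_n), class = "folded_sfs")
}

#' @export
print.folded_sfs <- function(x, ...) {
  cat("Folded SFS", if (nzchar(x$label)) paste0("'", x$label, "'"),
      "-", length(x$maf), "SNPs over", x$n_chromosomes, "chromosomes\n")
  cat("  mean MAF:", signif(mean(x$maf), 4),
      " intermediate (>= 0.30):", sum(x$maf >= 0.30), "\n")
  invisible(x)
}

#' One-sided two-sample Kolmogorov-Smirnov comparison of two spectra
#'
#' Tests whether spectrum `a` is stochastically greater than spectrum `b`
#' (i.e. `a`'s distribution function lies below `b`'s — `a` shifted toward
#' larger minor-allele frequencies). Computed on the raw per-SNP MAF values,
#' not the binned spectra. The exact p-value (which accommodates the heavy
#' ties of a 1/2N frequency grid) is used when `n_a * n_b` is at most
#' `exact_limit`; the asymptotic approximation otherwise.
#'
#' @param a,b `folded_sfs` objects (both non-empty).
#' @param exact_limit Size product below which the exact null distribution is
#'   enumerated (default `1e4`).
#' @return List with `label_a`, `label_b`, `d_statistic`, `p_value`,
#'   `alternative`.
#' @export
ks_compare <- function(a, b, exact_limit = 1e4) {
  stopifnot(inherits(a, "folded_sfs"), inherits(b, "folded_sfs"))
  if (length(a$maf) == 0L || length(b$maf) == 0L) {
    stop_input("cannot compare an empty spectrum")
  }
  exact <- length(a$maf) * length(b$maf) <= exact_limit
  kt <- suppressWarnings(
    ks.test(a$maf, b$maf, alternative = "less", exact = exact))
  list(label_a = a$label, label_b = b$label,
       d_statistic = unname(kt$statistic), p_value = kt$p.value,
       alternative = sprintf("'%s' stochastically greater than '%s'",
                             a$label, b$label))
}

#' Observed and expected heterozygosity of a SNP set
#'
#' Per SNP: observed heterozygosity is the fraction of heterozygous
#' individuals; expected heterozygosity is `2 p (1 - p)` with `p` the
#' minor-allele frequency. Set-level summaries are the means over SNPs.
#'
#' @param snps SNP table with complete genotypes.
#' @param gene_set Optional gene ids to restrict to.
#' @return List with `per_snp` (data frame `gene_id`, `pos`, `maf`,
#'   `observed`, `expected`) and `summary` (named means).
#' @export
heterozygosity <- function(snps, gene_set = NULL) {
  if (!is.null(gene_set)) snps <- snps[snps$gene_id %in% gene_set, , drop = FALSE]
  geno <- snp_genotypes(snps)
  called <- rowSums(!is.na(geno))
  het <- rowSums(geno == 1L, na.rm = TRUE)
  alt <- rowSums(geno, na.rm = TRUE)
  p <- pmin(alt, 2L * called - alt) / (2L * called)
  per_snp <- data.frame(gene_id = snps$gene_id, pos = snps$pos, maf = p,
                        observed = het / called, expected = 2 * p * (1 - p),
                        stringsAsFactors = FALSE)
  list(per_snp = per_snp,
       summary = c(mean_observed = mean(per_snp$observed),
                   mean_expected = mean(per_snp$expected)))
}

#' Seep-versus-control allele-frequency differentiation tests
#'
#' Per SNP, a 2x2 table of (site group) x (major/minor allele) chromosome
#' counts is tested with a two-sided Fisher exact test; sites monomorphic in
#' both groups take p = 1 by convention. Multiple testing is corrected to
#' q-values, by Benjamini-Hochberg (default) or Storey's lambda-grid
#' estimator of the null proportion.
#'
#' @param snps SNP table with complete genotypes.
#' @param samples Sample sheet giving each individual's site.
#' @param method `"BH"` or `"storey"`.
#' @return Data frame per SNP: `gene_id`, `pos`, minor-allele counts per
#'   group, `fisher_p`, `q_value`.
#' @export
allele_freq_tests <- function(snps, samples, method = c("BH", "storey")) {
  method <- match.arg(method)
  geno <- snp_genotypes(snps)
  idx <- match(colnames(geno), samples$individual_id)
  if (anyNA(idx)) {
    stop_input("individual(s) missing from the sample sheet: ",
               paste(colnames(geno)[is.na(idx)], collapse = ", "))
  }
  site <- samples$site[idx]
  p <- numeric(nrow(snps))
  cnt <- matrix(0L, nrow(snps), 4L,
                dimnames = list(NULL, c("minor_seep", "major_seep",
                                        "minor_control", "major_control")))
  ## orient the minor allele over the whole sample, consistently across groups
  for (i in seq_len(nrow(snps))) {
    g <- geno[i, ]
    alt_tot <- sum(g, na.rm = TRUE)
    chrom_tot <- 2L * sum(!is.na(g))
    minor_is_alt <- alt_tot <= chrom_tot - alt_tot
    for (grp in c("seep", "control")) {
      gg <- g[site == grp & !is.na(g)]
      altc <- sum(gg)
      tot <- 2L * length(gg)
      minc <- if (minor_is_alt) altc else tot - altc
      cnt[i, paste0("minor_", grp)] <- minc
      cnt[i, paste0("major_", grp)] <- tot - minc
    }
    tab <- matrix(cnt[i, ], 2L, 2L, byrow = TRUE)  # rows seep/control
    p[i] <- if (sum(tab[, 1L]) == 0L || sum(tab[, 2L]) == 0L) {
      1
    } else {
      fisher.test(tab)$p.value
    }
  }
  q <- if (method == "BH") p.adjust(p, "BH") else storey_qvalue(p)
  out <- data.frame(gene_id = snps$gene_id, pos = snps$pos,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(cnt))
  out$fisher_p <- p
  out$q_value <- q
  out
}

## Storey q-values: pi0 estimated on the lambda grid 0.05..0.95 with a cubic
## smoothing spline evaluated at the largest lambda, then the step-up
## transform of pi0 * p * m / rank. Falls back to pi0 = 1 (BH) when the
## estimate degenerates, which at small SNP counts it often does.
storey_qvalue <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  m <- length(p)
  if (m < 2L) return(pmin(p, 1))
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
  pi0 <- tryCatch({
    fit <- smooth.spline(lambda, pi0_l, df = 3)
    predict(fit, x = max(lambda))$y
  }, error = function(e) 1)
  pi0 <- min(max(pi0, 1e-8), 1)
  ord <- order(p, decreasing = TRUE)
  q <- numeric(m)
  running <- 1
  for (i in seq_along(ord)) {
    j <- ord[i]
    rank_j <- m - i + 1L
    running <- min(running, pi0 * p[j] * m / rank_j)
    q[j] <- running
  }
  q
}

#' Per-gene report of confirmed intermediate-frequency SNPs
#'
#' Counts, per gene, the SNPs at or above the intermediate-frequency
#' threshold that were confirmed by both callers, with their
#' synonymous/nonsynonymous breakdown; genes reaching `min_strong` such SNPs
#' are flagged as strong evidence of balancing selection.
#'
#' @param snps SNP table with `maf`, `callers` and (optionally) `effect`
#'   columns.
#' @param threshold Intermediate-frequency MAF threshold (default 0.30,
#'   inclusive).
#' @param min_strong Confirmed intermediate SNPs required for the strong-
#'   evidence flag (default 3).
#' @return Data frame per gene: `gene_id`, `n_intermediate`, `n_synonymous`,
#'   `n_nonsynonymous`, `strong_evidence`.
#' @export
intermediate_snp_report <- function(snps, threshold = 0.30, min_strong = 3L) {
  genes <- sort(unique(snps$gene_id))
  conf <- snps$callers == "both" & snps$maf >= threshold
  eff <- if (is.null(snps$effect)) rep(NA_character_, nrow(snps)) else snps$effect
  out <- data.frame(gene_id = genes, n_intermediate = 0L,
                    n_synonymous = 0L, n_nonsynonymous = 0L,
                    strong_evidence = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    sel <- conf & snps$gene_id == genes[i]
    out$n_intermediate[i] <- sum(sel)
    out$n_synonymous[i] <- sum(sel & eff %in% "synonymous")
    out$n_nonsynonymous[i] <- sum(sel & eff %in% "nonsynonymous")
  }
  out$strong_evidence <- out$n_intermediate >= min_strong
  out
}
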