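## Functional keywords: GO-term enrichment of the up-regulated set, mapping
## GO ids to the eleven functional keywords and six main functions, and the
## construction of the neutral reference gene set used by the selection tests.

#' Assign functional keywords and main-function flags to genes
#'
#' A gene's keyword set is the image of its GO annotations under the
#' GO-to-keyword map; main-function flags are derived through the
#' keyword-to-main-function column of the map. GO ids absent from the map are
#' ignored (they are counted in the `"coverage"` attribute, not errors);
#' genes whose keyword set comes out empty are flagged unannotated.
#'
#' @param go_map Named list mapping gene id to GO ids (see [read_go_map()]).
#' @param keyword_map Data frame `go_id`, `keyword`, `main_function`
#'   (see [read_keyword_map()]).
#' @return Data frame with `gene_id`, `keywords` (comma-joined), `annotated`,
#'   and one logical column per main function. Attribute `"coverage"` holds
#'   the fraction of GO annotations that mapped to a keyword.
#' @export
assign_keywords <- function(go_map, keyword_map) {
  genes <- names(go_map)
  fns <- main_functions()
  out <- data.frame(gene_id = genes, keywords = "", annotated = FALSE,
                    stringsAsFactors = FALSE)
  for (fn in fns) out[[fn]] <- FALSE
  n_go <- 0L
  n_mapped <- 0L
  for (i in seq_along(go_map)) {
    gos <- go_map[[i]]
    n_go <- n_go + length(gos)
    hit <- match(gos, keyword_map$go_id)
    hit <- hit[!is.na(hit)]
    n_mapped <- n_mapped + length(hit)
    if (length(hit) == 0L) next
    kws <- sort(unique(keyword_map$keyword[hit]))
    out$keywords[i] <- paste(kws, collapse = ",")
    out$annotated[i] <- TRUE
    for (fn in unique(keyword_map$main_function[hit])) out[[fn]][i] <- TRUE
  }
  attr(out, "coverage") <- if (n_go > 0L) n_mapped / n_go else NA_real_
  out
}

#' Count genes per main functional category
#'
#' Aggregates the six main-function flags of a gene table (either the
#' packaged up-regulated gene table or [assign_keywords()] output).
#'
#' @param flags Data frame carrying one logical column per main function.
#' @return Named integer vector of per-function gene counts, plus
#'   `n_genes` and `n_annotated` (genes with at least one flag).
#' @export
main_function_counts <- function(flags) {
  fns <- main_functions()
  miss <- setdiff(fns, names(flags))
  if (length(miss)) stop_input("missing flag column(s): ", paste(miss, collapse = ", "))
  counts <- vapply(fns, function(fn) sum(flags[[fn]]), 0L)
  any_flag <- Reduce(`|`, lapply(fns, function(fn) flags[[fn]]))
  c(counts, n_genes = nrow(flags), n_annotated = sum(any_flag))
}

#' GO-term enrichment of a gene set by Fisher's exact test
#'
#' For every GO term annotated to at least one gene of the set, builds the
#' 2x2 table (in set / not in set) x (has term / lacks term) over the
#' annotation universe and applies a two-sided Fisher exact test; p-values
#' are Bonferroni-corrected over the terms tested.
#'
#' @param set_genes Character vector of gene ids (must be a subset of the
#'   universe).
#' @param genome_annotation Named list mapping every universe gene id to its
#'   GO ids.
#' @return Data frame with one row per tested term: `go_id`, `n_in_set`,
#'   `n_set`, `n_in_genome`, `n_genome`, `odds_ratio`, `p`, `p_bonf`,
#'   ordered by `p`.
#' @export
enrich <- function(set_genes, genome_annotation) {
  universe <- names(genome_annotation)
  outside <- setdiff(set_genes, universe)
  if (length(outside)) {
    stop_input("gene(s) absent from the annotation universe: ",
               paste(head(outside, 5L), collapse = ", "))
  }
  empty <- data.frame(go_id = character(), n_in_set = integer(),
                      n_set = integer(), n_in_genome = integer(),
                      n_genome = integer(), odds_ratio = numeric(),
                      p = numeric(), p_bonf = numeric(), stringsAsFactors = FALSE)
  if (length(set_genes) == 0L) return(empty)
  in_set <- universe %in% set_genes
  long_gene <- rep(seq_along(genome_annotation),
                   lengths(genome_annotation))
  long_go <- unlist(genome_annotation, use.names = FALSE)
  terms <- sort(unique(long_go[in_set[long_gene]]))
  if (length(terms) == 0L) return(empty)
  n_set <- length(set_genes)
  n_genome <- length(universe)
  rows <- lapply(terms, function(term) {
    has <- unique(long_gene[long_go == term])
    n_in_genome <- length(has)
    n_in_set <- sum(in_set[has])
    tab <- matrix(c(n_in_set, n_set - n_in_set,
                    n_in_genome - n_in_set,
                    n_genome - n_set - (n_in_genome - n_in_set)), 2L, 2L)
    ft <- fisher.test(tab)
    data.frame(go_id = term, n_in_set = n_in_set, n_set = n_set,
               n_in_genome = n_in_genome, n_genome = n_genome,
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonf <- pmin(1, out$p * nrow(out))
  out <- out[order(out$p, out$go_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the neutral reference gene set
#'
#' A gene enters the neutral set when it shows no evidence of differential
#' expression in either single-factor Wald contrast (sex and pH, raw p >
#' `p_cutoff`) and carries none of the functional keywords of the
#' up-regulated set.
#'
#' @param wald Data frame from [wald_contrasts()] (`gene_id`, `wald_p_sex`,
#'   `wald_p_ph`).
#' @param keyword_flags Data frame from [assign_keywords()]; genes absent
#'   from it are treated as keyword-free.
#' @param p_cutoff Wald p-value threshold (default 0.05).
#' @return Sorted character vector of neutral gene ids.
#' @export
select_neutral_genes <- function(wald, keyword_flags = NULL, p_cutoff = 0.05) {
  keep <- !is.na(wald$wald_p_sex) & !is.na(wald$wald_p_ph) &
    wald$wald_p_sex > p_cutoff & wald$wald_p_ph > p_cutoff
  ids <- wald$gene_id[keep]
  if (!is.null(keyword_flags)) {
    flagged <- keyword_flags$gene_id[keyword_flags$annotated]
    ids <- setdiff(ids, flagged)
  }
  sort(ids)
}
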