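## Transcript deduplication by protein homology: filter hits, keep the best
## transcript per reference protein, then merge across reference species onto
## a single anchor-species ortholog id. Mirrors a multi-assembly, multi-
## reference BLASTp post-processing chain.

#' Filter homology hits at the significance and identity cutoffs
#'
#' Retains hits with e-value strictly below `max_evalue` and percent identity
#' strictly above `min_identity`.
#'
#' @param hits Canonical hit table (see [read_hits()]).
#' @param max_evalue E-value cutoff (default `1e-6`).
#' @param min_identity Percent-identity cutoff (default 70).
#' @return Filtered hit table.
#' @export
filter_hits <- function(hits, max_evalue = 1e-6, min_identity = 70) {
  keep <- hits$evalue < max_evalue & hits$pct_identity > min_identity
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep the best transcript per reference protein
#'
#' Within each (reference species, reference protein) group, the retained hit
#' is the one whose alignment covers the greatest length of the reference
#' protein; ties are broken by higher percent identity, then lower e-value,
#' then lexicographically smaller transcript id, making the result
#' order-independent.
#'
#' @param hits Filtered canonical hit table.
#' @return One-row-per-(species, protein) hit table.
#' @export
best_per_reference <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$ref_species, hits$ref_protein_id,
               -hits$ref_aln_length, -hits$pct_identity, hits$evalue,
               hits$query_transcript_id)
  sorted <- hits[ord, , drop = FALSE]
  key <- paste(sorted$ref_species, sorted$ref_protein_id, sep = "\r")
  out <- sorted[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge best hits across reference species onto anchor-gene models
#'
#' Each retained (species, protein) hit is mapped through the ortholog map to
#' an anchor-species gene id. Per anchor gene, the chosen transcript is the
#' one with the maximal recovered fraction of a reference protein
#' (`100 * ref_aln_length / ref_protein_length`), with the same tie-breaking
#' chain as [best_per_reference()]; `n_species_support` counts the distinct
#' reference species contributing at least one retained hit. Hits whose
#' (species, protein) is absent from the map are not silently dropped: they
#' are collected in the `"unanchored"` attribute of the result.
#'
#' @param best_hits Output of [best_per_reference()].
#' @param ortholog_map Data frame with columns `ref_species`,
#'   `ref_protein_id`, `anchor_gene_id`.
#' @return Gene-model data frame (`anchor_gene_id`, `chosen_transcript_id`,
#'   `n_species_support`, `pct_recovered`), ordered by anchor id, with an
#'   `"unanchored"` attribute holding unmapped hits.
#' @export
merge_across_species <- function(best_hits, ortholog_map) {
  empty <- data.frame(anchor_gene_id = character(),
                      chosen_transcript_id = character(),
                      n_species_support = integer(),
                      pct_recovered = numeric(), stringsAsFactors = FALSE)
  if (nrow(best_hits) == 0L) {
    attr(empty, "unanchored") <- best_hits
    return(empty)
  }
  key <- paste(best_hits$ref_species, best_hits$ref_protein_id, sep = "\r")
  mkey <- paste(ortholog_map$ref_species, ortholog_map$ref_protein_id, sep = "\r")
  anchor <- ortholog_map$anchor_gene_id[match(key, mkey)]
  unanchored <- best_hits[is.na(anchor), , drop = FALSE]
  rownames(unanchored) <- NULL
  hits <- best_hits[!is.na(anchor), , drop = FALSE]
  anchor <- anchor[!is.na(anchor)]
  if (nrow(hits) == 0L) {
    attr(empty, "unanchored") <- unanchored
    return(empty)
  }
  hits$pct_recovered <- 100 * hits$ref_aln_length / hits$ref_protein_length
  ord <- order(anchor, -hits$pct_recovered, -hits$pct_identity, hits$evalue,
               hits$query_transcript_id)
  hits <- hits[ord, , drop = FALSE]
  anchor <- anchor[ord]
  first <- !duplicated(anchor)
  out <- data.frame(
    anchor_gene_id = anchor[first],
    chosen_transcript_id = hits$query_transcript_id[first],
    n_species_support = as.integer(
      tapply(hits$ref_species, anchor, function(s) length(unique(s)))[anchor[first]]),
    pct_recovered = hits$pct_recovered[first],
    stringsAsFactors = FALSE)
  out <- out[order(out$anchor_gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unanchored") <- unanchored
  out
}
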