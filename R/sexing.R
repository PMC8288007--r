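## Expression-based sexing. Zona-pellucida (egg envelope) genes are strongly
## female-biased in gonad tissue; summing their normalised expression gives a
## bimodal score that separates females (high) from males (low).

#' Per-individual marker expression scores
#'
#' @param counts Integer count matrix (genes x individuals).
#' @param marker_ids Ids of the marker (zp-like) genes; all must be rows of
#'   `counts`.
#' @param sf Per-individual size factors; computed with [size_factors()] when
#'   omitted.
#' @return Data frame with columns `individual_id` and `score` (sum of
#'   normalised counts over the marker genes).
#' @export
marker_scores <- function(counts, marker_ids, sf = NULL) {
  missing_ids <- setdiff(marker_ids, rownames(counts))
  if (length(missing_ids)) {
    stop_input("marker gene(s) absent from the count matrix: ",
               paste(missing_ids, collapse = ", "))
  }
  sf <- sf %||% size_factors(counts)
  norm <- sweep(counts[marker_ids, , drop = FALSE], 2L, sf, "/")
  data.frame(individual_id = colnames(counts), score = colSums(norm),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify individuals as female or male from marker scores
#'
#' Scores are ranked on the log10(score + 1) scale and split at the largest
#' gap; the high group is labelled `F`, the low group `M`. The separation is
#' the ratio of the geometric means of (score + 1) in the two groups; when it
#' falls below `min_separation` (or all scores are equal) the classification
#' is ambiguous and every label is returned as `"unknown"`.
#'
#' @param scores Data frame from [marker_scores()].
#' @param min_separation Minimum high/low geometric-mean ratio required for a
#'   confident call (default 10, one order of magnitude).
#' @return List with `assignments` (data frame `individual_id`, `sex`,
#'   `score`), `separation` (the ratio), and `status`
#'   (`"ok"` or `"ambiguous"`).
#' @export
classify_sex <- function(scores, min_separation = 10) {
  if (nrow(scores) < 2L) stop_input("need >= 2 individuals to classify")
  ls <- log10(scores$score + 1)
  ord <- order(ls)
  sorted <- ls[ord]
  gaps <- diff(sorted)
  out <- scores
  if (all(gaps == 0)) {
    out$sex <- "unknown"
    return(list(assignments = out[c("individual_id", "sex", "score")],
                separation = 1, status = "ambiguous"))
  }
  cut <- which.max(gaps)  # split between sorted[cut] and sorted[cut + 1]
  low <- ord[seq_len(cut)]
  high <- ord[seq(cut + 1L, length(ls))]
  separation <- 10^(mean(ls[high]) - mean(ls[low]))
  if (separation < min_separation) {
    out$sex <- "unknown"
    status <- "ambiguous"
    warning("marker-score separation (", signif(separation, 3),
            ") below min_separation; sexes returned as unknown", call. = FALSE)
  } else {
    out$sex <- ifelse(seq_len(nrow(out)) %in% high, "F", "M")
    status <- "ok"
  }
  list(assignments = out[c("individual_id", "sex", "score")],
       separation = separation, status = status)
}
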