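## Readers and writers for the plain-text formats the pipeline touches.
## All readers validate and reject malformed input with file/line coordinates;
## every write->read round trip is an identity.

#' Read a FASTA file of coding or transcript sequences
#'
#' Sequences are upper-cased and RNA `U` is normalised to `T`. Record ids are
#' the first whitespace-delimited token of the header line.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_input("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  if (anyDuplicated(ids)) {
    stop_input("duplicate sequence id(s) in ", path, ": ",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(nchar(seqs) == 0L)) {
    stop_input("empty sequence(s) in ", path, ": ",
               paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop_input("all sequences must be named")
  }
  if (anyDuplicated(names(seqs))) {
    stop_input("duplicate sequence id(s): ",
               paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  seqs <- toupper(gsub("U", "T", seqs, fixed = TRUE))
  if (any(nchar(seqs) == 0L)) stop_input("refusing to write empty sequence(s)")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a gene x individual count matrix
#'
#' Tab-separated with a header row; first column holds gene ids, remaining
#' columns one individual each. Counts must be non-negative integers; any
#' violation is reported with its gene/individual coordinates.
#'
#' @param path Path to the TSV file.
#' @return Integer matrix with gene rownames and individual colnames.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop_input("counts file not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_input(path, ": need a gene id column plus >=1 individual")
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) stop_input(path, ": duplicate gene id(s)")
  m <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(apply(m, 2L, as.numeric))
  num <- matrix(num, nrow = nrow(df), dimnames = list(genes, colnames(df)[-1L]))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop_input(path, ": invalid count '", m[bad[1L, 1L], bad[1L, 2L]],
               "' at gene '", genes[bad[1L, 1L]], "', individual '",
               colnames(num)[bad[1L, 2L]], "'")
  }
  storage.mode(num) <- "integer"
  num
}

#' Write a count matrix as TSV
#' @param counts Integer matrix, genes x individuals.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the sample sheet describing the cohort
#'
#' Expected columns: `individual_id`, `site` (one of `seep`, `control`),
#' `sex` (`F`, `M`, or `unknown`) and `body_length_mm` (> 0).
#'
#' @param path Path to the TSV file.
#' @return Validated data frame.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop_input("sample sheet not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "site", "sex", "body_length_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_input(path, ": missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$individual_id)) {
    stop_input(path, ": duplicate individual id(s)")
  }
  bad <- which(!df$site %in% c("seep", "control"))
  if (length(bad)) {
    stop_input(path, ", row ", bad[1L], ": unknown site label '", df$site[bad[1L]],
               "' (expected 'seep' or 'control')")
  }
  bad <- which(!df$sex %in% c("F", "M", "unknown"))
  if (length(bad)) {
    stop_input(path, ", row ", bad[1L], ": unknown sex label '", df$sex[bad[1L]], "'")
  }
  if (any(!is.finite(df$body_length_mm)) || any(df$body_length_mm <= 0)) {
    stop_input(path, ": body_length_mm must be positive and finite")
  }
  df[need]
}

#' Write a sample sheet as TSV
#' @param samples Sample-sheet data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Canonical hit-table columns used throughout the homology module.
hit_columns <- c("query_transcript_id", "sample_id", "ref_species",
                 "ref_protein_id", "evalue", "pct_identity",
                 "ref_aln_length", "ref_protein_length")

#' Read a protein-homology hit table
#'
#' The file is a 15-column tab-separated dialect of tabular BLAST output
#' (`-outfmt 6`) with two leading metadata columns and a trailing subject
#' length: `sample_id`, `ref_species`, then the standard twelve
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`), then `slen` (reference protein length in residues).
#' A header row is required. The reference-aligned length is taken as
#' `send - sstart + 1`.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `query_transcript_id`, `sample_id`,
#'   `ref_species`, `ref_protein_id`, `evalue`, `pct_identity`,
#'   `ref_aln_length`, `ref_protein_length`.
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) stop_input("hit table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) != 15L) {
    stop_input(path, ": expected 15 columns (sample_id, ref_species, 12 tabular-",
               "BLAST columns, slen), found ", ncol(df))
  }
  names(df) <- c("sample_id", "ref_species", "qseqid", "sseqid", "pident",
                 "length", "mismatch", "gapopen", "qstart", "qend",
                 "sstart", "send", "evalue", "bitscore", "slen")
  out <- data.frame(
    query_transcript_id = as.character(df$qseqid),
    sample_id = as.character(df$sample_id),
    ref_species = as.character(df$ref_species),
    ref_protein_id = as.character(df$sseqid),
    evalue = as.numeric(df$evalue),
    pct_identity = as.numeric(df$pident),
    ref_aln_length = as.integer(df$send - df$sstart + 1L),
    ref_protein_length = as.integer(df$slen),
    stringsAsFactors = FALSE
  )
  validate_hits(out, path)
  out
}

validate_hits <- function(hits, where = "hit table") {
  bad <- which(hits$pct_identity < 0 | hits$pct_identity > 100)
  if (length(bad)) stop_input(where, ", row ", bad[1L], ": pct_identity outside [0, 100]")
  bad <- which(hits$evalue < 0)
  if (length(bad)) stop_input(where, ", row ", bad[1L], ": negative e-value")
  bad <- which(hits$ref_aln_length > hits$ref_protein_length | hits$ref_aln_length < 1L)
  if (length(bad)) {
    stop_input(where, ", row ", bad[1L],
               ": ref_aln_length must be in [1, ref_protein_length]")
  }
  invisible(hits)
}

#' Write a hit table in the 15-column dialect read by [read_hits()]
#'
#' Fields not represented in the canonical form (mismatch, gap counts, query
#' coordinates, bitscore) are written as zeros; alignment coordinates are
#' written as `sstart = 1`, `send = ref_aln_length`.
#'
#' @param hits Canonical hit data frame (see [read_hits()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  df <- data.frame(
    sample_id = hits$sample_id, ref_species = hits$ref_species,
    qseqid = hits$query_transcript_id, sseqid = hits$ref_protein_id,
    pident = hits$pct_identity, length = hits$ref_aln_length,
    mismatch = 0L, gapopen = 0L, qstart = 1L, qend = hits$ref_aln_length,
    sstart = 1L, send = hits$ref_aln_length, evalue = hits$evalue,
    bitscore = 0, slen = hits$ref_protein_length, stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-to-GO annotation map
#'
#' Tab-separated with header columns `gene_id` and `go_ids`
#' (comma-separated GO identifiers; empty for unannotated genes).
#'
#' @param path Path to the TSV file.
#' @return Named list mapping gene id to a character vector of GO ids.
#' @export
read_go_map <- function(path) {
  if (!file.exists(path)) stop_input("GO map not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "go_ids") %in% names(df))) {
    stop_input(path, ": expected columns gene_id, go_ids")
  }
  if (anyDuplicated(df$gene_id)) stop_input(path, ": duplicate gene id(s)")
  out <- lapply(df$go_ids, function(s) {
    v <- trimws(strsplit(as.character(s), ",", fixed = TRUE)[[1L]])
    v[nzchar(v)]
  })
  names(out) <- df$gene_id
  out
}

#' Read the GO-to-keyword / keyword-to-main-function map
#'
#' Tab-separated with header columns `go_id`, `keyword`, `main_function`.
#' The eleven functional keywords must map onto the six main functions
#' (`homeostasis`, `energy_production`, `protein_production`,
#' `protein_binding`, `actin`, `signal_transduction`).
#'
#' @param path Path to the TSV file; defaults to the fixture shipped with the
#'   package.
#' @return Data frame with columns `go_id`, `keyword`, `main_function`.
#' @export
read_keyword_map <- function(path = system.file("extdata", "go_keyword_map.tsv",
                                                package = "seepselect")) {
  if (!file.exists(path)) stop_input("keyword map not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("go_id", "keyword", "main_function") %in% names(df))) {
    stop_input(path, ": expected columns go_id, keyword, main_function")
  }
  bad <- which(!df$main_function %in% main_functions())
  if (length(bad)) {
    stop_input(path, ", row ", bad[1L], ": unknown main function '",
               df$main_function[bad[1L]], "'")
  }
  if (anyDuplicated(df$go_id)) stop_input(path, ": duplicate go_id row(s)")
  df
}

#' The six main functional categories of seep-up-regulated genes
#' @return Character vector of category labels.
#' @export
main_functions <- function() {
  c("homeostasis", "energy_production", "protein_production",
    "protein_binding", "actin", "signal_transduction")
}

#' Read the packaged table of up-regulated genes
#'
#' A machine-readable transcription of the published list of 66 genes
#' up-regulated at CO2 seeps: stickleback ortholog id, gene name, number of
#' supporting reference species (1-4), percent of the reference protein
#' recovered, and one logical flag per main functional category.
#'
#' @param path Path to the TSV; defaults to the packaged fixture.
#' @return Data frame with one row per up-regulated gene.
#' @export
read_upregulated_table <- function(path = system.file(
                                     "extdata", "upregulated_genes_table.tsv",
                                     package = "seepselect")) {
  if (!file.exists(path)) stop_input("up-regulated gene table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("ortholog_gene_id", "gene_name", "n_species", "pct_recovered",
            main_functions())
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_input(path, ": missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$ortholog_gene_id)) stop_input(path, ": duplicate gene id(s)")
  if (any(df$n_species < 1L | df$n_species > 4L)) {
    stop_input(path, ": n_species must be within 1..4")
  }
  if (any(df$pct_recovered <= 0 | df$pct_recovered > 100)) {
    stop_input(path, ": pct_recovered must be within (0, 100]")
  }
  for (fn in main_functions()) df[[fn]] <- as.logical(df[[fn]])
  df[need]
}

#' Write a SNP table
#'
#' Serialises reconciled SNPs as a VCF-like TSV: `gene_id`, `pos` (1-based
#' within the coding sequence), `ref`, `alt`, `maf`, `callers`, then one
#' genotype column per individual (`0/0`, `0/1`, `1/1`, or `./.`). Rows are
#' sorted by (gene, pos) regardless of insertion order.
#'
#' @param snps SNP table as returned by [reconcile_and_filter()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_table <- function(snps, path) {
  geno <- snp_genotypes(snps)
  tok <- matrix("./.", nrow(geno), ncol(geno), dimnames = dimnames(geno))
  tok[!is.na(geno) & geno == 0L] <- "0/0"
  tok[!is.na(geno) & geno == 1L] <- "0/1"
  tok[!is.na(geno) & geno == 2L] <- "1/1"
  df <- data.frame(gene_id = snps$gene_id, pos = snps$pos + 1L,
                   ref = snps$ref, alt = snps$alt,
                   maf = snps$maf, callers = snps$callers,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(tok, stringsAsFactors = FALSE))
  df <- df[order(df$gene_id, df$pos), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SNP table written by [write_snp_table()]
#'
#' @param path Path to the TSV file.
#' @return SNP data frame with 0-based `pos` and a genotype matrix in the
#'   `geno` column (alt-allele dosage 0/1/2, `NA` for missing).
#' @export
read_snp_table <- function(path) {
  if (!file.exists(path)) stop_input("SNP table not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  fixed <- c("gene_id", "pos", "ref", "alt", "maf", "callers")
  miss <- setdiff(fixed, names(df))
  if (length(miss)) stop_input(path, ": missing column(s): ", paste(miss, collapse = ", "))
  ind <- setdiff(names(df), fixed)
  tok <- as.matrix(df[, ind, drop = FALSE])
  geno <- matrix(NA_integer_, nrow(tok), ncol(tok), dimnames = list(NULL, ind))
  geno[tok == "0/0"] <- 0L
  geno[tok == "0/1"] <- 1L
  geno[tok == "1/1"] <- 2L
  bad <- which(matrix(!(tok %in% c("0/0", "0/1", "1/1", "./.")), nrow(tok)),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop_input(path, ", data row ", bad[1L, 1L], ": invalid genotype token '",
               tok[bad[1L, 1L], bad[1L, 2L]], "'")
  }
  out <- df[fixed]
  out$pos <- as.integer(out$pos) - 1L
  out$geno <- geno
  out
}

## Accessor: genotype dosage matrix of a SNP table (rows = SNPs).
snp_genotypes <- function(snps) {
  if (is.null(snps$geno)) stop_input("SNP table has no genotype matrix")
  snps$geno
}
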