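## End-to-end orchestration: build (or load) a data set, then run sexing,
## homology merging, differential expression, keyword annotation, dual-route
## SNP calling and the selection tests, writing every intermediate table and
## a manifest that records seed, thresholds and content hashes.

#' Run configuration
#'
#' Collects every tunable threshold of the pipeline with the conventional
#' defaults: caller thresholds as in [caller_params()], differential
#' expression called at BH-adjusted p < 0.05, neutral-set Wald cutoff 0.05,
#' intermediate-frequency MAF threshold 0.30.
#'
#' @param seed Integer seed governing every random draw.
#' @param outdir Output directory (created if absent).
#' @param scenario Scenario parameter list from [scenario_params()], used
#'   when no input paths are given.
#' @param inputs Optional named list of input paths (`counts`,
#'   `sample_sheet`, ...); `NULL` runs the synthetic scenario.
#' @param caller A [caller_params()].
#' @param de_alpha Adjusted-p threshold for differential expression.
#' @param neutral_p Wald p cutoff for the neutral set.
#' @param maf_threshold Intermediate-frequency threshold.
#' @param qvalue_method `"BH"` or `"storey"` for the allele-frequency tests.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, outdir = tempfile("seepselect_run_"),
                       scenario = scenario_params(), inputs = NULL,
                       caller = caller_params(), de_alpha = 0.05,
                       neutral_p = 0.05, maf_threshold = 0.30,
                       qvalue_method = "BH") {
  structure(list(seed = as.integer(seed), outdir = outdir,
                 scenario = scenario, inputs = inputs, caller = caller,
                 de_alpha = de_alpha, neutral_p = neutral_p,
                 maf_threshold = maf_threshold,
                 qvalue_method = qvalue_method),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognised top-level keys mirror the [run_config()] arguments; `caller`
#' and `scenario` may be nested maps of the respective parameter names.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  y <- yaml::read_yaml(path)
  cfg <- run_config()
  for (k in intersect(names(y), c("seed", "outdir", "de_alpha", "neutral_p",
                                  "maf_threshold", "qvalue_method", "inputs"))) {
    cfg[[k]] <- y[[k]]
  }
  if (!is.null(y$caller)) cfg$caller <- do.call(caller_params, y$caller)
  if (!is.null(y$scenario)) cfg$scenario <- do.call(scenario_params, y$scenario)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Parameters of the default synthetic scenario
#'
#' The scenario emulates the study conditions: a 20-fish cohort (10 seep /
#' 10 control, sexes 6F+4M control and 4F+6M seep), strongly female-biased
#' marker genes, a block of genes up-regulated at seeps, null background
#' genes, and SNPs planted under a balanced (intermediate-frequency-enriched)
#' spectrum in the candidate genes versus the neutral spectrum elsewhere.
#'
#' @param n_marker Marker (zp-like) genes.
#' @param n_up Genes up-regulated at seeps.
#' @param n_null Null background genes.
#' @param log2fc_up Log2 fold change of the up-regulated genes.
#' @param dispersion NB dispersion shared by non-marker genes.
#' @param baseline_mean Baseline expression mean.
#' @param cds_length Coding-sequence length per variant-bearing gene.
#' @param snps_per_gene Planted SNPs per variant-bearing gene.
#' @param coverage_mean,error_rate,qual_mean Pileup simulation settings.
#' @param beta_shape Balanced-spectrum shape.
#' @return Parameter list.
#' @export
scenario_params <- function(n_marker = 3L, n_up = 8L, n_null = 30L,
                            log2fc_up = 2, dispersion = 0.3,
                            baseline_mean = 150, cds_length = 300L,
                            snps_per_gene = 8L, coverage_mean = 50,
                            error_rate = 0.002, qual_mean = 35,
                            beta_shape = 5) {
  as.list(environment())
}

## Random coding sequence starting with ATG and free of premature stops.
random_cds <- function(length) {
  stopifnot(length %% 3L == 0L, length >= 6L)
  codons <- setdiff(names(Biostrings::GENETIC_CODE),
                    names(which(Biostrings::GENETIC_CODE == "*")))
  body <- sample(codons, length %/% 3L - 1L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""))
}

#' Build a complete synthetic data set with ground truth
#'
#' @param seed Integer seed.
#' @param params [scenario_params()].
#' @return List with `samples` (true sexes), `counts`, `references` (named
#'   CDS vector for variant-bearing genes), `genotypes`, `pileups`,
#'   `transcripts` (per-gene lists), `go_map`, `keyword_map`, `marker_ids`,
#'   and `truth` (effect table, candidate/neutral gene ids, genotype tables).
#' @export
synthio_scenario <- function(seed = 1L, params = scenario_params()) {
  cohort <- simulate_cohort(cohort_config(seed = seed))
  p <- params
  ids <- list(marker = sprintf("zp_marker_%02d", seq_len(p$n_marker)),
              up = sprintf("cand_%03d", seq_len(p$n_up)),
              null = sprintf("null_%03d", seq_len(p$n_null)))
  effects <- gene_effects(
    gene_id = unlist(ids),
    baseline_mean = p$baseline_mean,
    dispersion = p$dispersion,
    log2fc_ph = c(rep(0, p$n_marker), rep(p$log2fc_up, p$n_up), rep(0, p$n_null)),
    is_marker_female = c(rep(TRUE, p$n_marker),
                         rep(FALSE, p$n_up + p$n_null)))
  sim <- simulate_counts(cohort, effects, seed = seed + 1L)
  variant_genes <- c(ids$up, ids$null)
  references <- setNames(character(length(variant_genes)), variant_genes)
  genotypes <- list()
  pileups <- list()
  transcripts <- list()
  with_seed(seed + 2L, {
    for (g in variant_genes) references[g] <- random_cds(p$cds_length)
  })
  for (k in seq_along(variant_genes)) {
    g <- variant_genes[k]
    kind <- if (g %in% ids$up) "balanced" else "neutral"
    spec <- spectrum_spec(kind, p$snps_per_gene, beta_shape = p$beta_shape)
    genotypes[[g]] <- simulate_genotypes(
      g, spec, nrow(cohort), references[g], seed = seed + 10L + k,
      individual_ids = cohort$individual_id)
    pileups[[g]] <- simulate_pileups(
      genotypes[[g]], references[g], coverage_mean = p$coverage_mean,
      error_rate = p$error_rate, qual_mean = p$qual_mean,
      seed = seed + 1000L + k)
    transcripts[[g]] <- emit_haplotype_transcripts(
      genotypes[[g]], references[g], seed = seed + 2000L + k)
  }
  ## GO annotations: candidate genes carry mapped terms, null genes carry an
  ## unmapped placeholder term so the neutral filter is exercised
  kw <- read_keyword_map()
  go_map <- c(
    setNames(lapply(seq_along(ids$up), function(i) {
      kw$go_id[1L + (i - 1L) %% nrow(kw)]
    }), ids$up),
    setNames(rep(list("GO:0000000"), p$n_null), ids$null))
  list(samples = cohort, counts = sim$counts, references = references,
       genotypes = genotypes, pileups = pileups, transcripts = transcripts,
       go_map = go_map, keyword_map = kw, marker_ids = ids$marker,
       truth = list(effects = sim$truth$effects,
                    depth_factors = sim$truth$depth_factors,
                    candidate_genes = ids$up, neutral_genes = ids$null,
                    genotypes = genotypes))
}

#' Run the full pipeline
#'
#' Executes simulate/ingest, sexing, homology merging, differential
#' expression, keyword annotation, dual-route SNP calling and the selection
#' tests, writing every intermediate table under `config$outdir` together
#' with a YAML manifest (package version, seed, thresholds, md5 per output).
#' A stage failure aborts with the failing stage named; tables already
#' written are retained.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly; results are also returned in the
#'   `results` attribute.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$inputs)) {
    for (f in unlist(config$inputs)) {
      if (!file.exists(f)) stop_input("input file not found: ", f)
    }
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  emit <- function(obj, name, writer = write.table) {
    path <- file.path(config$outdir, name)
    if (identical(writer, write.table)) {
      write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      writer(obj, path)
    }
    outputs <<- c(outputs, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_input("stage '", name, "' failed: ", conditionMessage(e))
    })
  }
  res <- list()

  scen <- stage("ingest", {
    if (is.null(config$inputs)) {
      synthio_scenario(config$seed, config$scenario)
    } else {
      load_inputs(config$inputs)
    }
  })
  emit(scen$samples, "sample_sheet.tsv")
  emit(scen$counts, "counts.tsv", write_counts)

  res$sexing <- stage("sexing", {
    sf <- size_factors(scen$counts)
    cls <- classify_sex(marker_scores(scen$counts, scen$marker_ids, sf))
    cls$size_factors <- sf
    cls
  })
  emit(res$sexing$assignments, "sex_assignments.tsv")
  samples <- scen$samples
  if (res$sexing$status == "ok") {
    samples$sex <- res$sexing$assignments$sex[
      match(samples$individual_id, res$sexing$assignments$individual_id)]
  }

  if (!is.null(scen$hits)) {
    res$homology <- stage("homology", {
      merge_across_species(best_per_reference(filter_hits(scen$hits)),
                           scen$ortholog_map)
    })
    emit(res$homology, "gene_models.tsv")
  }

  res$de <- stage("expression", {
    sf <- res$sexing$size_factors
    list(lrt = lrt_ph(scen$counts, samples, sf),
         wald = wald_contrasts(scen$counts, samples, sf),
         overall = overall_expression_tests(scen$counts, samples, sf = sf))
  })
  emit(res$de$lrt, "de_results.tsv")
  emit(res$de$wald, "wald_contrasts.tsv")
  emit(res$de$overall$ancova, "ancova.tsv")

  res$funckey <- stage("funckey", {
    flags <- assign_keywords(scen$go_map, scen$keyword_map)
    up <- res$de$lrt$gene_id[!is.na(res$de$lrt$adj_p) &
                               res$de$lrt$adj_p < config$de_alpha &
                               res$de$lrt$direction == "up_in_seep"]
    neutral <- select_neutral_genes(res$de$wald, flags, config$neutral_p)
    neutral <- setdiff(neutral, c(up, scen$marker_ids))
    list(flags = flags, upregulated = up, neutral = neutral)
  })
  emit(res$funckey$flags[setdiff(names(res$funckey$flags), "keywords")],
       "keyword_flags.tsv")
  writeLines(res$funckey$upregulated,
             file.path(config$outdir, "upregulated_genes.txt"))
  writeLines(res$funckey$neutral,
             file.path(config$outdir, "neutral_genes.txt"))
  outputs <- c(outputs, file.path(config$outdir, "upregulated_genes.txt"),
               file.path(config$outdir, "neutral_genes.txt"))

  res$snps <- stage("variants", {
    genes <- names(scen$pileups)
    pu <- list()
    al <- list()
    for (g in genes) {
      pu[[g]] <- pileup_call(scen$pileups[[g]], scen$references[[g]],
                             config$caller)
      proj <- lapply(scen$transcripts[[g]], anchor_align,
                     reference_cds = scen$references[[g]])
      ok <- vapply(proj, `[[`, TRUE, "alignable")
      cc <- column_call(lapply(proj[ok], `[[`, "projection"))
      if (nrow(cc) > 0L) cc$gene_id <- g
      al[[g]] <- cc
    }
    pu_all <- do.call(rbind, lapply(pu, function(x) {
      x$geno <- NULL
      x
    }))
    rownames(pu_all) <- NULL
    pu_all$geno <- do.call(rbind, lapply(pu, snp_genotypes))
    al_all <- do.call(rbind, Filter(function(x) nrow(x) > 0L, al))
    if (is.null(al_all)) {
      al_all <- data.frame(gene_id = character(), pos = integer(),
                           major = character(), minor = character())
    }
    snps <- reconcile_and_filter(pu_all, al_all, nrow(scen$samples))
    add_coding_effects(snps, scen$references)
  })
  emit(res$snps, "snps.tsv", write_snp_table)

  res$selection <- stage("selection", {
    cand_genes <- intersect(res$funckey$upregulated, unique(res$snps$gene_id))
    neut_genes <- intersect(res$funckey$neutral, unique(res$snps$gene_id))
    sfs_c <- folded_sfs(res$snps, cand_genes, label = "candidate")
    sfs_n <- folded_sfs(res$snps, neut_genes, label = "neutral")
    ks <- if (length(sfs_c$maf) && length(sfs_n$maf)) {
      ks_compare(sfs_c, sfs_n)
    } else NULL
    seep_ids <- scen$samples$individual_id[scen$samples$site == "seep"]
    ctrl_ids <- scen$samples$individual_id[scen$samples$site == "control"]
    sfs_seep <- folded_sfs(res$snps, cand_genes, seep_ids, "candidate_seep")
    sfs_ctrl <- folded_sfs(res$snps, cand_genes, ctrl_ids, "candidate_control")
    ks_site <- if (length(sfs_seep$maf) && length(sfs_ctrl$maf)) {
      ks_compare(sfs_seep, sfs_ctrl)
    } else NULL
    cand_snps <- res$snps[res$snps$gene_id %in% cand_genes, , drop = FALSE]
    aft <- if (nrow(cand_snps)) {
      allele_freq_tests(cand_snps, scen$samples, config$qvalue_method)
    } else NULL
    list(sfs = list(candidate = sfs_c, neutral = sfs_n,
                    candidate_seep = sfs_seep, candidate_control = sfs_ctrl),
         ks = ks, ks_site = ks_site,
         heterozygosity = list(candidate = heterozygosity(res$snps, cand_genes),
                               neutral = heterozygosity(res$snps, neut_genes)),
         allele_freq = aft,
         intermediate = intermediate_snp_report(res$snps,
                                                config$maf_threshold))
  })
  if (!is.null(res$selection$allele_freq)) {
    emit(res$selection$allele_freq, "allele_freq_tests.tsv")
  }
  emit(res$selection$intermediate, "intermediate_snp_report.tsv")
  ks_rows <- do.call(rbind, lapply(
    Filter(Negate(is.null), res$selection[c("ks", "ks_site")]),
    function(k) data.frame(label_a = k$label_a, label_b = k$label_b,
                           d = k$d_statistic, p = k$p_value)))
  if (!is.null(ks_rows)) emit(ks_rows, "ks_tests.tsv")

  manifest <- list(
    package = "seepselect",
    version = as.character(utils::packageVersion("seepselect")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    thresholds = list(caller = unclass(config$caller),
                      de_alpha = config$de_alpha,
                      neutral_p = config$neutral_p,
                      maf_threshold = config$maf_threshold,
                      qvalue_method = config$qvalue_method),
    outputs = as.list(setNames(unname(tools::md5sum(outputs)),
                               basename(outputs))))
  yaml::write_yaml(manifest, file.path(config$outdir, "manifest.yaml"))
  attr(manifest, "results") <- res
  invisible(manifest)
}

## Assemble a scenario-shaped input list from files on disk.
load_inputs <- function(inputs) {
  need <- c("counts", "sample_sheet")
  miss <- setdiff(need, names(inputs))
  if (length(miss)) stop_input("missing input path(s): ", paste(miss, collapse = ", "))
  scen <- list(counts = read_counts(inputs$counts),
               samples = read_sample_sheet(inputs$sample_sheet),
               marker_ids = inputs$marker_ids %||% character(),
               go_map = if (!is.null(inputs$go_map)) read_go_map(inputs$go_map) else list(),
               keyword_map = read_keyword_map(inputs$keyword_map %||%
                                                system.file("extdata", "go_keyword_map.tsv",
                                                            package = "seepselect")),
               references = if (!is.null(inputs$references)) read_fasta(inputs$references) else NULL,
               hits = if (!is.null(inputs$hits)) read_hits(inputs$hits) else NULL,
               ortholog_map = if (!is.null(inputs$ortholog_map)) {
                 read.delim(inputs$ortholog_map, stringsAsFactors = FALSE)
               } else NULL,
               pileups = list(), transcripts = list(), genotypes = list())
  scen
}
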