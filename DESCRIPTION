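Package: seepselect
Title: Balancing-Selection Signatures in Genes Up-Regulated at Natural CO2 Seeps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect adaptive (balancing) selection acting on genes
    up-regulated in fish populations living at volcanic CO2 seeps, using only
    RNA-seq derived inputs. The pipeline spans ortholog-anchored transcript
    deduplication from tabular protein-homology hits, expression-based sexing
    via zona-pellucida marker genes, per-gene negative-binomial GLM
    likelihood-ratio tests for differential expression with sex and body-length
    covariates, construction of a neutral reference gene set, dual-route SNP
    calling (pileup thresholding and reference-anchored alignment column
    counting), folded site-frequency-spectrum comparison by one-sided
    two-sample Kolmogorov-Smirnov tests, heterozygosity summaries, and
    seep-versus-control allele-frequency differentiation tests. A synthetic
    cohort generator with known ground truth (Hardy-Weinberg genotypes under
    neutral or intermediate-frequency-enriched spectra, negative-binomial
    counts, sequencing-like pileups, haplotype transcripts) makes every stage
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    car,
    stats,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    jsonlite,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
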