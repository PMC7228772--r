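#!/usr/bin/env Rscript
# Stage 2: normalize counts to read percentages and compute gene-level
# fold-change enrichment over the mean mock-IP background.

suppressPackageStartupMessages(library(phipdiscover))

fix <- "results/fixtures"
counts <- read_count_matrix(file.path(fix, "counts.tsv"))
lib <- read_peptide_library(file.path(fix, "library.tsv"))
samples <- read_sample_sheet(file.path(fix, "samples.csv"))

enr <- enrichment_pipeline(counts, lib, samples)
write_enrichment(enr$gene, "results/gene_fold_change.tsv")
write_enrichment(enr$tile, "results/tile_fold_change.tsv")

cat("Enrichment over", sum(samples$role == "mock"), "mock-IPs;",
    "pseudocount =", signif(enr$gene$epsilon, 3), "% (one read at median",
    "mock depth)\n")
top <- sort(apply(enr$gene$fold, 1, max), decreasing = TRUE)[1:10]
cat("Top genes by maximal per-sample fold-change:\n")
print(round(top, 1))
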