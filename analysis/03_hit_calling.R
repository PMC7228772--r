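#!/usr/bin/env Rscript
# Stage 3: per-sample positivity (>= 10-fold over mock), candidate
# antigens at the case/control criteria, known/novel partition,
# frequency ranking, and the clustered z-score matrix.

suppressPackageStartupMessages(library(phipdiscover))

fix <- "results/fixtures"
counts <- read_count_matrix(file.path(fix, "counts.tsv"))
lib <- read_peptide_library(file.path(fix, "library.tsv"))
samples <- read_sample_sheet(file.path(fix, "samples.csv"))
truth <- read.delim(file.path(fix, "truth.tsv"))

enr <- enrichment_pipeline(counts, lib, samples)
pos <- call_positive_genes(enr$gene, threshold = 10)

cand2 <- candidate_antigens(pos, samples, min_cases = 2)  # known-antigen rule
cand3 <- candidate_antigens(pos, samples, min_cases = 3)  # novel-antigen rule
parts <- cross_reference_known(cand3, default_known_antigens())
ranking <- rank_by_frequency(pos, samples)

cand3$known_flag <- cand3$gene %in% default_known_antigens()
write.table(cand3, "results/candidates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(ranking, "results/ranking.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

planted <- unique(truth$antigen)
cat(sprintf("Candidates at >=2 cases / 0 controls: %d\n", nrow(cand2)))
cat(sprintf("Candidates at >=3 cases / 0 controls: %d (%d known, %d novel)\n",
            nrow(cand3), length(parts$known), length(parts$novel)))
cat(sprintf("Planted antigens recovered: %d/%d; false positives: %d\n",
            sum(planted %in% cand3$gene), length(planted),
            sum(!cand3$gene %in% planted)))

if (nrow(cand3) >= 2) {
  cl <- zscore_and_cluster(enr$gene, cand3$gene)
  zt <- data.frame(gene = rownames(cl$z), cl$z, check.names = FALSE)
  write.table(zt, "results/zscores.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(c(paste(cl$row_order, collapse = "\t"),
               paste(cl$col_order, collapse = "\t")),
             "results/cluster_orders.tsv")
  cat("Clustered z-score matrix written (",
      nrow(cl$z), "genes x", ncol(cl$z), "samples )\n")
}
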