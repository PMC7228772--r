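#!/usr/bin/env Rscript
# Stage 6: orthogonal radioligand binding assay statistics for the two
# antigens with simulated plates: antibody indices, 3-SD positivity
# cutoffs from the control sera, case/control Mann-Whitney tests,
# cross-assay correlation with PhIP-Seq enrichment, and dual-antigen
# concordance.

suppressPackageStartupMessages(library(phipdiscover))

fix <- "results/fixtures"
counts <- read_count_matrix(file.path(fix, "counts.tsv"))
lib <- read_peptide_library(file.path(fix, "library.tsv"))
samples <- read_sample_sheet(file.path(fix, "samples.csv"))
rlba <- read_rlba_table(file.path(fix, "rlba.csv"))

enr <- enrichment_pipeline(counts, lib, samples)
idx <- antibody_index_table(rlba)
roles <- setNames(samples$role, samples$sample_id)

out <- NULL
for (g in unique(idx$antigen)) {
  d <- idx[idx$antigen == g, ]
  iv <- setNames(d$index, d$sample_id)
  ctrl <- iv[roles[names(iv)] == "control"]
  call <- positivity_call(iv, ctrl, k_sd = 3)
  sera <- names(iv)[roles[names(iv)] %in% c("case", "control")]
  gd <- group_difference(iv[sera], roles[sera])
  r <- correlate_assays(iv, enr$gene$fold[g, ])
  cat(sprintf(
    "%s: cutoff %.3f, %d/%d cases positive, MW p = %.3g, Pearson r = %.2f\n",
    g, call$cutoff, sum(call$positive[roles[names(iv)] == "case"]),
    sum(roles[names(iv)] == "case"), gd$p, r))
  out <- rbind(out, data.frame(antigen = g, sample_id = names(iv),
                               index = unname(iv), cutoff = call$cutoff,
                               positive = unname(call$positive)))
}
write.table(out, "results/rlba_indices.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

ags <- unique(idx$antigen)
if (length(ags) >= 2) {
  flags <- lapply(ags[1:2], function(g) {
    d <- idx[idx$antigen == g, ]
    iv <- setNames(d$index, d$sample_id)
    cases <- names(iv)[roles[names(iv)] == "case"]
    positivity_call(iv[cases], iv[roles[names(iv)] == "control"], 3)$positive
  })
  cc <- concordance(flags[[1]], flags[[2]])
  cat(sprintf("Concordance of %s and %s positivity across cases: %.0f%%\n",
              ags[1], ags[2], 100 * cc$concordance))
}
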