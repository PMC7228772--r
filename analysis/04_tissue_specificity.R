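#!/usr/bin/env Rscript
# Stage 4: are the candidate antigens more tissue-restricted than chance?
# For each gene the specificity ratio is max tissue expression / summed
# expression; the observed mean over candidates is compared with 10,000
# resampled gene sets of the same size.

suppressPackageStartupMessages(library(phipdiscover))

fix <- "results/fixtures"
expr <- read_expression_matrix(file.path(fix, "expression.tsv"))
cand <- read.delim("results/candidates.tsv")

res <- resampling_enrichment_test(cand$gene, expr, n_iter = 10000L,
                                  seed = 42L)
print(res)
jsonlite::write_json(
  list(observed_mean_ratio = res$observed_mean_ratio,
       fold_vs_null = res$fold_vs_null, empirical_p = res$empirical_p,
       n_iter = res$n_iter, seed = res$seed,
       dropped_genes = res$dropped_genes),
  "results/tissue_specificity.json", auto_unbox = TRUE, digits = NA)
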