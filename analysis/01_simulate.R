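#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study the rest of the workflow analyzes.
#
# The study mirrors the cohort design the package defaults encode:
# 39 case sera, 28 non-case controls, 17 mock-IPs, 200 genes tiled into
# 49-residue peptides (25-residue overlap), 10 planted autoantigens with
# net enrichment factor 50 in 5-15 cases each, three phenotypes linked to
# the first three antigens, and RLBA plates for the first two antigens.

suppressPackageStartupMessages(library(phipdiscover))

fix_dir <- "results/fixtures"
paths <- make_fixtures(fix_dir, scale = "paper", seed = 1L)

truth <- read.delim(file.path(fix_dir, "truth.tsv"))
cat("Wrote synthetic study to", fix_dir, "\n")
cat("  planted antigens:",
    paste(unique(truth$antigen), collapse = ", "), "\n")
cat("  reactive (antigen, serum) pairs:",
    nrow(unique(truth[c("antigen", "sample_id")])), "\n")
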