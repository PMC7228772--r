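Package: phipdiscover
Title: Proteome-Wide Autoantigen Discovery from PhIP-Seq Serology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for phage immunoprecipitation sequencing
    (PhIP-Seq) autoantibody screens: normalization of peptide-level phage
    counts to read percentages, peptide- and gene-level fold-change
    enrichment over mock-IP background, per-sample positivity and
    case/control candidate-antigen calling, tissue-specificity resampling
    tests against consensus RNA expression, Kolmogorov-Smirnov association
    of enrichments with clinical phenotypes (with directional masking), and
    radioligand binding assay (RLBA) antibody-index statistics. Includes a
    fully seeded synthetic-data generator (tiled peptide library, multinomial
    sequencing counts over log-normal phage abundance, planted antigen
    reactivities, linked phenotypes, tissue-restricted expression, RLBA
    plates) so the whole pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
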