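---
title: "Methods: PhIP-Seq autoantigen discovery with phipdiscover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PhIP-Seq autoantigen discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phipdiscover)
```

## The measurement and the model

PhIP-Seq quantifies serum antibody reactivity against a tiled proteome:
each phage clone displays one 49-residue peptide, adjacent peptides
overlap by 25 residues (a 24-residue step, with the final tile anchored
to the protein's C-terminus so that every tile keeps the full display
length), and sequencing the immunoprecipitated phage yields a
peptide-by-sample count matrix. Three facts shape the analysis:

1. Raw counts reflect sequencing depth; we therefore work on the
   *percentage of reads per sample*, which removes depth exactly
   (columns sum to 100).
2. Phage libraries are far from uniform — abundant clones dominate the
   background even without serum. Reactivity is therefore measured as
   fold-change over *mock immunoprecipitations* (beads, no serum), using
   the mean mock percentage per peptide/gene as the background (median
   available as an option).
3. Single-sample positives are unreliable; the screen's unit of evidence
   is a gene positive (fold ≥ 10, boundary inclusive) in several case
   sera and in *zero* control sera.

Gene-level read percentage is the **sum** of the gene's member-tile
percentages. Summing reads naturally as "the gene's share of the
sample's reads", preserves the column-sum partition property, and
accumulates evidence from polyclonal responses hitting several tiles; a
`max` mode (best single tile) is provided for sensitivity analysis.

### The pseudocount

Mock backgrounds can be exactly zero for rare clones, which would make
fold-changes infinite. Both numerator and denominator therefore receive
a pseudocount ε equal to the percentage equivalent of **one read at the
median mock sequencing depth** (`100 / median mock column total`). This
has two desirable effects: folds stay finite, and folds computed from a
handful of reads are shrunk toward 1 rather than exploding. With a
positive background and ε → 0 the statistic is scale-free (doubling all
percentages changes nothing).

## Hit calling and display

Candidates require ≥ `min_cases` positive cases and ≤ 0 positive
controls; mocks never count, and validation-cohort samples are excluded
from discovery criteria via the sample sheet's `cohort` field. Two
thresholds are used in practice: 2 cases when cross-referencing
literature-reported antigens, 3 when nominating novel ones. Candidate
sets are monotone (nested) in both `min_cases` and the fold threshold —
a property the test suite checks.

For heatmap display, gene rows are z-scored across samples using the
sample (n−1) standard deviation and clustered with distance
1 − Pearson correlation, average linkage (complete linkage available).
Zero-variance rows cannot be z-scored or correlated; they are flagged,
set to zero, and placed last. All tie-breaks (candidate ordering,
frequency ranking) are alphabetical on the gene symbol so outputs are
byte-reproducible.

## Tissue restriction

A gene's specificity ratio is its maximum single-tissue expression
divided by its summed expression over all tissues (1 = fully
restricted, ≈ 1/n_tissues = broad). To ask whether a hit set is more
restricted than chance we compare its mean ratio with the mean ratios
of random gene sets of the same size, drawn uniformly without
replacement from all genes with nonzero total expression — hits are not
excluded from the pool, and no expression-level filter beyond
nonzero total is applied. The one-sided empirical p-value uses the
add-one estimator `(1 + #{null ≥ observed}) / (n_iter + 1)` (so p is
never 0 and is honest at finite iteration counts); the default is
10,000 iterations. Hit genes missing from the expression matrix are
excluded from both the observed mean and the null set size, and are
reported rather than silently dropped.

## Phenotype association

Each candidate gene's enrichment values are compared between cases with
and without each clinical manifestation using the two-sample
Kolmogorov–Smirnov test. KS depends only on the pooled ranks, so the
choice of fold vs log-fold is immaterial. The exact null distribution is
used when `n_with × n_without ≤ 10,000` (via R's `psmirnov`), the
asymptotic approximation otherwise; groups smaller than 3 (after
dropping missing phenotype values pairwise) yield a missing entry rather
than an unstable p-value. Direction is the with-group mean minus the
without-group mean; significant results in the protective direction
(direction ≤ 0, p < 0.05) are *masked* to p = 1, because an antibody
that is lower in affected individuals cannot support the antigen as a
driver of that manifestation. Raw p-values are reported by default;
Benjamini–Hochberg adjustment is available by flag. Phenotypes flagged
sex-specific (e.g. ovarian insufficiency) restrict the tested population
to the relevant sex when sample sex is recorded.

## RLBA statistics

The radioligand binding assay immunoprecipitates a ³⁵S-labeled
full-length protein; the antibody index calibrates each serum's counts
per minute between the plate's blanks (index 0) and the positive-control
antibody (index 1). Replicate wells are averaged *before* the index
formula. Positivity uses mean + k·SD of the control indices (sample SD,
strict inequality at the cutoff), k = 3 by default with per-antigen
overrides (k = 6 for antigens whose control background is so quiet that
3 SD is overly permissive). Negative indices are retained — they only
matter relative to cutoffs. Group differences use the two-sided
Mann–Whitney U test, cross-assay agreement uses Pearson correlation on
paired samples, and dual-antigen agreement is the fraction of samples
with equal flags plus the 2×2 table.

## The synthetic-study generator

Every stage is validated against simulated studies with planted ground
truth. The generator emulates, per sample, a multinomial draw of
`reads_per_sample` reads over per-tile weights:

- a **log-normal base abundance** per tile, drawn once and shared by all
  samples (it models library composition; log-normal is the standard
  heavy-tailed choice and produces realistic dropout at finite depth);
- a **net multiplicative enrichment factor** applied to epitope tiles in
  reactive case sera. The bench protocol's two sequential IP rounds are
  deliberately collapsed into this single net factor: the pipeline
  consumes post-protocol counts, so only the net enrichment is
  identifiable.

Mock samples never receive enrichment. Phenotypes are Bernoulli given
reactivity (penetrance for reactive cases, background rate otherwise);
expression matrices make planted antigens tissue-restricted (≥ 90% of
mass in one tissue) against near-uniform broad genes over 74 tissues;
RLBA plates follow the affine latent-reactivity model with Gaussian well
noise floored at 0. Synthetic amino-acid sequences are uniform-random —
sequence content is never used downstream, only coordinates.

Default study conditions mirror the cohort design the analysis criteria
were built for: **39 cases, 28 controls, 17 mock-IPs**, depth 10⁶ reads,
200 genes (~8 tiles each), 10 planted antigens with net factor 50 in
5–15 cases each, half of each antigen's tiles as epitopes. Where no
published value exists (abundance log-SD 1, epitope fraction 0.5, factor
50, linked-phenotype penetrance 0.9 over background 0.05), values were
chosen once as field-plausible and are exposed in
`simulation_config()` rather than tuned.

What the simulations do **not** emulate: sequencing error and alignment
ambiguity (the count matrix is the interface), epitope chemistry or
conformational antibodies (linear-tile reactivity only),
antibody-affinity kinetics across IP rounds, batch effects, and shared
cross-reactivity between related proteins. Passing tests therefore show
the *statistics* behave as specified under a realistic count-generating
process, not that the screen's biological sensitivity on real sera is
any particular number.

## Numerical choices and degenerate inputs

- Zero-read samples raise an error naming the sample; they are never
  silently NaN.
- Unannotated tiles and epitope tiles missing from the library raise
  listing errors.
- Empirical p-values use add-one estimators; seeds are explicit
  arguments everywhere and identical (config, seed) pairs give
  bit-identical outputs, including the end-to-end report payloads.
- Problem sizes in the shipped tests and acceptance runs: 20-seed
  recovery experiments at the 39/28/17 × 200-gene scale, 1000-replicate
  calibration of the resampling test at 1000 iterations each, and
  1000-draw KS null calibration — sizes chosen to give stable binomial
  checks (3-SD bands) at interactive runtimes.

## Known limitations

The gene-level "sum of percentages" convention and the pseudocount rule
are declared package choices where common practice varies; both
alternatives (`max` aggregation, user-supplied ε) are exposed. The
clustering linkage and the z-score axis likewise vary across published
heatmaps; defaults are declared, not inferred. The tissue-restriction
null samples genes uniformly, not matched on expression level or
protein length; strong global correlates of restriction could inflate
fold-vs-null for hit sets biased in those covariates.
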