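#' Simulation configuration for a synthetic PhIP-Seq study
#'
#' Bundles and validates the knobs of the synthetic-study generator. The
#' defaults mirror the design of a typical rare-disease serology cohort:
#' 39 case sera, 28 non-case control sera, and 17 mock immunoprecipitations
#' (beads only, no serum) that define the background; 200 genes tiled into
#' 49-residue peptides; 10 planted autoantigens, each strongly enriched
#' (net factor 50) in at least 5 case sera.
#'
#' @param n_cases,n_controls,n_mock Cohort sizes.
#' @param reads_per_sample Sequencing depth per sample (total reads).
#' @param abundance_logmean,abundance_logsd Parameters of the log-normal
#'   phage base-abundance distribution (one abundance per tile, shared by
#'   all samples: it models library composition, which antibodies then
#'   perturb).
#' @param n_genes Number of genes in the synthetic proteome.
#' @param tiles_per_gene_target Average tiles per gene; protein lengths are
#'   drawn so that tiling yields roughly this many tiles.
#' @param n_planted Number of planted autoantigens.
#' @param enrichment_factor Net multiplicative phage enrichment applied to a
#'   reactive tile in a reactive sample (the two sequential IP rounds are
#'   modeled as this single net factor).
#' @param epitope_fraction Fraction of an antigen's tiles that are reactive
#'   (its epitopes), in (0, 1].
#' @param reactive_cases_range Integer range; each planted antigen is
#'   reactive in a number of case sera drawn uniformly from this range.
#' @param seed Integer master seed; every downstream draw derives from it.
#' @return A list of class `phip_sim_config`.
#' @export
simulation_config <- function(n_cases = 39L, n_controls = 28L, n_mock = 17L,
                              reads_per_sample = 1e6,
                              abundance_logmean = 0, abundance_logsd = 1,
                              n_genes = 200L, tiles_per_gene_target = 8L,
                              n_planted = 10L, enrichment_factor = 50,
                              epitope_fraction = 0.5,
                              reactive_cases_range = c(5L, 15L),
                              seed = 1L) {
  cfg <- list(n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              n_mock = as.integer(n_mock),
              reads_per_sample = as.integer(reads_per_sample),
              abundance_logmean = abundance_logmean,
              abundance_logsd = abundance_logsd,
              n_genes = as.integer(n_genes),
              tiles_per_gene_target = as.integer(tiles_per_gene_target),
              n_planted = as.integer(n_planted),
              enrichment_factor = enrichment_factor,
              epitope_fraction = epitope_fraction,
              reactive_cases_range = as.integer(reactive_cases_range),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_cases >= 1, n_controls >= 0, n_mock >= 1,
              reads_per_sample >= 1, n_genes >= 1,
              n_planted >= 0, n_planted <= n_genes,
              epitope_fraction > 0, epitope_fraction <= 1,
              enrichment_factor > 1 || n_planted == 0,
              length(reactive_cases_range) == 2,
              n_planted == 0 || (reactive_cases_range[1] >= 1 &&
                                   reactive_cases_range[2] <= n_cases))
  })
  structure(cfg, class = "phip_sim_config")
}

#' Sample sheet for a synthetic cohort
#'
#' @param config A [simulation_config()].
#' @return data.frame with columns `sample_id`, `role` (case/control/mock),
#'   `cohort` (discovery for cases and controls, none for mocks), `sex`.
#' @export
synthetic_sample_sheet <- function(config) {
  ids <- c(sprintf("CASE%02d", seq_len(config$n_cases)),
           sprintf("CTRL%02d", seq_len(config$n_controls)),
           sprintf("MOCK%02d", seq_len(config$n_mock)))
  roles <- rep(c("case", "control", "mock"),
               c(config$n_cases, config$n_controls, config$n_mock))
  set.seed(config$seed + 11L)
  sex <- ifelse(roles == "mock", NA_character_,
                sample(c("F", "M"), length(ids), replace = TRUE))
  data.frame(sample_id = ids, role = roles,
             cohort = ifelse(roles == "mock", "none", "discovery"),
             sex = sex, stringsAsFactors = FALSE)
}

#' Plant ground-truth antigen reactivities
#'
#' Chooses which genes are autoantigens, which case sera react to each, and
#' which of the antigen's tiles carry the epitopes. This ground truth drives
#' [simulate_counts()] and is what the discovery pipeline must recover.
#'
#' @param library Peptide library (see [tile_proteome()]).
#' @param config A [simulation_config()].
#' @param case_ids Character vector of case sample ids.
#' @return A list of class `phip_truth` with elements `antigen_genes`,
#'   `reactive_map` (antigen -> case ids), `epitope_map` (antigen -> tile
#'   ids), `enrichment_factor` (named numeric), and `phenotype_links`
#'   (empty; see [link_phenotype()]).
#' @export
plant_truth <- function(library, config, case_ids) {
  stopifnot(length(case_ids) == config$n_cases)
  set.seed(config$seed + 23L)
  genes <- sort(unique(library$gene))
  antigens <- sort(sample(genes, config$n_planted))
  reactive_map <- list(); epitope_map <- list()
  for (g in antigens) {
    n_react <- if (config$reactive_cases_range[1] ==
                   config$reactive_cases_range[2])
      config$reactive_cases_range[1]
    else sample(seq(config$reactive_cases_range[1],
                    config$reactive_cases_range[2]), 1L)
    reactive_map[[g]] <- sort(sample(case_ids, n_react))
    tiles <- library$tile_id[library$gene == g]
    n_epi <- max(1L, ceiling(config$epitope_fraction * length(tiles)))
    epitope_map[[g]] <- sort(sample(tiles, n_epi))
  }
  structure(list(antigen_genes = antigens,
                 reactive_map = reactive_map,
                 epitope_map = epitope_map,
                 enrichment_factor =
                   stats::setNames(rep(config$enrichment_factor,
                                       length(antigens)), antigens),
                 phenotype_links = list()),
            class = "phip_truth")
}

#' Attach a phenotype to a planted antigen
#'
#' Records that a clinical phenotype is caused (stochastically) by
#' reactivity to an antigen: reactive cases are affected with probability
#' `penetrance`, non-reactive cases with probability `background_rate`.
#' An `antigen` of `NA` declares an unlinked phenotype with only the
#' background rate.
#'
#' @param truth A `phip_truth` object.
#' @param phenotype Phenotype name.
#' @param antigen Antigen gene symbol in `truth$antigen_genes`, or NA.
#' @param penetrance,background_rate Probabilities in \[0, 1\], with
#'   `penetrance >= background_rate`.
#' @return The updated truth object.
#' @export
link_phenotype <- function(truth, phenotype, antigen, penetrance,
                           background_rate) {
  if (penetrance < 0 || penetrance > 1 ||
      background_rate < 0 || background_rate > 1)
    stop("invalid config: penetrance and background_rate must be in [0, 1]")
  if (penetrance < background_rate)
    stop("invalid config: penetrance must be >= background_rate")
  if (!is.na(antigen) && !antigen %in% truth$antigen_genes)
    stop("antigen ", antigen, " is not planted in this truth")
  truth$phenotype_links[[phenotype]] <-
    list(antigen = antigen, penetrance = penetrance,
         background_rate = background_rate)
  truth
}

#' Simulate a peptide-by-sample read-count matrix
#'
#' Each sample's counts are one multinomial draw of `reads_per_sample` reads
#' over per-tile weights: a shared log-normal base abundance (the library
#' composition), multiplied by the antigen's net enrichment factor for
#' epitope tiles in sera reactive to that antigen. Mock samples never
#' receive enrichment. Identical (config, library, truth) give bit-identical
#' matrices.
#'
#' @param config A [simulation_config()].
#' @param library Peptide library.
#' @param truth A `phip_truth` object (or NULL for a null study with no
#'   reactivity anywhere).
#' @param samples Optional sample sheet; defaults to
#'   [synthetic_sample_sheet()].
#' @return list with `counts` (integer matrix, tiles x samples), `samples`
#'   (the sample sheet), and `base_abundance` (per-tile weights used).
#' @export
simulate_counts <- function(config, library, truth = NULL, samples = NULL) {
  validate_library(library)
  if (is.null(samples)) samples <- synthetic_sample_sheet(config)
  if (!is.null(truth)) {
    orphans <- setdiff(unlist(truth$epitope_map), library$tile_id)
    if (length(orphans))
      stop("truth epitope tiles absent from library: ",
           paste(utils::head(orphans, 5), collapse = ", "))
  }
  n_tiles <- nrow(library)
  set.seed(config$seed + 37L)
  base <- stats::rlnorm(n_tiles, config$abundance_logmean,
                        config$abundance_logsd)
  names(base) <- library$tile_id
  counts <- matrix(0L, n_tiles, nrow(samples),
                   dimnames = list(library$tile_id, samples$sample_id))
  tile_row <- stats::setNames(seq_len(n_tiles), library$tile_id)
  for (j in seq_len(nrow(samples))) {
    w <- base
    sid <- samples$sample_id[j]
    if (!is.null(truth) && samples$role[j] != "mock") {
      for (g in truth$antigen_genes) {
        if (sid %in% truth$reactive_map[[g]]) {
          rows <- tile_row[truth$epitope_map[[g]]]
          w[rows] <- w[rows] * truth$enrichment_factor[[g]]
        }
      }
    }
    counts[, j] <- stats::rmultinom(1L, config$reads_per_sample, w)[, 1L]
  }
  list(counts = counts, samples = samples, base_abundance = base)
}

#' Simulate a binary clinical-phenotype table
#'
#' For each phenotype linked in the truth object, each case is affected
#' with probability `penetrance` if reactive to the linked antigen and
#' `background_rate` otherwise.
#'
#' @param truth A `phip_truth` with phenotype links (see [link_phenotype()]).
#' @param case_ids Character vector of case sample ids.
#' @param seed Integer seed.
#' @return Integer matrix (0/1), cases x phenotypes.
#' @export
simulate_phenotypes <- function(truth, case_ids, seed = 1L) {
  links <- truth$phenotype_links
  if (!length(links)) stop("truth has no phenotype links")
  set.seed(seed)
  phen <- matrix(0L, length(case_ids), length(links),
                 dimnames = list(case_ids, names(links)))
  for (p in names(links)) {
    lk <- links[[p]]
    reactive <- if (is.na(lk$antigen)) character(0)
                else truth$reactive_map[[lk$antigen]]
    pr <- ifelse(case_ids %in% reactive, lk$penetrance, lk$background_rate)
    phen[, p] <- as.integer(stats::runif(length(case_ids)) < pr)
  }
  phen
}

#' Simulate a gene-by-tissue consensus expression matrix
#'
#' Emulates a consensus RNA expression resource over many tissues/cell
#' types. Tissue-restricted genes concentrate >= 90% of their expression
#' mass in a single (random) tissue; broad genes draw near-uniform positive
#' values, so their max/sum specificity ratio sits near 1/n_tissues.
#'
#' @param genes Character vector of gene symbols.
#' @param n_tissues Number of tissues (default 74).
#' @param restricted_genes Subset of `genes` to make tissue-restricted.
#' @param seed Integer seed.
#' @return Non-negative numeric matrix, genes x tissues.
#' @export
simulate_expression <- function(genes, n_tissues = 74L,
                                restricted_genes = character(0), seed = 1L) {
  stopifnot(all(restricted_genes %in% genes), n_tissues >= 2)
  set.seed(seed)
  expr <- matrix(stats::runif(length(genes) * n_tissues, 0.8, 1.2),
                 length(genes), n_tissues,
                 dimnames = list(genes,
                                 sprintf("tissue%02d", seq_len(n_tissues))))
  for (g in restricted_genes) {
    low <- stats::runif(n_tissues, 0, 0.05)
    k <- sample.int(n_tissues, 1L)
    r <- stats::runif(1L, 0.92, 0.99)  # target max/sum ratio
    low[k] <- 0
    expr[g, ] <- low
    expr[g, k] <- r / (1 - r) * sum(low)
  }
  expr
}

#' Simulate a radioligand binding assay (RLBA) plate
#'
#' Emulates per-antigen scintillation counts: duplicate serum wells, blank
#' wells (no serum) and positive-control antibody wells. Expected serum cpm
#' is an affine function of the latent reactivity:
#' `blank_cpm + latent * (positive_cpm - blank_cpm)`, plus Gaussian noise,
#' floored at zero.
#'
#' @param latent_reactivity Named numeric vector in \[0, 1\], one entry per
#'   serum sample.
#' @param noise_sd Gaussian well noise (cpm).
#' @param blank_cpm,positive_cpm Expected blank and positive-control cpm;
#'   `positive_cpm` must exceed `blank_cpm`.
#' @param antigen Antigen label for the output table.
#' @param n_replicates Wells per serum (default 2: duplicates).
#' @param n_blanks,n_positive Number of blank / positive-control wells.
#' @param seed Integer seed.
#' @return data.frame with columns `antigen`, `sample_id`, `replicate`,
#'   `cpm`; blanks and positive controls use the reserved sample ids
#'   `BLANK` and `POSCTRL`.
#' @export
simulate_rlba <- function(latent_reactivity, noise_sd = 0,
                          blank_cpm = 300, positive_cpm = 35000,
                          antigen = "AG", n_replicates = 2L,
                          n_blanks = 4L, n_positive = 2L, seed = 1L) {
  stopifnot(positive_cpm > blank_cpm,
            all(latent_reactivity >= 0), all(latent_reactivity <= 1))
  set.seed(seed)
  ids <- names(latent_reactivity)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_along(latent_reactivity))
  mk <- function(sample_id, mu, n) {
    cpm <- pmax(0, mu + stats::rnorm(n, 0, noise_sd))
    data.frame(antigen = antigen, sample_id = sample_id,
               replicate = seq_len(n), cpm = cpm, stringsAsFactors = FALSE)
  }
  span <- positive_cpm - blank_cpm
  rows <- c(
    list(mk("BLANK", blank_cpm, n_blanks),
         mk("POSCTRL", positive_cpm, n_positive)),
    lapply(seq_along(ids), function(i)
      mk(ids[i], blank_cpm + latent_reactivity[i] * span, n_replicates)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic PhIP-Seq study
#'
#' Convenience wrapper that generates, from a single config and seed, the
#' full set of study inputs: proteome, tiled peptide library, planted truth
#' (with phenotype links for the first planted antigens), count matrix,
#' sample sheet, phenotype table and a tissue expression matrix in which
#' the planted antigens are tissue-restricted.
#'
#' @param config A [simulation_config()].
#' @param n_linked_phenotypes Number of phenotypes linked to planted
#'   antigens (penetrance 0.9, background 0.05); the rest of
#'   `n_phenotypes` are unlinked background phenotypes (rate 0.3).
#' @param n_phenotypes Total phenotypes simulated.
#' @return list with `library`, `truth`, `counts`, `samples`, `phenotypes`,
#'   `expression`, `proteome`, `config`.
#' @export
simulate_study <- function(config = simulation_config(),
                           n_linked_phenotypes = min(3L, config$n_planted),
                           n_phenotypes = 8L) {
  # protein lengths chosen so tiling yields ~tiles_per_gene_target tiles
  k <- config$tiles_per_gene_target
  len_mid <- 49L + 24L * (k - 1L)
  proteome <- random_proteome(
    config$n_genes,
    length_range = c(max(49L, len_mid - 96L), len_mid + 96L),
    seed = config$seed)
  library <- tile_proteome(proteome)
  samples <- synthetic_sample_sheet(config)
  case_ids <- samples$sample_id[samples$role == "case"]
  truth <- plant_truth(library, config, case_ids)
  phen <- NULL
  if (n_phenotypes > 0 && config$n_planted > 0) {
    for (i in seq_len(min(n_linked_phenotypes, config$n_planted)))
      truth <- link_phenotype(truth, sprintf("PHEN%02d", i),
                              truth$antigen_genes[i], 0.9, 0.05)
    i0 <- min(n_linked_phenotypes, config$n_planted)
    for (i in seq_len(max(0L, n_phenotypes - i0)))
      truth <- link_phenotype(truth, sprintf("PHEN%02d", i0 + i), NA,
                              0.3, 0.3)
    phen <- simulate_phenotypes(truth, case_ids, seed = config$seed + 53L)
  }
  sim <- simulate_counts(config, library, truth, samples)
  expr <- simulate_expression(sort(unique(library$gene)),
                              restricted_genes = truth$antigen_genes,
                              seed = config$seed + 71L)
  list(library = library, truth = truth, counts = sim$counts,
       samples = samples, phenotypes = phen, expression = expr,
       proteome = proteome, config = config)
}
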