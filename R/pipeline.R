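#' Default end-to-end run configuration
#'
#' Thresholds encode the discovery criteria of the screen: 10-fold
#' positivity over the mock background, candidates reported at a minimum
#' of 2 positive cases (known-antigen cross-reference) or 3 positive cases
#' (novel antigens), with 0 positive controls allowed.
#'
#' @param ... Overrides for any config field.
#' @return Named list of class `phip_run_config`.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    simulate = TRUE,            # simulate inputs instead of reading files
    sim = list(),               # overrides for simulation_config()
    counts = NULL, library = NULL, samples = NULL,  # input paths
    phenotypes = NULL, expression = NULL, rlba = NULL,
    known_genes = NULL,         # vector or file path; NULL = shipped list
    fold_threshold = 10, min_cases_known = 2L, min_cases_novel = 3L,
    max_controls = 0L, gene_mode = "sum", mock_stat = "mean",
    n_iter = 10000L, k_sd = 3, antigen_overrides = list(),
    min_group_size = 3L, alpha_mask = 0.05,
    seed = 1L, out_dir = "phip_run")
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]]))
    over <- over[[1]]
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "phip_run_config")
}

resolve_known_genes <- function(known_genes) {
  if (is.null(known_genes)) return(default_known_antigens())
  if (length(known_genes) == 1 && file.exists(known_genes))
    return(default_known_antigens(known_genes))
  known_genes
}

#' Run the discovery pipeline end to end
#'
#' Ingests (or simulates) a study, computes mock-background fold-change
#' enrichment, calls per-sample positivity and candidate antigens,
#' partitions them into known and novel, ranks by cohort frequency,
#' z-scores and clusters the candidate enrichments, and — when the
#' corresponding inputs are present — runs the tissue-restriction
#' resampling test, the phenotype association screen, and the RLBA
#' statistics. All tables are written under `config$out_dir` together
#' with a config snapshot and an artifact manifest (md5 checksums);
#' re-running with the same config and seed reproduces the payloads
#' byte for byte.
#'
#' @param config A `phip_run_config` (see [default_run_config()]), a list
#'   of overrides, or a path to a YAML file of overrides.
#' @return Invisibly, a `ReportBundle`-style list with all stage results.
#' @export
run_discovery <- function(config = default_run_config()) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!inherits(config, "phip_run_config"))
    config <- default_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  # -- stage: inputs ------------------------------------------------------
  if (isTRUE(config$simulate)) {
    sim_over <- config$sim
    if (is.null(sim_over$seed)) sim_over$seed <- config$seed
    sim_cfg <- do.call(simulation_config, sim_over)
    study <- simulate_study(sim_cfg)
    counts <- study$counts; library <- study$library
    samples <- study$samples; phen <- study$phenotypes
    expr <- study$expression
    rlba <- NULL
    note("simulated study: %d tiles, %d genes, %d samples",
         nrow(counts), length(unique(library$gene)), ncol(counts))
  } else {
    if (is.null(config$counts) || is.null(config$library) ||
        is.null(config$samples))
      stop("stage inputs: counts, library and samples paths are required")
    counts <- read_count_matrix(config$counts)
    library <- read_peptide_library(config$library)
    samples <- read_sample_sheet(config$samples)
    phen <- if (!is.null(config$phenotypes))
      read_phenotype_table(config$phenotypes) else NULL
    expr <- if (!is.null(config$expression))
      read_expression_matrix(config$expression) else NULL
    rlba <- if (!is.null(config$rlba))
      read_rlba_table(config$rlba) else NULL
    study <- NULL
    note("loaded study: %d tiles x %d samples", nrow(counts),
         ncol(counts))
  }
  if (!any(samples$role == "mock"))
    stop("stage inputs: no mock samples in the sample sheet")

  # -- stage: enrichment --------------------------------------------------
  enr <- enrichment_pipeline(counts, library, samples,
                             mode = config$gene_mode,
                             mock_stat = config$mock_stat)
  note("enrichment: pseudocount epsilon = %.3g%%", enr$gene$epsilon)
  write_enrichment(enr$gene, file.path(out_dir, "gene_fold_change.tsv"))

  # -- stage: hit calling -------------------------------------------------
  pos <- call_positive_genes(enr$gene, config$fold_threshold)
  known_genes <- resolve_known_genes(config$known_genes)
  cand_known <- candidate_antigens(pos, samples, config$min_cases_known,
                                   config$max_controls)
  cand_novel <- candidate_antigens(pos, samples, config$min_cases_novel,
                                   config$max_controls)
  parts <- cross_reference_known(cand_novel, known_genes)
  ranking <- rank_by_frequency(pos, samples)
  note("hit calling: %d candidates at >=%d cases (%d known, %d novel)",
       nrow(cand_novel), config$min_cases_novel, length(parts$known),
       length(parts$novel))
  cand_out <- cand_novel
  cand_out$known_flag <- cand_out$gene %in% known_genes
  data.table::fwrite(cand_out, file.path(out_dir, "candidates.tsv"),
                     sep = "\t")
  data.table::fwrite(ranking, file.path(out_dir, "ranking.tsv"),
                     sep = "\t")

  clust <- NULL
  if (nrow(cand_novel) >= 2 && ncol(enr$gene$fold) >= 2) {
    clust <- zscore_and_cluster(enr$gene, cand_novel$gene)
    zt <- data.table::data.table(gene = rownames(clust$z), clust$z)
    data.table::fwrite(zt, file.path(out_dir, "zscores.tsv"), sep = "\t")
    writeLines(c(paste(clust$row_order, collapse = "\t"),
                 paste(clust$col_order, collapse = "\t")),
               file.path(out_dir, "cluster_orders.tsv"))
  }

  # -- stage: tissue specificity -----------------------------------------
  spec <- NULL
  if (!is.null(expr) && nrow(cand_novel) >= 2) {
    spec <- resampling_enrichment_test(cand_novel$gene, expr,
                                       n_iter = config$n_iter,
                                       seed = config$seed + 101L)
    jsonlite::write_json(
      list(observed_mean_ratio = spec$observed_mean_ratio,
           fold_vs_null = spec$fold_vs_null,
           empirical_p = spec$empirical_p, n_iter = spec$n_iter,
           seed = spec$seed, dropped_genes = spec$dropped_genes),
      file.path(out_dir, "tissue_specificity.json"),
      auto_unbox = TRUE, digits = NA)
    note("tissue specificity: fold vs null %.2f, p = %.4g",
         spec$fold_vs_null, spec$empirical_p)
  }

  # -- stage: phenotype association --------------------------------------
  assoc <- NULL
  if (!is.null(phen) && nrow(cand_novel) >= 1) {
    assoc <- association_screen(enr$gene, phen,
                                genes = cand_novel$gene,
                                min_group_size = config$min_group_size,
                                alpha_mask = config$alpha_mask)
    data.table::fwrite(assoc, file.path(out_dir, "associations.tsv"),
                       sep = "\t")
    note("association screen: %d gene x phenotype tests, %d masked",
         nrow(assoc), sum(assoc$masked, na.rm = TRUE))
  }

  # -- stage: RLBA --------------------------------------------------------
  rlba_out <- NULL
  if (!is.null(rlba)) {
    idx <- antibody_index_table(rlba)
    roles <- stats::setNames(samples$role, samples$sample_id)
    rows <- lapply(split(idx, idx$antigen), function(d) {
      iv <- stats::setNames(d$index, d$sample_id)
      ctrl <- iv[roles[names(iv)] == "control"]
      call <- positivity_call(iv, ctrl, k_sd = config$k_sd,
                              antigen = d$antigen[1],
                              antigen_overrides =
                                unlist(config$antigen_overrides))
      gd <- group_difference(iv[roles[names(iv)] %in%
                                  c("case", "control")],
                             roles[names(iv)][roles[names(iv)] %in%
                                                c("case", "control")])
      data.frame(antigen = d$antigen[1], sample_id = names(iv),
                 index = unname(iv), cutoff = call$cutoff,
                 k_sd = call$k_sd, positive = unname(call$positive),
                 mw_p = gd$p, stringsAsFactors = FALSE)
    })
    rlba_out <- do.call(rbind, rows)
    rownames(rlba_out) <- NULL
    data.table::fwrite(rlba_out, file.path(out_dir, "rlba_indices.tsv"),
                       sep = "\t")
    note("RLBA: %d antigens, %d sera",
         length(unique(rlba_out$antigen)),
         length(unique(rlba_out$sample_id)))
  }

  # -- report -------------------------------------------------------------
  snapshot <- unclass(config)
  snapshot$sim <- if (isTRUE(config$simulate) && !is.null(study))
    unclass(study$config) else config$sim
  jsonlite::write_json(snapshot, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  payloads <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- data.frame(
    file = payloads,
    bytes = file.size(file.path(out_dir, payloads)),
    md5 = unname(tools::md5sum(file.path(out_dir, payloads))),
    stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA)
  invisible(list(config = config, study = study, enrichment = enr,
                 positivity = pos, candidates_known_rule = cand_known,
                 candidates = cand_novel, known = parts$known,
                 novel = parts$novel, ranking = ranking,
                 clustering = clust, specificity = spec,
                 associations = assoc, rlba = rlba_out,
                 manifest = manifest, log = log_lines))
}

#' Planted-antigen recovery for one simulated study
#'
#' Simulates a study under the default (cohort-mirroring) conditions,
#' runs enrichment and candidate calling at the discovery criteria
#' (10-fold, >= `min_cases` cases, 0 controls), and scores the candidate
#' list against the planted ground truth.
#'
#' @param seed Integer seed for the simulated study.
#' @param sim List of overrides for [simulation_config()].
#' @param min_cases Candidate criterion (default 3).
#' @param fold_threshold Positivity threshold (default 10).
#' @return list with `n_planted`, `n_recovered`, `n_false`,
#'   `candidates`, `planted`.
#' @export
recover_planted <- function(seed, sim = list(), min_cases = 3L,
                            fold_threshold = 10) {
  sim$seed <- seed
  cfg <- do.call(simulation_config, sim)
  study <- simulate_study(cfg, n_phenotypes = 0L)
  enr <- enrichment_pipeline(study$counts, study$library, study$samples)
  pos <- call_positive_genes(enr$gene, fold_threshold)
  cand <- candidate_antigens(pos, study$samples, min_cases)
  planted <- study$truth$antigen_genes
  list(n_planted = length(planted),
       n_recovered = sum(planted %in% cand$gene),
       n_false = sum(!cand$gene %in% planted),
       candidates = cand, planted = planted)
}

#' Write a fixture study to disk
#'
#' Generates a complete synthetic study and writes every input file the
#' pipeline readers consume, plus a ground-truth table for assertions.
#' `tiny` (20 genes, 6 cases / 4 controls / 3 mocks, shallow depth) is
#' meant for unit tests; `paper` mirrors the cohort design the defaults
#' encode (39/28/17, 200 genes, 10 planted antigens).
#'
#' @param out_dir Output directory (created if needed).
#' @param scale `"tiny"` or `"paper"`.
#' @param seed Integer seed.
#' @return Invisibly, named vector of the written paths.
#' @export
make_fixtures <- function(out_dir, scale = c("tiny", "paper"),
                          seed = 1L) {
  scale <- match.arg(scale)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- if (scale == "tiny")
    simulation_config(n_cases = 6L, n_controls = 4L, n_mock = 3L,
                      reads_per_sample = 5e4, n_genes = 20L,
                      tiles_per_gene_target = 4L, n_planted = 3L,
                      reactive_cases_range = c(3L, 4L), seed = seed)
  else simulation_config(seed = seed)
  study <- simulate_study(cfg)
  paths <- c(
    counts = write_count_matrix(study$counts,
                                file.path(out_dir, "counts.tsv")),
    library = write_peptide_library(study$library,
                                    file.path(out_dir, "library.tsv")),
    samples = write_sample_sheet(study$samples,
                                 file.path(out_dir, "samples.csv")),
    phenotypes = write_phenotype_table(
      study$phenotypes, file.path(out_dir, "phenotypes.csv")),
    expression = write_expression_matrix(
      study$expression, file.path(out_dir, "expression.tsv")))
  # RLBA plates for the first two planted antigens, driven by the truth
  set.seed(cfg$seed + 97L)
  serum_ids <- study$samples$sample_id[study$samples$role != "mock"]
  rlba <- do.call(rbind, lapply(
    utils::head(study$truth$antigen_genes, 2L), function(g) {
      reactive <- serum_ids %in% study$truth$reactive_map[[g]]
      latent <- ifelse(reactive, stats::runif(length(serum_ids), 0.5, 1),
                       stats::runif(length(serum_ids), 0, 0.04))
      names(latent) <- serum_ids
      simulate_rlba(latent, noise_sd = 300, antigen = g,
                    seed = cfg$seed + 97L + match(
                      g, study$truth$antigen_genes))
    }))
  paths["rlba"] <- write_rlba_table(rlba, file.path(out_dir, "rlba.csv"))
  truth_rows <- do.call(rbind, lapply(
    study$truth$antigen_genes, function(g)
      expand.grid(antigen = g,
                  sample_id = study$truth$reactive_map[[g]],
                  tile_id = study$truth$epitope_map[[g]],
                  factor = study$truth$enrichment_factor[[g]],
                  stringsAsFactors = FALSE)))
  data.table::fwrite(truth_rows, file.path(out_dir, "truth.tsv"),
                     sep = "\t")
  paths["truth"] <- file.path(out_dir, "truth.tsv")
  invisible(paths)
}
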