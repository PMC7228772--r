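#' Normalize raw counts to percentage of reads per sample
#'
#' Converts a tile-by-sample integer count matrix to read percentages:
#' `100 * count / column total`. This removes sequencing-depth differences
#' between samples; every column of the result sums to 100.
#'
#' @param counts Non-negative numeric matrix, tiles x samples, with
#'   dimnames.
#' @return Numeric matrix of percentages with the same dimnames.
#' @export
normalize_to_percent <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  totals <- colSums(counts)
  bad <- names(totals)[totals == 0]
  if (length(bad))
    stop("degenerate sample(s) with zero total reads: ",
         paste(bad, collapse = ", "))
  sweep(counts, 2L, totals, "/") * 100
}

#' Aggregate tile percentages to gene level
#'
#' Gene-level read percentage is, by default, the sum of the gene's member
#' tile percentages (a gene's total share of the sample's reads). Because
#' genes partition tiles, gene-level columns still sum to 100. A `max`
#' mode (the gene's best single tile) is available for sensitivity
#' analysis.
#'
#' @param norm Tile-by-sample percentage matrix (see
#'   [normalize_to_percent()]).
#' @param library Peptide library mapping `tile_id` to `gene`.
#' @param mode `"sum"` (default) or `"max"`.
#' @return Gene-by-sample numeric matrix covering every library gene
#'   (genes with no observed tiles get zero rows); rows ordered by gene
#'   symbol.
#' @export
aggregate_by_gene <- function(norm, library, mode = c("sum", "max")) {
  mode <- match.arg(mode)
  orphans <- setdiff(rownames(norm), library$tile_id)
  if (length(orphans))
    stop("tiles missing from library annotation: ",
         paste(utils::head(orphans, 10), collapse = ", "))
  gene_of <- stats::setNames(library$gene, library$tile_id)
  g <- gene_of[rownames(norm)]
  agg <- if (mode == "sum") {
    rowsum(norm, group = g)
  } else {
    do.call(rbind, lapply(split(seq_len(nrow(norm)), g), function(idx)
      apply(norm[idx, , drop = FALSE], 2L, max)))
  }
  all_genes <- sort(unique(library$gene))
  out <- matrix(0, length(all_genes), ncol(norm),
                dimnames = list(all_genes, colnames(norm)))
  out[rownames(agg), ] <- agg
  out
}

#' Pseudocount for fold-change in percentage units
#'
#' The fold-change pseudocount is the read-percentage equivalent of a
#' single read at the median mock-IP sequencing depth: `100 / median depth
#' of the mock samples`. It keeps fold-changes finite when the mock
#' background is zero and shrinks folds computed from very few reads.
#'
#' @param counts Raw count matrix (tiles x samples).
#' @param mock_ids Mock sample ids (columns of `counts`).
#' @return Scalar pseudocount in percent units.
#' @export
pseudocount_percent <- function(counts, mock_ids) {
  stopifnot(length(mock_ids) >= 1, all(mock_ids %in% colnames(counts)))
  100 / stats::median(colSums(counts[, mock_ids, drop = FALSE]))
}

#' Fold-change enrichment over the mock-IP background
#'
#' The central statistic of the screen: for each gene (or tile) and each
#' serum sample, the sample's read percentage divided by the mean read
#' percentage across mock-IP (beads only, no serum) samples, with a small
#' pseudocount added to numerator and denominator:
#' `fold = (value + eps) / (mock background + eps)`.
#'
#' @param values Gene- or tile-by-sample percentage matrix (mock columns
#'   included).
#' @param mock_ids Mock sample ids; must be columns of `values`.
#' @param epsilon Pseudocount in percent units (see
#'   [pseudocount_percent()]); default 0.
#' @param mock_stat `"mean"` (default) or `"median"` mock background.
#' @return A list of class `phip_enrichment`: `fold` (matrix over the
#'   non-mock samples), `mock_background` (per-row), `epsilon`,
#'   `mock_stat`.
#' @export
fold_change <- function(values, mock_ids, epsilon = 0,
                        mock_stat = c("mean", "median")) {
  mock_stat <- match.arg(mock_stat)
  if (length(mock_ids) < 1) stop("invalid config: empty mock set")
  if (!all(mock_ids %in% colnames(values)))
    stop("mock ids absent from matrix: ",
         paste(setdiff(mock_ids, colnames(values)), collapse = ", "))
  stopifnot(epsilon >= 0)
  mocks <- values[, mock_ids, drop = FALSE]
  bg <- if (mock_stat == "mean") rowMeans(mocks)
        else apply(mocks, 1L, stats::median)
  keep <- setdiff(colnames(values), mock_ids)
  fold <- (values[, keep, drop = FALSE] + epsilon) / (bg + epsilon)
  if (!all(is.finite(fold)))
    stop("non-finite fold-changes; use a positive epsilon when the mock ",
         "background can be zero")
  structure(list(fold = fold, mock_background = bg, epsilon = epsilon,
                 mock_stat = mock_stat),
            class = "phip_enrichment")
}

#' Full enrichment pipeline from raw counts
#'
#' Runs normalization, gene aggregation and fold-change in one call, with
#' the pseudocount derived from the mock sequencing depths.
#'
#' @param counts Raw tile-by-sample count matrix.
#' @param library Peptide library.
#' @param samples Sample sheet with `sample_id` and `role` columns.
#' @param mode Gene aggregation mode, see [aggregate_by_gene()].
#' @param mock_stat Mock background statistic, see [fold_change()].
#' @return list with `gene` (`phip_enrichment` at gene level), `tile`
#'   (`phip_enrichment` at tile level) and `gene_percent` (gene-level
#'   percentage matrix including mocks).
#' @export
enrichment_pipeline <- function(counts, library, samples,
                                mode = "sum", mock_stat = "mean") {
  mock_ids <- samples$sample_id[samples$role == "mock"]
  if (!length(mock_ids)) stop("sample sheet contains no mock samples")
  eps <- pseudocount_percent(counts, mock_ids)
  norm <- normalize_to_percent(counts)
  gene_pct <- aggregate_by_gene(norm, library, mode = mode)
  list(gene = fold_change(gene_pct, mock_ids, eps, mock_stat),
       tile = fold_change(norm, mock_ids, eps, mock_stat),
       gene_percent = gene_pct)
}

#' Per-protein epitope profile
#'
#' Lays a sample's tile-level fold-changes along the protein's coordinates
#' and counts how many distinct tiles exceed the positivity threshold — a
#' proxy for a polyclonal response targeting multiple sites of the same
#' protein.
#'
#' @param gene Gene symbol.
#' @param tile_fold Named numeric vector (or single-column matrix) of
#'   tile-level fold-changes for one sample, named by tile_id.
#' @param library Peptide library.
#' @param threshold Reactivity threshold on the fold scale (default 10).
#' @return A data.frame (tile_id, start, end, fold) sorted by start
#'   coordinate, with attribute `n_reactive_tiles`.
#' @export
peptide_profile <- function(gene, tile_fold, library, threshold = 10) {
  if (is.matrix(tile_fold)) tile_fold <- tile_fold[, 1L]
  tiles <- library[library$gene == gene, , drop = FALSE]
  if (!nrow(tiles)) stop("unknown gene: ", gene)
  tiles <- tiles[order(tiles$start, tiles$tile_id), , drop = FALSE]
  fold <- tile_fold[tiles$tile_id]
  if (anyNA(fold))
    stop("tile fold-changes missing for gene ", gene)
  out <- data.frame(tile_id = tiles$tile_id, start = tiles$start,
                    end = tiles$end, fold = unname(fold),
                    stringsAsFactors = FALSE)
  attr(out, "n_reactive_tiles") <- sum(out$fold >= threshold)
  out
}
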