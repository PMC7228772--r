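#' Call per-sample gene positivity
#'
#' A sample is positive for a gene when its fold-change enrichment over the
#' mock background is at or above the threshold (10-fold or greater, by
#' default; the boundary is inclusive).
#'
#' @param enr A `phip_enrichment` (see [fold_change()]) or a bare
#'   gene-by-sample fold matrix.
#' @param threshold Positivity threshold on the fold scale (default 10).
#' @return Logical gene-by-sample matrix.
#' @export
call_positive_genes <- function(enr, threshold = 10) {
  stopifnot(threshold > 0)
  fold <- if (inherits(enr, "phip_enrichment")) enr$fold else enr
  fold >= threshold
}

#' Candidate-antigen selection by case/control positivity
#'
#' A gene is a candidate antigen when it is positive in at least
#' `min_cases` case sera and at most `max_controls` control sera
#' (default zero: never positive in a control). Mock samples never enter
#' the counts, and validation-cohort samples are excluded from the
#' discovery criteria unless `include_validation = TRUE`.
#'
#' @param pos Logical gene-by-sample positivity matrix
#'   (see [call_positive_genes()]).
#' @param samples Sample sheet with `sample_id`, `role`, and optionally
#'   `cohort` columns.
#' @param min_cases Minimum positive cases (>= 1).
#' @param max_controls Maximum positive controls (default 0).
#' @param include_validation Count validation-cohort samples too?
#' @return data.frame (gene, n_case_pos, n_control_pos) containing only
#'   the candidates, ordered by descending case count then alphabetically;
#'   attributes `min_cases`, `max_controls`.
#' @export
candidate_antigens <- function(pos, samples, min_cases,
                               max_controls = 0L,
                               include_validation = FALSE) {
  if (min_cases < 1) stop("invalid config: min_cases must be >= 1")
  keep_cohort <- if (include_validation || is.null(samples$cohort))
    rep(TRUE, nrow(samples))
  else samples$cohort != "validation"
  case_ids <- samples$sample_id[samples$role == "case" & keep_cohort]
  ctrl_ids <- samples$sample_id[samples$role == "control" & keep_cohort]
  case_ids <- intersect(case_ids, colnames(pos))
  ctrl_ids <- intersect(ctrl_ids, colnames(pos))
  n_case <- rowSums(pos[, case_ids, drop = FALSE])
  n_ctrl <- rowSums(pos[, ctrl_ids, drop = FALSE])
  sel <- n_case >= min_cases & n_ctrl <= max_controls
  out <- data.frame(gene = rownames(pos)[sel],
                    n_case_pos = unname(n_case[sel]),
                    n_control_pos = unname(n_ctrl[sel]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_case_pos, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "min_cases") <- as.integer(min_cases)
  attr(out, "max_controls") <- as.integer(max_controls)
  out
}

#' Partition candidates into known and novel antigens
#'
#' Cross-references a candidate list against a curated list of
#' literature-reported autoantigens.
#'
#' @param candidates Candidate data.frame (see [candidate_antigens()]) or a
#'   character vector of genes.
#' @param known_genes Character vector of literature-reported antigen gene
#'   symbols (see [default_known_antigens()]).
#' @return list with `known` and `novel` character vectors; their union is
#'   the candidate genes, disjoint.
#' @export
cross_reference_known <- function(candidates, known_genes) {
  genes <- if (is.data.frame(candidates)) candidates$gene else candidates
  list(known = genes[genes %in% known_genes],
       novel = genes[!genes %in% known_genes])
}

#' Curated literature-reported autoantigen list
#'
#' Reads the plain-text list of previously reported autoantigen gene
#' symbols shipped with the package (one symbol per line, `#` comments).
#'
#' @param path Optional path to an alternative list file.
#' @return Character vector of gene symbols.
#' @export
default_known_antigens <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "known_antigens.txt",
                        package = "phipdiscover")
  x <- readLines(path)
  x <- trimws(sub("#.*", "", x))
  x[nzchar(x)]
}

#' Rank genes by positivity frequency among cases
#'
#' @param pos Logical gene-by-sample positivity matrix.
#' @param samples Sample sheet with `sample_id` and `role`.
#' @return data.frame (gene, n_positive_cases) over all genes, in
#'   descending case count with alphabetical tie-break.
#' @export
rank_by_frequency <- function(pos, samples) {
  case_ids <- intersect(samples$sample_id[samples$role == "case"],
                        colnames(pos))
  if (!length(case_ids)) stop("no case samples present")
  n <- rowSums(pos[, case_ids, drop = FALSE])
  out <- data.frame(gene = rownames(pos), n_positive_cases = unname(n),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_positive_cases, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Z-score gene enrichments and cluster for heatmap display
#'
#' Each gene row is z-scored across samples (sample standard deviation,
#' n - 1). Rows and columns are then hierarchically clustered with
#' distance = 1 - Pearson correlation and average linkage (complete
#' linkage available), returning the leaf orders used to render the
#' clustered heatmaps. Zero-variance rows cannot be z-scored or
#' correlated: they are set to all-zero, flagged, and placed last in the
#' row order.
#'
#' @param enr A `phip_enrichment` or a fold matrix.
#' @param genes Optional gene subset (default: all rows).
#' @param linkage `"average"` (default) or `"complete"`.
#' @return list with `z` (z-score matrix), `row_order` and `col_order`
#'   (character vectors of labels in leaf order), and `flagged`
#'   (zero-variance genes).
#' @export
zscore_and_cluster <- function(enr, genes = NULL,
                               linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  fold <- if (inherits(enr, "phip_enrichment")) enr$fold else enr
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(fold))
    if (length(miss))
      stop("genes absent from enrichment matrix: ",
           paste(miss, collapse = ", "))
    fold <- fold[genes, , drop = FALSE]
  }
  if (nrow(fold) < 2 || ncol(fold) < 2)
    stop("need at least 2 genes and 2 samples to cluster")
  mu <- rowMeans(fold)
  sdv <- apply(fold, 1L, stats::sd)
  flagged <- rownames(fold)[sdv == 0]
  z <- (fold - mu) / ifelse(sdv == 0, 1, sdv)
  z[flagged, ] <- 0
  ok <- setdiff(rownames(fold), flagged)
  row_order <- if (length(ok) >= 2) {
    d <- stats::as.dist(1 - stats::cor(t(z[ok, , drop = FALSE])))
    ok[stats::hclust(d, method = linkage)$order]
  } else ok
  cc <- stats::cor(z[ok, , drop = FALSE])
  cc[is.na(cc)] <- 0  # zero-variance sample columns
  col_order <- if (length(ok) >= 2 && ncol(fold) >= 2) {
    colnames(fold)[stats::hclust(stats::as.dist(1 - cc),
                                 method = linkage)$order]
  } else colnames(fold)
  list(z = z, row_order = c(row_order, flagged), col_order = col_order,
       flagged = flagged)
}
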