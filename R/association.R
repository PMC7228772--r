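#' Kolmogorov-Smirnov association of one gene with one phenotype
#'
#' Compares the distribution of a gene's enrichment values between case
#' samples with and without a clinical phenotype, using the two-sided
#' two-sample Kolmogorov-Smirnov test. The exact null distribution is used
#' when `n_with * n_without <= 10000`, the asymptotic approximation
#' otherwise. Direction is the with-group mean minus the without-group
#' mean (positive = enrichment higher in affected individuals). Because KS
#' depends only on ranks of the pooled sample, the result is invariant to
#' strictly increasing transforms of the enrichments (fold vs log-fold is
#' immaterial).
#'
#' @param enr A `phip_enrichment` or gene-by-sample fold matrix.
#' @param phen Binary phenotype matrix/data.frame, case samples x
#'   phenotypes (values 0/1/NA).
#' @param gene Gene symbol (row of the enrichment matrix).
#' @param phenotype Phenotype name (column of `phen`).
#' @param min_group_size Minimum per-group size (default 3); smaller
#'   groups return a missing result rather than an unstable p-value.
#' @return list with `D`, `p`, `direction`, `n_with`, `n_without`,
#'   `missing` (logical).
#' @export
ks_association <- function(enr, phen, gene, phenotype,
                           min_group_size = 3L) {
  fold <- if (inherits(enr, "phip_enrichment")) enr$fold else enr
  if (!gene %in% rownames(fold)) stop("unknown gene: ", gene)
  if (!phenotype %in% colnames(phen))
    stop("unknown phenotype: ", phenotype)
  ids <- intersect(rownames(phen), colnames(fold))
  status <- phen[ids, phenotype]
  keep <- !is.na(status)
  ids <- ids[keep]; status <- status[keep]
  x <- fold[gene, ids[status == 1]]
  y <- fold[gene, ids[status == 0]]
  if (length(x) < min_group_size || length(y) < min_group_size)
    return(list(D = NA_real_, p = NA_real_, direction = NA_real_,
                n_with = length(x), n_without = length(y),
                missing = TRUE))
  exact <- length(x) * length(y) <= 10000
  kt <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  list(D = unname(kt$statistic), p = kt$p.value,
       direction = mean(x) - mean(y),
       n_with = length(x), n_without = length(y), missing = FALSE)
}

#' Mask significant associations in the protective direction
#'
#' Associations where enrichment is higher in individuals *without* the
#' phenotype (direction <= 0) cannot support the antigen as a cause of
#' that manifestation; significant p-values in that direction are masked
#' (reported as p = 1), matching the display convention of directional
#' association heatmaps.
#'
#' @param assoc Long-format association data.frame (see
#'   [association_screen()]) with columns `p_raw` and `direction`.
#' @param alpha_mask Significance level below which protective-direction
#'   entries are masked (default 0.05).
#' @return The data.frame with `p_masked` and logical `masked` columns
#'   (re)computed.
#' @export
directional_mask <- function(assoc, alpha_mask = 0.05) {
  stopifnot(all(c("p_raw", "direction") %in% names(assoc)))
  masked <- !is.na(assoc$p_raw) & !is.na(assoc$direction) &
    assoc$direction <= 0 & assoc$p_raw < alpha_mask
  assoc$p_masked <- ifelse(masked, 1, assoc$p_raw)
  assoc$masked <- masked
  assoc
}

#' Gene x phenotype association screen
#'
#' Runs [ks_association()] for every requested gene-phenotype pair and
#' applies directional masking. Phenotype values of NA drop the sample for
#' that phenotype only. Phenotypes flagged sex-specific are tested only in
#' samples of the relevant sex (when sample sex is available). Raw
#' p-values are reported by default; Benjamini-Hochberg adjustment over
#' all non-missing tests is available with `bh_adjust = TRUE`.
#'
#' @param enr A `phip_enrichment` or fold matrix.
#' @param phen Binary phenotype matrix/data.frame (cases x phenotypes).
#' @param genes Genes to test (default: all enrichment rows).
#' @param phenotypes Phenotypes to test (default: all columns).
#' @param min_group_size Minimum per-group size (default 3).
#' @param alpha_mask Masking level (default 0.05).
#' @param bh_adjust Add a `p_bh` column (default FALSE).
#' @param sex Optional named character vector (sample id -> "F"/"M").
#' @param sex_specific Optional named character vector
#'   (phenotype -> "F"/"M") restricting those phenotypes to one sex.
#' @return Long-format data.frame (gene, phenotype, D, p_raw, p_masked,
#'   direction, n_with, n_without, masked), ordered by gene then
#'   phenotype.
#' @export
association_screen <- function(enr, phen, genes = NULL, phenotypes = NULL,
                               min_group_size = 3L, alpha_mask = 0.05,
                               bh_adjust = FALSE, sex = NULL,
                               sex_specific = NULL) {
  fold <- if (inherits(enr, "phip_enrichment")) enr$fold else enr
  if (is.null(dim(phen)) || ncol(phen) == 0 || nrow(phen) == 0)
    stop("invalid input: empty phenotype table")
  if (is.null(genes)) genes <- rownames(fold)
  if (is.null(phenotypes)) phenotypes <- colnames(phen)
  miss <- setdiff(genes, rownames(fold))
  if (length(miss))
    stop("genes absent from enrichment: ", paste(miss, collapse = ", "))
  phen <- as.matrix(phen)
  rows <- vector("list", length(genes) * length(phenotypes))
  i <- 0L
  for (g in genes) for (p in phenotypes) {
    ph <- phen
    if (!is.null(sex_specific) && p %in% names(sex_specific) &&
        !is.null(sex)) {
      keep <- rownames(ph)[!is.na(sex[rownames(ph)]) &
                             sex[rownames(ph)] == sex_specific[[p]]]
      ph <- ph[keep, , drop = FALSE]
    }
    res <- ks_association(fold, ph, g, p, min_group_size)
    i <- i + 1L
    rows[[i]] <- data.frame(gene = g, phenotype = p, D = res$D,
                            p_raw = res$p, direction = res$direction,
                            n_with = res$n_with,
                            n_without = res$n_without,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- directional_mask(out, alpha_mask)
  if (bh_adjust) {
    out$p_bh <- NA_real_
    ok <- !is.na(out$p_raw)
    out$p_bh[ok] <- stats::p.adjust(out$p_raw[ok], method = "BH")
  }
  out[order(out$gene, out$phenotype), , drop = FALSE]
}

#' Wide p-value matrix from an association screen
#'
#' @param assoc Long-format screen output (see [association_screen()]).
#' @param value Column to spread (default `"p_masked"`).
#' @return Gene-by-phenotype numeric matrix.
#' @export
association_matrix <- function(assoc, value = "p_masked") {
  genes <- sort(unique(assoc$gene))
  phens <- sort(unique(assoc$phenotype))
  m <- matrix(NA_real_, length(genes), length(phens),
              dimnames = list(genes, phens))
  m[cbind(match(assoc$gene, genes), match(assoc$phenotype, phens))] <-
    assoc[[value]]
  m
}
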