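#' Antibody index from radioligand binding assay counts
#'
#' Calibrates raw scintillation counts (cpm) against the plate's blanks
#' and positive-control antibody: replicate wells are averaged first, then
#' `index = (mean sample - mean blank) / (mean positive - mean blank)`.
#' The mean blank maps to 0 and the positive control to 1; indices can be
#' negative when a serum reads below the blanks. The index is invariant to
#' affine rescaling of all cpm values, so instrument gain cancels.
#'
#' @param sample_cpms Numeric vector of replicate well cpm for one serum.
#' @param blank_cpms Numeric vector of blank-well cpm.
#' @param positive_cpms Numeric vector of positive-control-well cpm.
#' @return Scalar antibody index (dimensionless).
#' @export
antibody_index <- function(sample_cpms, blank_cpms, positive_cpms) {
  b <- mean(blank_cpms); p <- mean(positive_cpms)
  if (p <= b)
    stop("degenerate assay: positive-control cpm not above blank cpm")
  (mean(sample_cpms) - b) / (p - b)
}

#' Antibody indices for a whole RLBA table
#'
#' @param rlba data.frame with columns `antigen`, `sample_id`,
#'   `replicate`, `cpm`; blank wells use sample id `BLANK` and
#'   positive-control wells `POSCTRL`.
#' @return data.frame (antigen, sample_id, index).
#' @export
antibody_index_table <- function(rlba) {
  need <- c("antigen", "sample_id", "cpm")
  stopifnot(all(need %in% names(rlba)))
  out <- lapply(split(rlba, rlba$antigen), function(d) {
    blanks <- d$cpm[d$sample_id == "BLANK"]
    pos <- d$cpm[d$sample_id == "POSCTRL"]
    if (!length(blanks) || !length(pos))
      stop("antigen ", d$antigen[1],
           ": RLBA table needs BLANK and POSCTRL wells")
    sera <- d[!d$sample_id %in% c("BLANK", "POSCTRL"), , drop = FALSE]
    idx <- vapply(split(sera$cpm, sera$sample_id),
                  antibody_index, numeric(1),
                  blank_cpms = blanks, positive_cpms = pos)
    data.frame(antigen = d$antigen[1], sample_id = names(idx),
               index = unname(idx), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Positivity calls from control-based SD cutoffs
#'
#' A serum is positive for an antigen when its antibody index exceeds
#' (strictly) the mean of the non-case control indices plus `k_sd` control
#' standard deviations (sample SD). The default is 3 SD; a stricter
#' per-antigen override (e.g. 6 SD for antigens with an extremely quiet
#' control background) can be supplied.
#'
#' @param indices Named numeric vector of antibody indices to call.
#' @param control_indices Numeric vector of control indices (>= 2).
#' @param k_sd SD multiplier (default 3).
#' @param antigen Antigen name (used for override lookup only).
#' @param antigen_overrides Optional named numeric vector of per-antigen
#'   `k_sd` overrides (e.g. `c(RFX6 = 6)`).
#' @return list with `positive` (named logical), `cutoff`, `k_sd`.
#' @export
positivity_call <- function(indices, control_indices, k_sd = 3,
                            antigen = NULL, antigen_overrides = NULL) {
  if (length(control_indices) < 2)
    stop("insufficient controls: need >= 2 control indices for an SD")
  if (!is.null(antigen) && !is.null(antigen_overrides) &&
      antigen %in% names(antigen_overrides))
    k_sd <- antigen_overrides[[antigen]]
  cutoff <- mean(control_indices) + k_sd * stats::sd(control_indices)
  list(positive = indices > cutoff, cutoff = cutoff, k_sd = k_sd)
}

#' Case/control group comparison of antibody indices
#'
#' Two-sided Mann-Whitney U test between the two groups (exact for small
#' samples without ties, normal approximation with tie correction
#' otherwise, as implemented by [stats::wilcox.test()]).
#'
#' @param indices Numeric vector of antibody indices.
#' @param labels Factor/character vector of the same length with exactly
#'   two groups (e.g. case/control).
#' @return list with `U` (statistic for the first group level) and `p`.
#' @export
group_difference <- function(indices, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2 || any(table(labels) == 0))
    stop("invalid input: need two non-empty groups")
  x <- indices[labels == levels(labels)[1]]
  y <- indices[labels == levels(labels)[2]]
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Cross-assay Pearson correlation
#'
#' Correlates RLBA antibody indices with PhIP-Seq fold-change enrichments
#' on paired samples (typically the discovery cohort).
#'
#' @param rlba_indices Named numeric vector (sample id -> index).
#' @param phip_folds Named numeric vector (sample id -> fold-change).
#' @param sample_ids Optional explicit pairing; defaults to the
#'   intersection of the names.
#' @return Pearson correlation coefficient r.
#' @export
correlate_assays <- function(rlba_indices, phip_folds, sample_ids = NULL) {
  if (is.null(sample_ids))
    sample_ids <- intersect(names(rlba_indices), names(phip_folds))
  if (length(sample_ids) < 3)
    stop("need >= 3 paired observations")
  x <- rlba_indices[sample_ids]; y <- phip_folds[sample_ids]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant series")
  stats::cor(x, y)
}

#' Concordance of positivity between two antigens
#'
#' Fraction of shared samples with the same positivity flag for both
#' antigens, plus the underlying 2x2 contingency table.
#'
#' @param pos_a,pos_b Named logical vectors of positivity flags.
#' @return list with `concordance` (fraction equal) and `table` (2x2).
#' @export
concordance <- function(pos_a, pos_b) {
  ids <- intersect(names(pos_a), names(pos_b))
  if (!length(ids)) stop("invalid input: no shared samples")
  a <- pos_a[ids]; b <- pos_b[ids]
  tab <- table(factor(a, c(FALSE, TRUE)), factor(b, c(FALSE, TRUE)),
               dnn = c("antigen_a", "antigen_b"))
  list(concordance = mean(a == b), table = tab)
}
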