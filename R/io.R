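#' Read a tile-by-sample count matrix from TSV
#'
#' Expected layout: first column `tile_id`, remaining columns one per
#' sample, integer cells.
#'
#' @param path Path to a TSV file.
#' @return Integer matrix with tile rownames and sample colnames.
#' @export
read_count_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  if (names(dt)[1] != "tile_id")
    stop("count matrix must have 'tile_id' as its first column: ", path)
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- dt$tile_id
  storage.mode(m) <- "integer"
  if (any(m < 0, na.rm = TRUE)) stop("negative counts in ", path)
  m
}

#' Write a tile-by-sample count matrix to TSV
#' @param counts Integer matrix with dimnames.
#' @param path Output path.
#' @export
write_count_matrix <- function(counts, path) {
  dt <- data.table::data.table(tile_id = rownames(counts), counts)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a peptide-library annotation TSV
#'
#' Columns: `tile_id`, `gene`, `protein_id`, `start`, `end` (1-based
#' inclusive protein coordinates); `tile_len` is recomputed if absent.
#'
#' @param path Path to a TSV file.
#' @return Validated peptide-library data.frame.
#' @export
read_peptide_library <- function(path) {
  lib <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  if (!"tile_len" %in% names(lib))
    lib$tile_len <- lib$end - lib$start + 1L
  validate_library(lib)
  lib
}

#' Write a peptide-library annotation TSV
#' @param library Peptide-library data.frame.
#' @param path Output path.
#' @export
write_peptide_library <- function(library, path) {
  data.table::fwrite(library, path, sep = "\t")
  invisible(path)
}

#' Read a sample sheet CSV
#'
#' Columns: `sample_id`, `role` in case/control/mock, `cohort` in
#' discovery/validation/none, optional `sex`.
#'
#' @param path Path to a CSV file.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  ss <- data.table::fread(path, sep = ",", header = TRUE,
                          data.table = FALSE)
  need <- c("sample_id", "role", "cohort")
  miss <- setdiff(need, names(ss))
  if (length(miss))
    stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(ss$role), c("case", "control", "mock"))
  if (length(bad))
    stop("unknown sample roles: ", paste(bad, collapse = ", "))
  if (anyDuplicated(ss$sample_id)) stop("duplicate sample ids in ", path)
  ss
}

#' Write a sample sheet CSV
#' @param samples Sample-sheet data.frame.
#' @param path Output path.
#' @export
write_sample_sheet <- function(samples, path) {
  data.table::fwrite(samples, path, sep = ",", na = "NA")
  invisible(path)
}

#' Read a binary phenotype table CSV
#'
#' Rows are case sample ids (first column `sample_id`), columns are
#' phenotype names, cells 0/1/NA.
#'
#' @param path Path to a CSV file.
#' @return Integer matrix, samples x phenotypes.
#' @export
read_phenotype_table <- function(path) {
  dt <- data.table::fread(path, sep = ",", header = TRUE,
                          data.table = FALSE)
  if (names(dt)[1] != "sample_id")
    stop("phenotype table must have 'sample_id' first: ", path)
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- dt$sample_id
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L, NA)))
    stop("phenotype values must be 0, 1 or NA: ", path)
  m
}

#' Write a binary phenotype table CSV
#' @param phen Phenotype matrix (samples x phenotypes).
#' @param path Output path.
#' @export
write_phenotype_table <- function(phen, path) {
  dt <- data.table::data.table(sample_id = rownames(phen), phen)
  data.table::fwrite(dt, path, sep = ",")
  invisible(path)
}

#' Read a gene-by-tissue expression matrix
#'
#' Two layouts are supported: the consensus long format with columns
#' `Gene` (or `Gene name`), `Tissue` and `nTPM` (one row per gene-tissue
#' pair), and a wide matrix whose first column is the gene symbol and
#' remaining columns are tissues.
#'
#' @param path Path to a TSV file.
#' @param layout `"auto"` (default), `"long"` or `"wide"`.
#' @return Numeric matrix, genes x tissues.
#' @export
read_expression_matrix <- function(path, layout = c("auto", "long",
                                                    "wide")) {
  layout <- match.arg(layout)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  nm <- names(dt)
  is_long <- any(c("Gene", "Gene name") %in% nm) && "Tissue" %in% nm &&
    "nTPM" %in% nm
  if (layout == "auto") layout <- if (is_long) "long" else "wide"
  if (layout == "long") {
    if (!is_long) stop("not a long-format expression file: ", path)
    gcol <- if ("Gene name" %in% nm) "Gene name" else "Gene"
    genes <- sort(unique(dt[[gcol]]))
    tissues <- sort(unique(dt$Tissue))
    m <- matrix(0, length(genes), length(tissues),
                dimnames = list(genes, tissues))
    m[cbind(match(dt[[gcol]], genes), match(dt$Tissue, tissues))] <-
      dt$nTPM
    m
  } else {
    m <- as.matrix(dt[, -1, drop = FALSE])
    rownames(m) <- dt[[1]]
    m
  }
}

#' Write a gene-by-tissue expression matrix (long consensus layout)
#' @param expr Numeric matrix, genes x tissues.
#' @param path Output path.
#' @export
write_expression_matrix <- function(expr, path) {
  dt <- data.table::data.table(
    Gene = rep(rownames(expr), times = ncol(expr)),
    Tissue = rep(colnames(expr), each = nrow(expr)),
    nTPM = as.vector(expr))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read an RLBA raw-count CSV
#'
#' Columns: `antigen`, `sample_id` (with `BLANK` and `POSCTRL` reserved
#' for blank and positive-control wells), `replicate`, `cpm`.
#'
#' @param path Path to a CSV file.
#' @return data.frame.
#' @export
read_rlba_table <- function(path) {
  dt <- data.table::fread(path, sep = ",", header = TRUE,
                          data.table = FALSE)
  need <- c("antigen", "sample_id", "replicate", "cpm")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("RLBA table missing columns: ", paste(miss, collapse = ", "))
  if (any(dt$cpm < 0)) stop("negative cpm values in ", path)
  dt
}

#' Write an RLBA raw-count CSV
#' @param rlba RLBA data.frame.
#' @param path Output path.
#' @export
write_rlba_table <- function(rlba, path) {
  data.table::fwrite(rlba, path, sep = ",")
  invisible(path)
}

#' Write a gene-by-sample fold-change matrix to TSV
#' @param enr A `phip_enrichment` or fold matrix.
#' @param path Output path.
#' @export
write_enrichment <- function(enr, path) {
  fold <- if (inherits(enr, "phip_enrichment")) enr$fold else enr
  dt <- data.table::data.table(gene = rownames(fold), fold)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
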