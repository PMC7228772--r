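#' Generate a random synthetic proteome
#'
#' Builds a set of synthetic proteins with uniform-random amino-acid
#' sequences. Sequence content is never used downstream (only coordinates
#' are), but real-looking sequences keep the fixtures honest end to end.
#'
#' @param n_genes Number of proteins/genes to generate.
#' @param length_range Integer vector of length 2; protein lengths are drawn
#'   uniformly from this range (residues).
#' @param seed Integer RNG seed; identical inputs give identical output.
#' @param gene_prefix Prefix for generated gene symbols.
#' @return A data.frame with columns `protein_id`, `gene`, `sequence`,
#'   `length`, one row per protein. Gene symbols are unique.
#' @export
random_proteome <- function(n_genes, length_range = c(100L, 400L),
                            seed = 1L, gene_prefix = "G") {
  stopifnot(n_genes >= 1, length(length_range) == 2,
            length_range[1] >= 1, length_range[2] >= length_range[1])
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  lens <- sample.int(length_range[2] - length_range[1] + 1L, n_genes,
                     replace = TRUE) + length_range[1] - 1L
  genes <- sprintf("%s%04d", gene_prefix, seq_len(n_genes))
  seqs <- vapply(lens, function(L)
    paste(sample(aa, L, replace = TRUE), collapse = ""), character(1))
  data.frame(protein_id = paste0(genes, "_P1"), gene = genes,
             sequence = seqs, length = lens, stringsAsFactors = FALSE)
}

#' Tile a proteome into overlapping peptides
#'
#' Cuts every protein into fixed-length peptide tiles with a constant
#' overlap, the design used by proteome-wide phage-display libraries
#' (49-residue tiles stepping by 24 so adjacent tiles share 25 residues).
#' Tiling starts at residue 1 and steps by `tile_len - overlap`. When the
#' last regular tile does not reach the C-terminus, one extra tile is
#' anchored to the C-terminus (so trailing residues are covered by a
#' full-length tile, at the cost of extra overlap). Proteins shorter than
#' `tile_len` yield a single tile spanning the whole protein.
#'
#' @param proteome A data.frame with columns `protein_id`, `gene`, `length`
#'   (see [random_proteome()]); a `sequence` column is accepted and ignored.
#' @param tile_len Tile length in residues (default 49).
#' @param overlap Overlap between adjacent tiles in residues (default 25);
#'   must be strictly smaller than `tile_len`.
#' @return A peptide-library data.frame with columns `tile_id`, `gene`,
#'   `protein_id`, `start`, `end`, `tile_len`. Coordinates are 1-based
#'   inclusive; every residue of every protein is covered by at least one
#'   tile.
#' @examples
#' p <- data.frame(protein_id = "P1", gene = "G1", length = 73)
#' tile_proteome(p) # two tiles: [1,49] and [25,73]
#' @export
tile_proteome <- function(proteome, tile_len = 49L, overlap = 25L) {
  tile_len <- as.integer(tile_len); overlap <- as.integer(overlap)
  if (tile_len <= overlap || overlap < 0)
    stop("invalid tiling config: need tile_len > overlap >= 0")
  stopifnot(all(c("protein_id", "gene", "length") %in% names(proteome)),
            all(proteome$length >= 1))
  step <- tile_len - overlap
  out <- vector("list", nrow(proteome))
  for (i in seq_len(nrow(proteome))) {
    L <- proteome$length[i]
    if (L <= tile_len) {
      starts <- 1L
      ends <- L
    } else {
      starts <- seq.int(1L, L - tile_len + 1L, by = step)
      if (starts[length(starts)] + tile_len - 1L < L)
        starts <- c(starts, L - tile_len + 1L)
      ends <- starts + tile_len - 1L
    }
    out[[i]] <- data.frame(
      tile_id = sprintf("%s_t%03d", proteome$protein_id[i],
                        seq_along(starts)),
      gene = proteome$gene[i],
      protein_id = proteome$protein_id[i],
      start = starts, end = ends, tile_len = ends - starts + 1L,
      stringsAsFactors = FALSE)
  }
  lib <- do.call(rbind, out)
  rownames(lib) <- NULL
  lib
}

#' Validate a peptide library
#'
#' Checks the structural invariants of a peptide-library table: unique tile
#' ids, 1-based inclusive coordinates consistent with the stored tile
#' length, and one gene per tile.
#'
#' @param library A peptide-library data.frame (see [tile_proteome()]).
#' @return Invisibly, the library; stops on violation.
#' @export
validate_library <- function(library) {
  need <- c("tile_id", "gene", "protein_id", "start", "end", "tile_len")
  miss <- setdiff(need, names(library))
  if (length(miss))
    stop("library is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(library$tile_id))
    stop("library tile_ids are not unique")
  if (any(library$start < 1))
    stop("library coordinates must be 1-based (start >= 1)")
  if (any(library$end - library$start + 1L != library$tile_len))
    stop("tile_len inconsistent with start/end coordinates")
  invisible(library)
}
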