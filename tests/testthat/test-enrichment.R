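test_that("normalization converts counts to per-sample read percentages", {
  m <- matrix(c(30, 70), 2, 1, dimnames = list(c("t1", "t2"), "S"))
  expect_equal(as.vector(normalize_to_percent(m)), c(30, 70))
  one <- matrix(17L, 1, 1, dimnames = list("t1", "S"))
  expect_equal(as.vector(normalize_to_percent(one)), 100)
  norm <- normalize_to_percent(tiny_counts())
  expect_equal(unname(colSums(norm)), rep(100, 4), tolerance = 1e-10)
})

test_that("zero-read samples raise an error naming the sample", {
  m <- tiny_counts()
  m[, "S2"] <- 0L
  expect_error(normalize_to_percent(m), "S2")
})

test_that("normalization is invariant to uniform depth rescaling", {
  m <- tiny_counts()
  m2 <- m
  m2[, "S1"] <- m2[, "S1"] * 7L
  expect_equal(normalize_to_percent(m), normalize_to_percent(m2))
})

test_that("gene aggregation sums member tiles and preserves column sums", {
  norm <- normalize_to_percent(tiny_counts())
  gp <- aggregate_by_gene(norm, tiny_library())
  expect_equal(gp["GA", ], norm["t1", ] + norm["t2", ] + norm["t3", ])
  expect_equal(gp["GB", ], norm["t4", ] + norm["t5", ])
  expect_equal(unname(colSums(gp)), rep(100, 4), tolerance = 1e-10)
  # max mode returns the gene's best single tile
  gmax <- aggregate_by_gene(norm, tiny_library(), mode = "max")
  expect_equal(gmax["GB", "S1"], max(norm[c("t4", "t5"), "S1"]))
  # orphan tiles are reported
  bad <- rbind(norm, orphan = norm[1, ])
  expect_error(aggregate_by_gene(bad, tiny_library()), "orphan")
})

test_that("fold-change matches a brute-force oracle to 1e-12 relative", {
  counts <- tiny_counts()
  lib <- tiny_library()
  mock_ids <- "M1"
  eps <- pseudocount_percent(counts, mock_ids)
  # independent brute-force computation with explicit loops
  oracle <- local({
    pct <- counts
    for (j in colnames(counts)) {
      tot <- 0
      for (i in rownames(counts)) tot <- tot + counts[i, j]
      for (i in rownames(counts)) pct[i, j] <- 100 * counts[i, j] / tot
    }
    genes <- unique(lib$gene)
    gp <- matrix(0, length(genes), ncol(counts),
                 dimnames = list(genes, colnames(counts)))
    for (g in genes) for (j in colnames(counts))
      gp[g, j] <- sum(pct[lib$tile_id[lib$gene == g], j])
    keep <- setdiff(colnames(counts), mock_ids)
    fold <- matrix(0, length(genes), length(keep),
                   dimnames = list(genes, keep))
    for (g in genes) {
      bg <- mean(gp[g, mock_ids])
      for (j in keep) fold[g, j] <- (gp[g, j] + eps) / (bg + eps)
    }
    fold
  })
  enr <- enrichment_pipeline(counts, lib, tiny_samples())
  expect_equal(enr$gene$fold, oracle, tolerance = 1e-12)
  expect_equal(mean(abs(enr$gene$fold / oracle - 1)), 0,
               tolerance = 1e-12)
  expect_false("M1" %in% colnames(enr$gene$fold))
})

test_that("fold-change applies the one-read pseudocount rule", {
  # mock background exactly 0 at depth 1e6: eps = 1e-4 percent
  vals <- matrix(c(0.1, 0), 1, 2, dimnames = list("G", c("S", "M")))
  enr <- fold_change(vals, mock_ids = "M", epsilon = 1e-4)
  expect_equal(unname(enr$fold["G", "S"]), (0.1 + 1e-4) / 1e-4)
  # forced arithmetic: 0.25% over mock mean 0.01% with negligible eps
  vals2 <- matrix(c(0.25, 0.01), 1, 2,
                  dimnames = list("G", c("S", "M")))
  enr2 <- fold_change(vals2, "M", epsilon = 1e-9)
  expect_equal(unname(enr2$fold["G", "S"]), 25, tolerance = 1e-4)
  # equal to the mock mean -> fold ~ 1
  vals3 <- matrix(c(0.02, 0.02), 1, 2,
                  dimnames = list("G", c("S", "M")))
  expect_equal(unname(fold_change(vals3, "M")$fold["G", "S"]), 1,
               tolerance = 1e-3)
  expect_error(fold_change(vals, character(0)), "invalid config")
  expect_error(fold_change(vals, "M"), "non-finite|epsilon")
})

test_that("pseudocount equals one read at the median mock depth", {
  counts <- cbind(tiny_counts(),
                  M2 = c(10L, 10L, 10L, 10L, 10L))
  expect_equal(pseudocount_percent(counts, c("M1", "M2")),
               100 / stats::median(c(sum(tiny_counts()[, "M1"]), 50)))
})

test_that("with eps = 0 and positive mocks, fold-change is scale-free", {
  norm <- normalize_to_percent(tiny_counts())
  gp <- aggregate_by_gene(norm, tiny_library())
  f1 <- fold_change(gp, "M1", epsilon = 0)$fold
  f2 <- fold_change(gp * 2, "M1", epsilon = 0)$fold
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("median mock background is available as an option", {
  vals <- matrix(c(1, 1, 2, 9), 1, 4,
                 dimnames = list("G", c("S", "M1", "M2", "M3")))
  f_mean <- fold_change(vals, c("M1", "M2", "M3"), mock_stat = "mean")
  f_med <- fold_change(vals, c("M1", "M2", "M3"), mock_stat = "median")
  expect_equal(unname(f_mean$fold["G", "S"]), 1 / 4)
  expect_equal(unname(f_med$fold["G", "S"]), 1 / 2)
})

test_that("epitope profiles are coordinate-ordered with reactive counts", {
  lib <- tiny_library()
  fold <- c(t3 = 15, t1 = 12, t2 = 1, t4 = 3, t5 = 2)  # shuffled input
  prof <- peptide_profile("GA", fold, lib, threshold = 10)
  expect_equal(prof$tile_id, c("t1", "t2", "t3"))
  expect_equal(prof$start, sort(prof$start))
  expect_equal(attr(prof, "n_reactive_tiles"), 2L)
  none <- peptide_profile("GB", fold, lib, threshold = 10)
  expect_equal(attr(none, "n_reactive_tiles"), 0L)
  expect_error(peptide_profile("NOPE", fold, lib), "unknown gene")
})
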