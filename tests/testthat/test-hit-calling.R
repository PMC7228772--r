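test_that("positivity boundary is inclusive at the threshold", {
  fold <- matrix(c(10, 9.999, 10.0001, 0), 2, 2,
                 dimnames = list(c("A", "B"), c("S1", "S2")))
  pos <- call_positive_genes(fold, 10)
  expect_true(pos["A", "S1"])     # exactly 10 is positive
  expect_false(pos["B", "S1"])    # 9.999 is not
  expect_true(pos["A", "S2"])
  # raising the threshold never adds positives
  pos15 <- call_positive_genes(fold, 15)
  expect_true(all(pos[pos15]))
})

toy_positivity <- function() {
  samples <- data.frame(
    sample_id = c("C1", "C2", "C3", "C4", "N1", "N2", "M1"),
    role = c(rep("case", 4), rep("control", 2), "mock"),
    cohort = c(rep("discovery", 6), "none"), stringsAsFactors = FALSE)
  pos <- matrix(FALSE, 3, 7,
                dimnames = list(c("geneA", "geneB", "geneC"),
                                samples$sample_id))
  pos["geneA", c("C1", "C2", "C3")] <- TRUE
  pos["geneB", c("C1", "C2", "C3", "N1")] <- TRUE
  pos["geneC", c("C1", "M1")] <- TRUE   # mock positivity must not count
  list(pos = pos, samples = samples)
}

test_that("candidate antigens satisfy the case/control criteria exactly", {
  t <- toy_positivity()
  cand <- candidate_antigens(t$pos, t$samples, min_cases = 3)
  expect_equal(cand$gene, "geneA")          # geneB fails max_controls = 0
  expect_equal(cand$n_case_pos, 3L)
  cand2 <- candidate_antigens(t$pos, t$samples, min_cases = 3,
                              max_controls = 1)
  expect_setequal(cand2$gene, c("geneA", "geneB"))
  cand3 <- candidate_antigens(t$pos, t$samples, min_cases = 1)
  # mock positivity never counts: geneC has exactly one positive case
  expect_equal(cand3$n_case_pos[cand3$gene == "geneC"], 1L)
  expect_error(candidate_antigens(t$pos, t$samples, min_cases = 0),
               "invalid config")
})

test_that("candidate sets nest across min_cases and fold thresholds", {
  s <- small_study(seed = 31L)
  enr <- enrichment_pipeline(s$counts, s$library, s$samples)
  for (thr in c(5, 10, 20)) {
    pos <- call_positive_genes(enr$gene, thr)
    prev <- NULL
    for (k in 1:4) {
      cand <- candidate_antigens(pos, s$samples, k)$gene
      if (!is.null(prev)) expect_true(all(cand %in% prev))
      prev <- cand
    }
  }
  c10 <- candidate_antigens(call_positive_genes(enr$gene, 10),
                            s$samples, 2)$gene
  c20 <- candidate_antigens(call_positive_genes(enr$gene, 20),
                            s$samples, 2)$gene
  expect_true(all(c20 %in% c10))
})

test_that("sample order permutation changes no candidate set or ranking", {
  s <- small_study(seed = 32L)
  enr <- enrichment_pipeline(s$counts, s$library, s$samples)
  pos <- call_positive_genes(enr$gene)
  set.seed(1)
  perm <- sample(ncol(pos))
  pos_p <- pos[, perm]
  samples_p <- s$samples[sample(nrow(s$samples)), ]
  expect_identical(candidate_antigens(pos, s$samples, 2),
                   candidate_antigens(pos_p, samples_p, 2))
  expect_identical(rank_by_frequency(pos, s$samples),
                   rank_by_frequency(pos_p, samples_p))
})

test_that("validation-cohort samples are excluded from discovery criteria", {
  t <- toy_positivity()
  t$samples$cohort[t$samples$sample_id == "C3"] <- "validation"
  cand <- candidate_antigens(t$pos, t$samples, min_cases = 3)
  expect_equal(nrow(cand), 0L)   # geneA now has only 2 discovery cases
  cand_all <- candidate_antigens(t$pos, t$samples, min_cases = 3,
                                 include_validation = TRUE)
  expect_equal(cand_all$gene, "geneA")
})

test_that("known/novel partition is an exact disjoint cover", {
  parts <- cross_reference_known(c("A", "B", "C"), known_genes = "B")
  expect_equal(parts$known, "B")
  expect_equal(parts$novel, c("A", "C"))
  expect_equal(cross_reference_known(c("A", "B"), character(0))$novel,
               c("A", "B"))
  expect_length(cross_reference_known(c("A"), "Z")$known, 0)
  known <- default_known_antigens()
  expect_true(all(c("CYP11A1", "NLRP5", "SOX10", "TPH1") %in% known))
})

test_that("frequency ranking is descending with alphabetical ties", {
  samples <- data.frame(sample_id = sprintf("C%02d", 1:10),
                        role = "case", cohort = "discovery",
                        stringsAsFactors = FALSE)
  pos <- matrix(FALSE, 3, 10,
                dimnames = list(c("B", "C", "A"), samples$sample_id))
  pos["A", 1:10] <- TRUE
  pos["B", 1:4] <- TRUE
  pos["C", 1:4] <- TRUE
  rk <- rank_by_frequency(pos, samples)
  expect_equal(rk$gene, c("A", "B", "C"))
  expect_equal(rk$n_positive_cases, c(10L, 4L, 4L))
  pos[] <- FALSE
  rk0 <- rank_by_frequency(pos, samples)
  expect_equal(rk0$gene, c("A", "B", "C"))   # alphabetical when all zero
  expect_true(all(rk0$n_positive_cases == 0))
})

test_that("z-scoring uses the sample SD and clustering is deterministic", {
  fold <- rbind(g1 = c(1, 2, 3), g2 = c(1, 2, 3) * 10,
                g3 = c(9, 1, 4), flat = c(5, 5, 5))
  colnames(fold) <- c("s1", "s2", "s3")
  cl <- zscore_and_cluster(fold)
  expect_equal(unname(cl$z["g1", ]), c(-1, 0, 1))  # SD of 1,2,3 is 1
  expect_equal(cl$flagged, "flat")
  expect_true(all(cl$z["flat", ] == 0))
  expect_equal(utils::tail(cl$row_order, 1), "flat")
  # identical rows have Pearson distance 0 and merge first
  d <- 1 - stats::cor(t(cl$z[c("g1", "g2"), ]))
  expect_equal(unname(d["g1", "g2"]), 0, tolerance = 1e-12)
  h <- stats::hclust(stats::as.dist(
    1 - stats::cor(t(cl$z[c("g1", "g2", "g3"), ]))), "average")
  expect_setequal(abs(h$merge[1, ]), c(1, 2))
  expect_identical(cl, zscore_and_cluster(fold))
  expect_error(zscore_and_cluster(fold[1, , drop = FALSE]), "at least 2")
})
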