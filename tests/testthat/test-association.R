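phen_matrix <- function(status, ids = names(status)) {
  matrix(status, ncol = 1, dimnames = list(ids, "P"))
}

test_that("KS association reproduces exact small-sample values", {
  fold <- matrix(c(1, 2, 3, 4, 5, 6), 1,
                 dimnames = list("G", sprintf("C%d", 1:6)))
  phen <- phen_matrix(c(C1 = 1, C2 = 1, C3 = 1, C4 = 0, C5 = 0, C6 = 0))
  res <- ks_association(fold, phen, "G", "P")
  # fully separated groups: D = 1; 2 of the C(6,3)=20 assignments reach it
  expect_equal(res$D, 1)
  expect_equal(res$p, 0.1, tolerance = 1e-12)
  expect_lt(res$direction, 0)   # with-group {1,2,3} has the lower mean
  # identical multisets in both groups
  fold2 <- matrix(rep(c(1, 2, 3), 2), 1,
                  dimnames = list("G", sprintf("C%d", 1:6)))
  res2 <- ks_association(fold2, phen, "G", "P")
  expect_equal(res2$D, 0, tolerance = 1e-12)
  expect_equal(res2$p, 1)
})

test_that("KS is invariant under strictly increasing transforms", {
  set.seed(5)
  vals <- stats::rlnorm(20, 1, 1)
  fold <- matrix(vals, 1, dimnames = list("G", sprintf("C%02d", 1:20)))
  phen <- phen_matrix(stats::setNames(rep(c(1, 0), each = 10),
                                      colnames(fold)))
  a <- ks_association(fold, phen, "G", "P")
  b <- ks_association(log(fold), phen, "G", "P")
  expect_equal(a$D, b$D)
  expect_equal(a$p, b$p)
})

test_that("small groups yield missing results, not errors", {
  fold <- matrix(1:6, 1, dimnames = list("G", sprintf("C%d", 1:6)))
  phen <- phen_matrix(c(C1 = 1, C2 = 0, C3 = 0, C4 = 0, C5 = 0, C6 = 0))
  res <- ks_association(fold, phen, "G", "P")
  expect_true(res$missing)
  expect_true(is.na(res$p))
  # missing phenotype values drop samples pairwise
  phen2 <- phen_matrix(c(C1 = 1, C2 = 1, C3 = 1, C4 = 0, C5 = 0,
                         C6 = NA))
  res2 <- ks_association(fold, phen2, "G", "P", min_group_size = 2)
  expect_equal(res2$n_without, 2L)
})

test_that("directional masking hides protective-direction significance", {
  assoc <- data.frame(
    gene = "G", phenotype = c("a", "b", "c"),
    p_raw = c(0.01, 0.01, 0.2), direction = c(-0.5, 0.5, -0.5))
  out <- directional_mask(assoc, alpha_mask = 0.05)
  expect_equal(out$p_masked, c(1, 0.01, 0.2))
  expect_equal(out$masked, c(TRUE, FALSE, FALSE))
  # masking never changes which entries have positive direction
  expect_identical(out$direction > 0, assoc$direction > 0)
})

test_that("association screen recovers a planted phenotype link", {
  s <- small_study(seed = 41L)
  enr <- enrichment_pipeline(s$counts, s$library, s$samples)
  planted <- s$truth$antigen_genes[1]   # linked to PHEN01 at 0.9 / 0.05
  assoc <- association_screen(enr$gene, s$phenotypes,
                              genes = s$truth$antigen_genes)
  row <- assoc[assoc$gene == planted, ]
  expect_equal(row$phenotype[which.min(row$p_masked)], "PHEN01")
  m <- association_matrix(assoc)
  expect_equal(dim(m), c(length(s$truth$antigen_genes),
                         ncol(s$phenotypes)))
  expect_equal(m[planted, "PHEN01"],
               row$p_masked[row$phenotype == "PHEN01"])
})

test_that("permuting phenotype labels destroys a planted association", {
  s <- small_study(seed = 42L)
  enr <- enrichment_pipeline(s$counts, s$library, s$samples)
  planted <- s$truth$antigen_genes[1]
  phen <- s$phenotypes
  set.seed(1)
  ps <- replicate(100, {
    perm <- phen
    rownames(perm) <- sample(rownames(phen))
    ks_association(enr$gene, perm, planted, "PHEN01")$p
  })
  expect_gt(stats::median(ps, na.rm = TRUE), 0.1)
})

test_that("null phenotypes give calibrated raw p-values", {
  set.seed(17)
  n <- 39
  fold <- matrix(stats::rlnorm(n, 0, 1), 1,
                 dimnames = list("G", sprintf("C%02d", 1:n)))
  ps <- replicate(1000, {
    phen <- phen_matrix(stats::setNames(stats::rbinom(n, 1, 0.5),
                                        colnames(fold)))
    ks_association(fold, phen, "G", "P")$p
  })
  frac <- mean(ps < 0.05, na.rm = TRUE)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 1000) + 0.015)
})

test_that("degenerate screen inputs are handled explicitly", {
  fold <- matrix(1:6, 1, dimnames = list("G", sprintf("C%d", 1:6)))
  expect_error(association_screen(fold, matrix(nrow = 0, ncol = 0)),
               "empty phenotype")
  phen <- matrix(NA_integer_, 6, 1,
                 dimnames = list(sprintf("C%d", 1:6), "P"))
  out <- association_screen(fold, phen)
  expect_true(all(is.na(out$p_raw)))   # all-missing column stays missing
})

test_that("sex-specific phenotypes restrict the tested population", {
  n <- 12
  ids <- sprintf("C%02d", 1:n)
  fold <- matrix(c(rep(100, 4), rep(1, 8)), 1,
                 dimnames = list("G", ids))
  phen <- matrix(c(rep(1, 4), rep(0, 8)), ncol = 1,
                 dimnames = list(ids, "POI"))
  sex <- stats::setNames(rep(c("F", "M"), each = 6), ids)
  # restricted to females: only C01..C06 enter the test
  out <- association_screen(fold, phen, sex = sex,
                            sex_specific = c(POI = "F"))
  expect_equal(out$n_with + out$n_without, 6L)
  out_all <- association_screen(fold, phen)
  expect_equal(out_all$n_with + out_all$n_without, 12L)
})
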