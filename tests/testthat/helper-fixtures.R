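# Shared in-code fixtures for the unit tests.

# A hand-written 5-tile x 4-sample study: 2 genes, 1 mock sample.
tiny_library <- function() {
  data.frame(
    tile_id = c("t1", "t2", "t3", "t4", "t5"),
    gene = c("GA", "GA", "GA", "GB", "GB"),
    protein_id = c("PA", "PA", "PA", "PB", "PB"),
    start = c(1L, 25L, 49L, 1L, 25L),
    end = c(49L, 73L, 97L, 49L, 73L),
    tile_len = 49L, stringsAsFactors = FALSE)
}

tiny_counts <- function() {
  m <- matrix(c(100L, 200L, 300L, 150L, 250L,
                50L,  100L, 250L, 300L, 300L,
                10L,  20L,  30L,  15L,  25L,
                40L,  10L,  90L,  35L,  25L),
              nrow = 5,
              dimnames = list(c("t1", "t2", "t3", "t4", "t5"),
                              c("S1", "S2", "S3", "M1")))
  m
}

tiny_samples <- function() {
  data.frame(sample_id = c("S1", "S2", "S3", "M1"),
             role = c("case", "case", "control", "mock"),
             cohort = c("discovery", "discovery", "discovery", "none"),
             stringsAsFactors = FALSE)
}

small_study <- function(seed = 1L, ...) {
  cfg <- simulation_config(
    n_cases = 8L, n_controls = 6L, n_mock = 4L, reads_per_sample = 2e5,
    n_genes = 40L, tiles_per_gene_target = 5L, n_planted = 4L,
    reactive_cases_range = c(4L, 6L), seed = seed, ...)
  simulate_study(cfg)
}
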