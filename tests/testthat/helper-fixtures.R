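# Shared fixtures. Expensive artifacts (the default-scenario simulation and
# its full pipeline run) are computed once per test session and reused by
# every acceptance block.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (is.null(.fixture_cache[[key]])) assign(key, fn(), .fixture_cache)
  get(key, .fixture_cache)
}

# a small hand-checkable cohort: 6 SNP sites + 1 indel on two contigs,
# 4 individuals (diploid queen, diploid worker, haploid male, diploid queen)
toy_cohort <- function() {
  sites <- data.frame(
    contig = c("g001", "g001", "g001", "g001", "g002", "g002", "g002"),
    pos = c(5L, 9L, 12L, 20L, 3L, 7L, 11L),
    ref = c("A", "C", "G", "T", "A", "AT", "C"),
    alt = c("G", "T", "A", "C", "G", "A", "T"),
    stringsAsFactors = FALSE)
  individuals <- data.frame(
    individual_id = c("Q1", "W1", "M1", "Q2"),
    colony_id = c("c1", "c1", "c1", "c2"),
    caste = c("queen", "worker", "male", "queen"),
    nominal_species = c("ibericus", "ibericus", "structor", "structor"),
    ploidy = c(2L, 2L, 1L, 2L),
    stringsAsFactors = FALSE)
  a1 <- matrix(c(
    # Q1  W1  M1  Q2
      0L, 0L, 1L, 1L,   # site 1
      0L, 0L, 1L, 1L,   # site 2
      0L, 0L, 1L, 1L,   # site 3
      0L, 0L, NA, 1L,   # site 4 (M1 missing)
      0L, 0L, 0L, 0L,   # site 5 (monomorphic in calls)
      0L, 0L, 1L, 1L,   # site 6 (indel)
      0L, 0L, 1L, 0L),  # site 7 (ALT rare)
    nrow = 7, byrow = TRUE)
  a2 <- matrix(c(
      0L, 1L, 1L, 1L,
      0L, 1L, 1L, 1L,
      0L, 1L, 1L, 1L,
      0L, 1L, NA, 1L,
      0L, 0L, 0L, 0L,
      0L, 1L, 1L, 1L,
      0L, 0L, 1L, 0L),
    nrow = 7, byrow = TRUE)
  dp <- matrix(20L, 7, 4)
  gq <- matrix(60, 7, 4)
  new_cohort(sites, individuals, a1, a2, dp, gq)
}

# reduced scenario covering every caste path, fast enough for end-to-end tests
small_composition <- function() {
  data.frame(
    caste = c("worker", "worker", "male", "male", "queen", "queen",
              "egg", "egg", "spermatheca"),
    nominal_species = c("ibericus", "ibericus", "structor", "structor",
                        "ibericus", "structor", "structor", "ibericus",
                        "ibericus"),
    father_lineage = c("clonal", "wild", "clonal", "wild", "none", "none",
                       "clonal", "none", "clonal"),
    count = c(8L, 3L, 4L, 6L, 8L, 5L, 2L, 1L, 1L),
    stringsAsFactors = FALSE)
}

small_scenario <- function(seed = 7, ...) {
  sim_scenario(n_genes = 20, gene_length_codons = 150,
               composition = small_composition(), seed = seed, ...)
}

default_sim <- function() {
  memo("default_sim", function() simulate_cohort(sim_scenario(seed = 1)))
}

default_report <- function() {
  memo("default_report", function() {
    suppressMessages(
      run_pipeline(pipeline_config(scenario = sim_scenario(seed = 1),
                                   seed = 1)))
  })
}
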