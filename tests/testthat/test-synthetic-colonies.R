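test_that("degenerate limit: no divergence, no polymorphism", {
  sc <- small_scenario(seed = 3, fixed_diff_density = 0,
                       pi_s_targets = c(ibericus = 0, structor_wild = 0,
                                        structor_clonal = 0),
                       clonal_divergence = 0)
  pools <- suppressWarnings(build_species_pools(sc))
  expect_identical(pools$anc$ibericus, pools$anc$structor)
  for (ln in c("ibericus", "structor_wild", "structor_clonal")) {
    expect_equal(nrow(pools$lineages[[ln]]$vars), 0)
    expect_identical(pools$lineages[[ln]]$base, pools$anc$ibericus)
  }
})

test_that("realized fixed-difference count matches the binomial oracle", {
  # ~1e5 sites at density 0.02: expect within 3 SD of Binomial(L, 0.02)
  sc <- sim_scenario(n_genes = 112, gene_length_codons = 300,
                     composition = small_composition(), seed = 11)
  pools <- build_species_pools(sc)
  L <- 112 * 300 * 3
  n_fixed <- sum(pools$anc$ibericus != pools$anc$structor)
  expect_lt(abs(n_fixed - 0.02 * L), 3 * sqrt(L * 0.02 * 0.98))
})

test_that("F1 workers are heterozygous at every interspecific fixed difference", {
  sim <- simulate_cohort(small_scenario(seed = 5))
  co <- sim$cohort
  fixed_pos <- which(sim$pools$anc$ibericus != sim$pools$anc$structor)
  gl <- sim$pools$gene_length
  global_pos <- (match(co$sites$contig, sim$pools$gene_ids) - 1L) * gl +
    co$sites$pos
  at_fixed <- global_pos %in% fixed_pos
  workers <- sim$truth$individual_id[sim$truth$true_class %in% "F1"]
  for (w in workers) {
    i <- match(w, co$individuals$individual_id)
    expect_true(all(co$a1[at_fixed, i] != co$a2[at_fixed, i]),
                label = paste(w, "het at all fixed differences"))
  }
})

test_that("males are haploid and clonal males carry the host mitochondria", {
  sim <- default_sim()
  tr <- sim$truth
  males <- tr$individual_id[sim$cohort$individuals$caste == "male"]
  expect_true(all(sim$cohort$individuals$ploidy[
    sim$cohort$individuals$individual_id %in% males] == 1))
  clonal_males <- tr$individual_id[tr$true_class %in% "pure_paternal" &
                                     tr$true_father_lineage %in% "clonal"]
  expect_equal(length(clonal_males), 24)
  expect_true(all(tr$true_mito_species[tr$individual_id %in% clonal_males] ==
                    "ibericus"))
  expect_identical(unname(sim$mito[clonal_males[1]]),
                   unname(sim$mito[["REF_ibericus"]]))
  wild_males <- tr$individual_id[tr$true_father_lineage %in% "none" &
    sim$cohort$individuals$caste[match(tr$individual_id,
      sim$cohort$individuals$individual_id)] == "male"]
  expect_true(all(tr$true_mito_species[tr$individual_id %in% wild_males] ==
                    "structor"))
})

test_that("composition requesting an empty pool errors", {
  sc <- small_scenario(seed = 2,
                       n_haplotypes = c(ibericus = 40L, structor_wild = 40L,
                                        structor_clonal = 0L))
  pools <- suppressWarnings(build_species_pools(sc))
  expect_error(simulate_individuals(sc, pools), "empty")
})

test_that("fixed seed gives a byte-identical VCF", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_scenario(simulate_cohort(small_scenario(seed = 9)), d1)
  write_scenario(simulate_cohort(small_scenario(seed = 9)), d2)
  expect_identical(readLines(file.path(d1, "cohort.vcf")),
                   readLines(file.path(d2, "cohort.vcf")))
  # and a different seed gives a different cohort
  d3 <- withr::local_tempdir()
  write_scenario(simulate_cohort(small_scenario(seed = 10)), d3)
  expect_false(identical(readLines(file.path(d1, "cohort.vcf")),
                         readLines(file.path(d3, "cohort.vcf"))))
})

test_that("scenario files round-trip through write/read", {
  sc <- small_scenario(seed = 4)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_scenario_config(sc, path)
  sc2 <- read_scenario_config(path)
  expect_identical(sc2$composition, sc$composition)
  expect_equal(sc2$pi_s_targets, sc$pi_s_targets)
  expect_equal(sc2$seed, sc$seed)
  expect_equal(sc2$n_genes, sc$n_genes)
})

test_that("written scenario directory reloads into an equivalent cohort", {
  sim <- simulate_cohort(small_scenario(seed = 6))
  dir <- withr::local_tempdir()
  write_scenario(sim, dir)
  co2 <- read_cohort(file.path(dir, "cohort.vcf"), file.path(dir, "meta.tsv"))
  expect_equal(co2$a1, sim$cohort$a1, ignore_attr = TRUE)
  expect_equal(co2$a2, sim$cohort$a2, ignore_attr = TRUE)
  expect_equal(co2$individuals$ploidy, sim$cohort$individuals$ploidy)
  ref <- Biostrings::readBStringSet(file.path(dir, "reference.fasta"))
  expect_equal(as.character(ref[["g001"]]), sim$reference[["g001"]])
})

test_that("truth table covers every individual with consistent classes", {
  sim <- default_sim()
  tr <- sim$truth
  expect_setequal(tr$individual_id, sim$cohort$individuals$individual_id)
  expect_equal(sum(tr$true_class %in% "F1"), 164)
  expect_equal(sum(tr$true_father_lineage %in% "clonal" &
                     tr$true_class %in% "F1"), 144)
  expect_equal(sum(tr$true_father_lineage %in% "wild" &
                     tr$true_class %in% "F1"), 20)
  # F1s carry exactly one haplotype from each species pool
  f1 <- tr[tr$true_class %in% "F1", ]
  expect_true(all(grepl("^ibericus", f1$maternal_hap)))
  expect_true(all(grepl("^structor", f1$paternal_hap)))
})
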