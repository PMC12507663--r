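# independent scalar transcription of the published rule table, in priority
# order: depth -> missing -> reference het -> hybrid het match -> shared hom
phase_oracle <- function(h1, h2, m1, m2, dh, dm, min_depth = 3) {
  if (dh < min_depth || dm < min_depth) return(c("N", "N", "LOW_DEPTH"))
  if (is.na(h1) || is.na(m1)) return(c("N", "N", "MISSING"))
  if (m1 != m2) return(c("N", "N", "MAT_REF_HET"))
  if (h1 != h2) {
    if (m1 == h1) return(c(h1, h2, "HET_MATCH"))
    if (m1 == h2) return(c(h2, h1, "HET_MATCH"))
    return(c("N", "N", "NO_MATCH"))
  }
  if (h1 == m1) return(c(h1, h1, "HOM_SHARED"))
  c("N", "N", "NO_MATCH")
}

test_that("phase_site equals the rule-table oracle on exhaustive enumeration", {
  alleles <- c("A", "G", "T", NA)
  combos <- expand.grid(h1 = alleles, h2 = alleles, m1 = alleles,
                        m2 = alleles, dh = c(2, 3), dm = c(2, 10),
                        stringsAsFactors = FALSE)
  # a call is either fully present or fully missing
  combos <- combos[is.na(combos$h1) == is.na(combos$h2) &
                     is.na(combos$m1) == is.na(combos$m2), ]
  for (k in seq_len(nrow(combos))) {
    cb <- combos[k, ]
    got <- phase_site(list(alleles = c(cb$h1, cb$h2), depth = cb$dh),
                      list(alleles = c(cb$m1, cb$m2), depth = cb$dm))
    want <- phase_oracle(cb$h1, cb$h2, cb$m1, cb$m2, cb$dh, cb$dm)
    expect_identical(c(got$maternal_allele, got$paternal_allele,
                       got$rule_applied), want,
                     label = paste(unlist(cb), collapse = "/"))
  }
})

test_that("phase_individual is monotone in min_depth", {
  sim <- simulate_cohort(small_scenario(seed = 21, depth_mean = 4))
  panel <- filter_sites(sim$cohort)
  f1 <- classify_f1(het_profiles(panel))
  ref <- select_maternal_reference(sim$cohort, "ibericus", f1)
  hyb <- sim$truth$individual_id[sim$truth$true_class %in% "F1"][1]
  p3 <- phase_individual(sim$cohort, hyb, ref, min_depth = 3)
  p6 <- phase_individual(sim$cohort, hyb, ref, min_depth = 6)
  a3 <- p3$maternal_allele != "N"
  a6 <- p6$maternal_allele != "N"
  expect_true(all(which(a6) %in% which(a3)))
  expect_lte(attr(p6, "assigned_fraction"), attr(p3, "assigned_fraction"))
  # where both assign, they agree
  both <- a3 & a6
  expect_identical(p3$paternal_allele[both], p6$paternal_allele[both])
})

test_that("an F1-flagged maternal reference is rejected", {
  sim <- simulate_cohort(small_scenario(seed = 22))
  panel <- filter_sites(sim$cohort)
  f1 <- classify_f1(het_profiles(panel))
  hybs <- f1$individual_id[f1$is_f1]
  expect_error(phase_individual(sim$cohort, hybs[1], hybs[2], f1_calls = f1),
               "F1")
})

test_that("paternal haplomes have zero errors at assigned sites (error-free sim)", {
  # The zero-error guarantee requires a monomorphic maternal reference: at a
  # site where the mother carries a private maternal-species variant, the
  # homozygous-reference rule necessarily assigns the reference allele as
  # maternal. With the maternal species monomorphic the guarantee is exact.
  sim <- simulate_cohort(small_scenario(
    seed = 23, pi_s_targets = c(ibericus = 0, structor_wild = 0.0014,
                                structor_clonal = 0.00027)))
  panel <- filter_sites(sim$cohort)
  f1 <- classify_f1(het_profiles(panel))
  ref <- select_maternal_reference(sim$cohort, "ibericus", f1)
  gl <- sim$pools$gene_length
  tr <- sim$truth
  hybs <- tr$individual_id[tr$true_class %in% "F1"]
  for (hyb in hybs[1:4]) {
    ph <- phase_individual(sim$cohort, hyb, ref)
    hap <- tr$paternal_hap[tr$individual_id == hyb]
    lineage <- sub("_h\\d+$", "", hap)
    hnum <- as.integer(sub("^.*_h", "", hap))
    true_chars <- xenopop:::haplotype_chars(sim$pools, lineage, hnum)
    gpos <- (match(ph$contig, sim$pools$gene_ids) - 1L) * gl + ph$pos
    assigned <- ph$rule == "HET_MATCH"
    expect_gt(sum(assigned), 0)
    expect_identical(ph$paternal_allele[assigned], true_chars[gpos[assigned]],
                     label = paste("paternal alleles of", hyb))
  }
})

test_that("haplome sequences substitute phased alleles into the backbone", {
  sim <- simulate_cohort(small_scenario(seed = 24))
  panel <- filter_sites(sim$cohort)
  f1 <- classify_f1(het_profiles(panel))
  ref <- select_maternal_reference(sim$cohort, "ibericus", f1)
  hyb <- f1$individual_id[f1$is_f1][1]
  ph <- phase_individual(sim$cohort, hyb, ref)
  hp <- build_haplome_sequences(ph, sim$reference)
  expect_named(hp, c("maternal", "paternal"))
  expect_equal(hp$paternal$role, "paternal")
  # spot-check one HET_MATCH site
  i <- which(ph$rule == "HET_MATCH")[1]
  g <- ph$contig[i]
  expect_equal(substr(hp$paternal$gene_sequences[[g]], ph$pos[i], ph$pos[i]),
               ph$paternal_allele[i])
  expect_equal(substr(hp$maternal$gene_sequences[[g]], ph$pos[i], ph$pos[i]),
               ph$maternal_allele[i])
  # strict mode masks HOM_SHARED sites to N
  hs <- build_haplome_sequences(ph, sim$reference, strict = TRUE)
  j <- which(ph$rule == "HOM_SHARED")[1]
  gj <- ph$contig[j]
  expect_equal(substr(hs$paternal$gene_sequences[[gj]], ph$pos[j], ph$pos[j]),
               "N")
})

test_that("genes above the gap threshold are dropped", {
  sim <- simulate_cohort(small_scenario(seed = 25))
  panel <- filter_sites(sim$cohort)
  f1 <- classify_f1(het_profiles(panel))
  ref <- select_maternal_reference(sim$cohort, "ibericus", f1)
  hyb <- f1$individual_id[f1$is_f1][1]
  ph <- phase_individual(sim$cohort, hyb, ref)
  hp <- build_haplome_sequences(ph, sim$reference, max_gap_fraction = 0)
  # with zero tolerance every gene containing any N must be dropped
  kept <- names(hp$paternal$gene_sequences)
  for (g in kept) expect_false(grepl("N", hp$paternal$gene_sequences[[g]]))
})

test_that("consensus sequences mask het and low-depth calls", {
  co <- toy_cohort()
  backbone <- c(g001 = paste(rep("A", 25), collapse = ""),
                g002 = paste(rep("C", 15), collapse = ""))
  co$dp[1, 1] <- 1L   # Q1 low depth at g001:5
  cs <- consensus_sequence(co, "Q1", backbone)
  expect_equal(substr(cs$gene_sequences[["g001"]], 5, 5), "-")
  # W1 het at g001:9 -> N
  cw <- consensus_sequence(co, "W1", backbone)
  expect_equal(substr(cw$gene_sequences[["g001"]], 9, 9), "N")
  # M1 hom ALT at g001:12 -> ALT nucleotide substituted
  cm <- consensus_sequence(co, "M1", backbone)
  expect_equal(substr(cm$gene_sequences[["g001"]], 12, 12), "A")
  # M1 missing at g001:20 -> N
  expect_equal(substr(cm$gene_sequences[["g001"]], 20, 20), "N")
})

test_that("select_maternal_reference picks the deepest non-hybrid queen", {
  co <- toy_cohort()
  co$dp[, 4] <- 40L   # Q2 deepest, but wrong species
  expect_equal(select_maternal_reference(co, "ibericus"), "Q1")
  expect_equal(select_maternal_reference(co, "structor"), "Q2")
  f1 <- data.frame(individual_id = c("Q1", "W1"), is_f1 = c(TRUE, TRUE))
  expect_error(select_maternal_reference(co, "ibericus", f1), "queen")
})
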