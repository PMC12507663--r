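test_that("het_proportion counts heterozygous calls over the panel", {
  co <- toy_cohort()
  # W1 is heterozygous at sites 1,2,3,4,6; panel has 7 sites
  p <- het_proportion(co, "W1")
  expect_equal(p$het_sites, 5)
  expect_equal(p$panel_size, 7)
  expect_equal(p$het_proportion, 5 / 7)
  # per-called-sites denominator for a partially missing individual
  p2 <- het_proportion(co, "M1", denominator = "called")
  expect_equal(p2$het_proportion, 0)
})

test_that("haploids get het 0 with a ploidy note", {
  co <- toy_cohort()
  p <- het_proportion(co, "M1")
  expect_equal(p$het_proportion, 0)
  expect_match(p$note, "haploid")
})

test_that("classify_f1 matches the exhaustive split oracle on 4 values", {
  prof <- data.frame(individual_id = c("a", "b", "c", "d"),
                     het_proportion = c(0.80, 0.79, 0.05, 0.04))
  # oracle: evaluate every split point of the sorted values by hand
  v <- sort(prof$het_proportion)          # 0.04 0.05 0.79 0.80
  expect_equal(which.max(diff(v)), 2)     # largest gap after the 2nd value
  out <- classify_f1(prof)
  expect_equal(out$is_f1[match(c("a", "b", "c", "d"), out$individual_id)],
               c(TRUE, TRUE, FALSE, FALSE))
})

test_that("a mid-value individual joins the upper cluster", {
  prof <- data.frame(
    individual_id = sprintf("i%02d", 1:9),
    het_proportion = c(0.81, 0.80, 0.79, 0.78, 0.58, 0.06, 0.05, 0.04, 0.03))
  out <- classify_f1(prof)
  expect_true(out$is_f1[out$individual_id == "i05"])
  expect_equal(sum(out$is_f1), 5)
})

test_that("no separation -> no flags", {
  prof <- data.frame(individual_id = c("a", "b", "c"),
                     het_proportion = c(0.05, 0.05, 0.05))
  expect_warning(out <- classify_f1(prof), "identical")
  expect_false(any(out$is_f1))
  # separated but below the min_separation guard
  prof2 <- data.frame(individual_id = c("a", "b", "c", "d"),
                      het_proportion = c(0.10, 0.11, 0.19, 0.20))
  expect_false(any(classify_f1(prof2)$is_f1))
})

# build a well-specified two-source cohort: each allele copy drawn from
# q*p_M + (1-q)*p_P at sites with known source frequencies
make_admixture_cohort <- function(q, n_sites, seed) {
  set.seed(seed)
  pm <- runif(n_sites, 0.05, 0.95)   # ALT frequency in the maternal source
  pp <- runif(n_sites, 0.05, 0.95)   # ALT frequency in the paternal source
  mk <- function(p_of_alt) list(a1 = as.integer(runif(n_sites) < p_of_alt),
                                a2 = as.integer(runif(n_sites) < p_of_alt))
  # source pools: 30 maternal + 30 paternal reference individuals
  ids <- c(sprintf("M%02d", 1:30), sprintf("P%02d", 1:30), "X")
  n <- length(ids)
  a1 <- matrix(NA_integer_, n_sites, n); a2 <- a1
  for (j in 1:30) { g <- mk(pm); a1[, j] <- g$a1; a2[, j] <- g$a2 }
  for (j in 31:60) { g <- mk(pp); a1[, j] <- g$a1; a2[, j] <- g$a2 }
  mix <- q * pm + (1 - q) * pp                           # ALT freq of admixed
  g <- mk(mix); a1[, 61] <- g$a1; a2[, 61] <- g$a2
  sites <- data.frame(contig = "c1", pos = seq_len(n_sites),
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  meta <- data.frame(individual_id = ids, colony_id = "c",
                     caste = "queen", nominal_species =
                       c(rep("ibericus", 30), rep("structor", 30), "ibericus"),
                     ploidy = 2L, stringsAsFactors = FALSE)
  co <- new_cohort(sites, meta, a1, a2,
                   matrix(20L, n_sites, n), matrix(60, n_sites, n))
  # use the TRUE source frequencies so the oracle is exact
  floor <- 1e-3
  list(cohort = co,
       sf = list(maternal = pmin(pmax(cbind(1 - pm, pm), floor), 1 - floor),
                 paternal = pmin(pmax(cbind(1 - pp, pp), floor), 1 - floor),
                 floor = floor))
}

test_that("estimate_ancestry recovers planted q within 0.02 at 1e4 sites", {
  for (q in c(0, 0.25, 0.5, 0.75, 1)) {
    fix <- make_admixture_cohort(q, 10000, seed = round(100 * q) + 17)
    est <- estimate_ancestry(fix$cohort, "X", fix$sf)
    expect_lt(abs(est$q_maternal - q), 0.02, label = paste("q =", q))
  }
})

test_that("estimate_ancestry agrees with an independent grid-search oracle", {
  fix <- make_admixture_cohort(0.37, 800, seed = 41)
  est <- estimate_ancestry(fix$cohort, "X", fix$sf)
  # oracle: direct grid evaluation of the same likelihood
  i <- which(fix$cohort$individuals$individual_id == "X")
  carried <- c(fix$cohort$a1[, i], fix$cohort$a2[, i])
  pm <- rbind(fix$sf$maternal, fix$sf$maternal)[cbind(seq_along(carried),
                                                      carried + 1L)]
  pp <- rbind(fix$sf$paternal, fix$sf$paternal)[cbind(seq_along(carried),
                                                      carried + 1L)]
  grid <- seq(0, 1, by = 1e-4)
  ll <- vapply(grid, function(q) sum(log(q * pm + (1 - q) * pp)), numeric(1))
  expect_lt(abs(est$q_maternal - grid[which.max(ll)]), 2e-4)
})

test_that("boundary and symmetry cases on a fixed-difference-only panel", {
  sim <- simulate_cohort(small_scenario(seed = 12))
  panel <- filter_sites(sim$cohort)
  meta <- sim$cohort$individuals
  tr <- sim$truth
  mids <- meta$individual_id[meta$caste == "queen" &
                               meta$nominal_species == "ibericus"]
  pids <- meta$individual_id[meta$caste %in% c("queen", "male") &
                               meta$nominal_species == "structor"]
  dg <- fixed_difference_sites(panel, mids, pids)
  keep <- paste(panel$sites$contig, panel$sites$pos) %in%
    paste(dg$contig, dg$pos)
  ap <- xenopop:::subset_sites(panel, keep)
  sf <- source_allele_freqs(ap, mids, pids)
  # pure maternal individual -> q = 1
  expect_equal(estimate_ancestry(ap, mids[1], sf)$q_maternal, 1)
  # error-free F1 -> q = 0.5 by symmetry
  f1 <- tr$individual_id[tr$true_class %in% "F1"][1]
  expect_equal(estimate_ancestry(ap, f1, sf)$q_maternal, 0.5, tolerance = 1e-3)
})

test_that("uninformative panel errors", {
  co <- toy_cohort()
  sf <- list(maternal = matrix(0.5, 7, 2), paternal = matrix(0.5, 7, 2),
             floor = 1e-3)
  expect_error(estimate_ancestry(co, "W1", sf), "uninformative")
})

test_that("compare_groups matches an exact Wilcoxon enumeration", {
  a <- c(1.1, 2.3, 3.1)
  b <- c(0.2, 0.4)
  p <- compare_groups(a, b)
  # oracle: enumerate all choose(5,3) assignments of the pooled values
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[1:3]) - 3 * 4 / 2
  combs <- utils::combn(5, 3)
  w_all <- apply(combs, 2, function(ix) sum(r[ix]) - 6)
  p_exact <- mean(abs(w_all - 3) >= abs(w_obs - 3))  # E[W] = n1*n2/2 = 3
  expect_equal(p, p_exact)
  expect_error(compare_groups(numeric(0), b), "non-empty")
})
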