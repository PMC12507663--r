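rand_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_at <- function(s, pos) {
  ch <- strsplit(s, "")[[1]]
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  paste(ch, collapse = "")
}

test_that("p_distance counts mismatches over jointly callable sites", {
  s <- rand_seq(300, 1)
  expect_equal(p_distance(s, s)$distance, 0)
  s2 <- mutate_at(s, c(10, 20, 30))
  d <- p_distance(s, s2)
  expect_equal(d$distance, 3 / 300)
  expect_equal(d$overlap, 300)
  # N and gap positions are excluded from numerator and denominator
  s3 <- s2
  substr(s3, 10, 10) <- "N"
  substr(s3, 50, 50) <- "-"
  d3 <- p_distance(s, s3)
  expect_equal(d3$overlap, 298)
  expect_equal(d3$distance, 2 / 298)
  # insufficient overlap -> distance undefined
  short <- p_distance(substr(s, 1, 80), substr(s2, 1, 80))
  expect_true(is.na(short$distance))
})

test_that("p_distance_matrix agrees with pairwise p_distance", {
  base <- rand_seq(400, 2)
  seqs <- list(a = base, b = mutate_at(base, 1:4), c = mutate_at(base, 5:10))
  dm <- p_distance_matrix(seqs)
  expect_s3_class(dm, "DistanceMatrix")
  for (i in c("a", "b", "c")) for (j in c("a", "b", "c")) {
    want <- if (i == j) 0 else p_distance(seqs[[i]], seqs[[j]])$distance
    expect_equal(dm$values[i, j], want, label = paste(i, j))
  }
  expect_equal(unname(dm$pairwise_overlap["a", "b"]), 400)
})

test_that("nj_tree recovers an additive 4-taxon tree exactly", {
  # tree ((A:1,B:2):3,(C:4,D:5)) -> additive distances
  labs <- c("A", "B", "C", "D")
  v <- matrix(0, 4, 4, dimnames = list(labs, labs))
  v["A", "B"] <- v["B", "A"] <- 3
  v["A", "C"] <- v["C", "A"] <- 8
  v["A", "D"] <- v["D", "A"] <- 9
  v["B", "C"] <- v["C", "B"] <- 9
  v["B", "D"] <- v["D", "B"] <- 10
  v["C", "D"] <- v["D", "C"] <- 9
  dm <- structure(list(labels = labs, values = v,
                       pairwise_overlap = matrix(1000, 4, 4,
                                                 dimnames = list(labs, labs))),
                  class = "DistanceMatrix")
  tr <- nj_tree(dm)
  expect_s3_class(tr, "phylo")
  path <- ape::cophenetic.phylo(tr)[labs, labs]
  expect_equal(path, v, tolerance = 1e-10)
})

test_that("nj_tree clamps negative branch lengths to zero", {
  labs <- c("A", "B", "C", "D")
  v <- matrix(c(0, 1, 1, 3,
                1, 0, 1, 3,
                1, 1, 0, 3,
                3, 3, 3, 0), 4, 4, dimnames = list(labs, labs))
  dm <- structure(list(labels = labs, values = v,
                       pairwise_overlap = matrix(1000, 4, 4)),
                  class = "DistanceMatrix")
  tr <- nj_tree(dm)
  expect_true(all(tr$edge.length >= 0))
})

test_that("nearest-panel assignment, margins and ties", {
  base <- rand_seq(300, 3)
  pA <- list(mutate_at(base, 101:104))
  pB <- list(mutate_at(base, 201:208))
  # query identical to the base: closer to panel A
  r <- assign_by_nearest_panel(base, list(A = pA, B = pB),
                               n_bootstrap = 200, query_id = "q")
  expect_equal(r$assigned_group, "A")
  expect_equal(unname(r$panel_distances["A"]), 4 / 300)
  expect_equal(unname(r$margin), 4 / 300)
  expect_gt(r$support, 0.9)
  # exactly equidistant panels -> unassigned
  pB2 <- list(mutate_at(base, 201:204))
  r2 <- assign_by_nearest_panel(base, list(A = pA, B = pB2), n_bootstrap = 0)
  expect_equal(r2$assigned_group, "unassigned")
  # min_margin above the gap -> unassigned
  r3 <- assign_by_nearest_panel(base, list(A = pA, B = pB),
                                n_bootstrap = 0, min_margin = 0.05)
  expect_equal(r3$assigned_group, "unassigned")
})

test_that("mito assignment and mismatch flags", {
  m_ib <- rand_seq(200, 4)
  m_st <- mutate_at(m_ib, seq(1, 200, by = 10))
  refs <- list(ibericus = m_ib, structor = m_st)
  q <- mutate_at(m_ib, 7)       # one private mutation off the ibericus type
  r <- assign_mito(q, refs, n_bootstrap = 100)
  expect_equal(r$assigned_group, "ibericus")
  nuc <- list(assigned_group = "structor")
  flag <- detect_mito_nuclear_mismatch(nuc, r, individual_id = "x")
  expect_true(flag$is_mismatch)
  flag2 <- detect_mito_nuclear_mismatch(list(assigned_group = "structor"),
                                        list(assigned_group = "structor"))
  expect_false(flag2$is_mismatch)
  flag3 <- detect_mito_nuclear_mismatch(list(assigned_group = "unassigned"),
                                        r)
  expect_true(is.na(flag3$is_mismatch))
})

test_that("detect_clonal_cluster matches a union-find single-linkage oracle", {
  base <- rand_seq(1000, 5)
  # clonal cluster: 4 near-identical sequences; wild: 4 spread sequences
  seqs <- list(c1 = base, c2 = mutate_at(base, 1),
               c3 = mutate_at(base, 2), c4 = mutate_at(base, 3),
               w1 = mutate_at(base, 101:115), w2 = mutate_at(base, 201:218),
               w3 = mutate_at(base, 301:314), w4 = mutate_at(base, 401:416))
  h <- 0.012
  cl <- detect_clonal_cluster(seqs, max_intra_distance = h)
  # oracle: union-find over all pairs with distance <= h
  ids <- names(seqs)
  parent <- as.list(stats::setNames(ids, ids))
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in ids) for (j in ids) {
    if (i < j && p_distance(seqs[[i]], seqs[[j]])$distance <= h)
      parent[[find(i)]] <- find(j)
  }
  comp <- vapply(ids, find, character(1))
  expect_equal(length(unique(comp[paste0("c", 1:4)])), 1)
  got <- cl$membership
  expect_equal(length(unique(got[paste0("c", 1:4)])), 1)
  # same partition as the union-find components
  expect_equal(unname(as.integer(factor(comp, levels = unique(comp)))),
               unname(as.integer(factor(got[ids],
                                        levels = unique(got[ids])))))
  # the clonal cluster is the tight multi-member one
  expect_setequal(names(got)[got == cl$clonal_cluster], paste0("c", 1:4))
})

test_that("classify_embryo separates androgenetic, hybrid and maternal eggs", {
  sim <- simulate_cohort(small_scenario(seed = 26))
  panel <- filter_sites(sim$cohort)
  meta <- sim$cohort$individuals
  mids <- meta$individual_id[meta$caste == "queen" &
                               meta$nominal_species == "ibericus"]
  pids <- meta$individual_id[meta$caste %in% c("male", "queen") &
                               meta$nominal_species == "structor"]
  dg <- fixed_difference_sites(panel, mids, pids)
  expect_gt(nrow(dg), 20)
  tr <- sim$truth
  eggs <- meta$individual_id[meta$caste == "egg"]
  expect_gt(length(eggs), 0)
  for (e in eggs) {
    cls <- classify_embryo(sim$cohort, e, dg)
    truth_cls <- tr$true_class[tr$individual_id == e]
    want <- c(pure_paternal = "paternal_only", pure_maternal = "maternal_only",
              F1 = "hybrid")[[truth_cls]]
    expect_equal(cls$class, want, label = e)
  }
  # too few called sites -> indeterminate
  few <- dg[1:3, ]
  expect_equal(classify_embryo(sim$cohort, eggs[1], few)$class,
               "indeterminate")
})
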