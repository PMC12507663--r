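# Synthetic colony generator: two species diverged by fixed differences, each
# lineage carrying within-lineage polymorphism calibrated to a synonymous
# diversity target, F1 hybrid workers, a near-monomorphic clonal male lineage
# carrying the host species' mitochondria, haploid males, eggs and spermatheca
# mixtures -- with a planted truth table for every individual.

LINEAGES <- c("ibericus", "structor_wild", "structor_clonal")
LINEAGE_SPECIES <- c(ibericus = "ibericus", structor_wild = "structor",
                     structor_clonal = "structor")

#' Default cohort composition
#'
#' Mirrors the study's sampling: 164 F1 workers (144 clonal-sired, 20
#' wild-sired), 24 clonal males, 53 wild-type males in their own colonies and
#' 127 non-hybrid diploid controls.
#'
#' @return data.frame with columns `caste`, `nominal_species`,
#'   `father_lineage`, `count`.
#' @export
default_composition <- function() {
  data.frame(
    caste = c("worker", "worker", "male", "male", "queen", "queen"),
    nominal_species = c("ibericus", "ibericus", "structor", "structor",
                        "ibericus", "structor"),
    father_lineage = c("clonal", "wild", "clonal", "wild", "none", "none"),
    count = c(144L, 20L, 24L, 53L, 100L, 27L),
    stringsAsFactors = FALSE)
}

#' Define a simulation scenario
#'
#' Generative parameters of the synthetic cohort. Diversity targets default to
#' the study system's lineage-level estimates (synonymous diversity 0.00045
#' for the maternal species, 0.0014 for the wild paternal lineage, 0.00027 for
#' the clonal male lineage; nonsynonymous/synonymous ratios 0.21 wild vs 0.43
#' clonal).
#'
#' @param n_genes number of codon-aligned genes.
#' @param gene_length_codons codons per gene.
#' @param fixed_diff_density per-site probability of an interspecific fixed
#'   difference.
#' @param pi_s_targets named numeric, synonymous diversity per lineage.
#' @param pi_n_over_pi_s_targets named numeric, pi_n/pi_s per lineage.
#' @param clonal_divergence per-site divergence of the clonal lineage's base
#'   haplotype from the wild paternal-species ancestor.
#' @param composition data.frame as [default_composition()].
#' @param n_haplotypes named integer, pool size per lineage.
#' @param mito_length,mito_divergence mitochondrial haplotype length and
#'   between-species per-site divergence.
#' @param depth_mean expected per-call read depth (Poisson).
#' @param quality_model named numeric `c(mean=, sd=)` for per-call genotype
#'   quality (rounded normal, floored at 0).
#' @param genotype_error per-allele-copy symmetric flip probability (0 = off).
#' @param seed integer seed; a fixed seed makes every output reproducible.
#' @return an object of class `SimScenario`.
#' @export
sim_scenario <- function(n_genes = 100, gene_length_codons = 300,
                         fixed_diff_density = 0.02,
                         pi_s_targets = c(ibericus = 0.00045,
                                          structor_wild = 0.0014,
                                          structor_clonal = 0.00027),
                         pi_n_over_pi_s_targets = c(ibericus = 0.21,
                                                    structor_wild = 0.21,
                                                    structor_clonal = 0.43),
                         clonal_divergence = 0.005,
                         composition = default_composition(),
                         n_haplotypes = c(ibericus = 40L, structor_wild = 40L,
                                          structor_clonal = 40L),
                         mito_length = 2000, mito_divergence = 0.05,
                         depth_mean = 20, quality_model = c(mean = 60, sd = 10),
                         genotype_error = 0, seed = 1) {
  probs <- c(fixed_diff_density, clonal_divergence, mito_divergence,
             genotype_error, pi_s_targets)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  stopifnot(all(LINEAGES %in% names(pi_s_targets)),
            all(LINEAGES %in% names(pi_n_over_pi_s_targets)),
            all(LINEAGES %in% names(n_haplotypes)),
            all(composition$count >= 0),
            n_genes >= 1, gene_length_codons >= 2, depth_mean > 0)
  structure(list(
    n_genes = as.integer(n_genes),
    gene_length_codons = as.integer(gene_length_codons),
    fixed_diff_density = fixed_diff_density,
    pi_s_targets = pi_s_targets,
    pi_n_over_pi_s_targets = pi_n_over_pi_s_targets,
    clonal_divergence = clonal_divergence,
    composition = composition,
    n_haplotypes = as.integer(n_haplotypes[LINEAGES]) |> stats::setNames(LINEAGES),
    mito_length = as.integer(mito_length),
    mito_divergence = mito_divergence,
    depth_mean = depth_mean,
    quality_model = quality_model,
    genotype_error = genotype_error,
    seed = as.integer(seed)), class = "SimScenario")
}

#' @export
print.SimScenario <- function(x, ...) {
  cat("SimScenario:", x$n_genes, "genes x", x$gene_length_codons, "codons;",
      sum(x$composition$count), "individuals; seed", x$seed, "\n")
  invisible(x)
}

# substitute bases at the given (global) positions, sampling a replacement of
# the requested class among changes that keep the codon a sense codon
mutate_sites <- function(seqvec, positions, class = c("any", "syn", "nonsyn")) {
  class <- match.arg(class)
  for (pos in positions) {
    ci <- (pos - 1L) %/% 3L
    off <- (pos - 1L) %% 3L + 1L
    codon <- paste(seqvec[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
    cand <- switch(class,
      any = c(codon_env$SYN_SUBS[[codon]][[off]],
              codon_env$NONSYN_SUBS[[codon]][[off]]),
      syn = codon_env$SYN_SUBS[[codon]][[off]],
      nonsyn = codon_env$NONSYN_SUBS[[codon]][[off]])
    if (!length(cand)) next
    seqvec[pos] <- if (length(cand) == 1) cand else sample(cand, 1)
  }
  seqvec
}

# draw singleton variants of one class for a lineage pool; each variant sits
# on exactly one haplotype, so its expected pairwise-diversity contribution is
# 2/n_hap per site
# `exclude`: positions that must stay intact (interspecific fixed
# differences; mutating one would silently undo a planted species marker)
draw_variants <- function(base, lambda, n_hap, class, exclude = integer(0)) {
  n <- stats::rpois(1, lambda)
  if (n == 0)
    return(data.frame(hap = integer(0), pos = integer(0), base = character(0),
                      class = character(0), stringsAsFactors = FALSE))
  L <- length(base)
  pos <- integer(n); nb <- character(n)
  for (k in seq_len(n)) {
    for (tries in 1:1000) {
      p <- sample.int(L, 1)
      if (p %in% exclude) next
      ci <- (p - 1L) %/% 3L
      off <- (p - 1L) %% 3L + 1L
      codon <- paste(base[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
      cand <- if (class == "syn") codon_env$SYN_SUBS[[codon]][[off]]
              else codon_env$NONSYN_SUBS[[codon]][[off]]
      if (length(cand)) {
        pos[k] <- p
        nb[k] <- if (length(cand) == 1) cand else sample(cand, 1)
        break
      }
    }
  }
  data.frame(hap = sample.int(n_hap, n, replace = TRUE), pos = pos, base = nb,
             class = class, stringsAsFactors = FALSE)
}

#' Build per-lineage haplotype pools
#'
#' Draws an ancestral codon sequence, places interspecific fixed differences
#' at `fixed_diff_density`, diverges the clonal lineage's base haplotype from
#' the wild ancestor by `clonal_divergence`, and seeds each lineage pool with
#' singleton variants calibrated so that synonymous diversity and the
#' nonsynonymous/synonymous mix hit the scenario targets in expectation.
#' Mitochondrial haplotypes differ between the species at `mito_divergence`.
#'
#' @param scenario a `SimScenario`.
#' @return an object of class `SpeciesPools`.
#' @export
build_species_pools <- function(scenario) {
  stopifnot(inherits(scenario, "SimScenario"))
  set.seed(scenario$seed)
  n_cod <- scenario$n_genes * scenario$gene_length_codons
  L <- 3L * n_cod
  anc_cod <- sample(codon_env$SENSE, n_cod, replace = TRUE)
  ib_anc <- unlist(strsplit(anc_cod, ""), use.names = FALSE)
  st_anc <- mutate_sites(ib_anc, which(stats::runif(L) < scenario$fixed_diff_density))
  fixed_pos <- which(ib_anc != st_anc)
  # clonal-lineage divergence and within-lineage variants never touch a
  # fixed-difference position: mutating one could revert it to the other
  # species' allele and silently erase a planted species marker
  cl_pos <- setdiff(which(stats::runif(L) < scenario$clonal_divergence),
                    fixed_pos)
  cl_base <- mutate_sites(st_anc, cl_pos)

  bases <- list(ibericus = ib_anc, structor_wild = st_anc,
                structor_clonal = cl_base)
  lineages <- list()
  for (ln in LINEAGES) {
    base <- bases[[ln]]
    cods <- vapply(seq_len(n_cod),
                   function(i) paste(base[(3 * i - 2):(3 * i)], collapse = ""),
                   character(1))
    l_syn <- sum(codon_env$SYN_SITES[cods])
    l_non <- sum(codon_env$NONSYN_SITES[cods])
    n_hap <- scenario$n_haplotypes[[ln]]
    lam_s <- scenario$pi_s_targets[[ln]] * l_syn * n_hap / 2
    lam_n <- scenario$pi_s_targets[[ln]] * scenario$pi_n_over_pi_s_targets[[ln]] *
      l_non * n_hap / 2
    if ((lam_s > 0 && lam_s < 1) || (lam_n > 0 && lam_n < 1))
      warning("lineage ", ln, ": expected variant count below 1; ",
              "diversity target barely reachable at this gene length")
    vars <- rbind(draw_variants(base, lam_s, n_hap, "syn", exclude = fixed_pos),
                  draw_variants(base, lam_n, n_hap, "nonsyn",
                                exclude = fixed_pos))
    lineages[[ln]] <- list(base = base, vars = vars, n_hap = n_hap)
  }

  mito_ib <- sample(DNA_BASES4, scenario$mito_length, replace = TRUE)
  mito_st <- mito_ib
  flip <- which(stats::runif(scenario$mito_length) < scenario$mito_divergence)
  for (p in flip) mito_st[p] <- sample(setdiff(DNA_BASES4, mito_st[p]), 1)

  structure(list(
    scenario = scenario, L = L,
    gene_length = 3L * scenario$gene_length_codons,
    n_genes = scenario$n_genes,
    gene_ids = sprintf("g%03d", seq_len(scenario$n_genes)),
    anc = list(ibericus = ib_anc, structor = st_anc),
    lineages = lineages,
    mito = c(ibericus = paste(mito_ib, collapse = ""),
             structor = paste(mito_st, collapse = ""))), class = "SpeciesPools")
}

#' @export
print.SpeciesPools <- function(x, ...) {
  cat("SpeciesPools:", x$n_genes, "genes,", x$L, "bp;",
      sum(x$anc$ibericus != x$anc$structor), "interspecific fixed differences\n")
  for (ln in LINEAGES)
    cat("  ", ln, ": ", x$lineages[[ln]]$n_hap, " haplotypes, ",
        nrow(x$lineages[[ln]]$vars), " variants\n", sep = "")
  invisible(x)
}

# full sequence (character vector) of one pool haplotype
haplotype_chars <- function(pools, lineage, hap) {
  li <- pools$lineages[[lineage]]
  s <- li$base
  v <- li$vars[li$vars$hap == hap, , drop = FALSE]
  if (nrow(v)) s[v$pos] <- v$base
  s
}

#' Per-gene alignments of all pool haplotypes
#'
#' @param pools a `SpeciesPools`.
#' @return list of `GeneSequenceSet`, sequence ids `<lineage>_h<k>`.
#' @export
pool_gene_sets <- function(pools) {
  gl <- pools$gene_length
  seq_mat <- list()
  for (ln in LINEAGES) {
    nh <- pools$lineages[[ln]]$n_hap
    for (h in seq_len(nh))
      seq_mat[[sprintf("%s_h%02d", ln, h)]] <- haplotype_chars(pools, ln, h)
  }
  lapply(seq_len(pools$n_genes), function(g) {
    idx <- ((g - 1L) * gl + 1L):(g * gl)
    seqs <- vapply(seq_mat, function(s) paste(s[idx], collapse = ""), character(1))
    new_gene_set(pools$gene_ids[g], seqs)
  })
}

#' Reference gene backbones
#'
#' The maternal species' ancestral sequence, split per gene; this is the
#' genome against which the simulated VCF's REF alleles are defined.
#'
#' @param pools a `SpeciesPools`.
#' @return named character vector, gene id -> sequence.
#' @export
reference_sequences <- function(pools) {
  gl <- pools$gene_length
  out <- vapply(seq_len(pools$n_genes), function(g) {
    paste(pools$anc$ibericus[((g - 1L) * gl + 1L):(g * gl)], collapse = "")
  }, character(1))
  names(out) <- pools$gene_ids
  out
}

# recipe for one composition row -> list of per-individual draws
sim_recipe <- function(caste, species, father) {
  if (caste == "worker" || (caste == "egg" && species == "ibericus" &&
                            father %in% c("clonal", "wild"))) {
    pat <- if (father == "clonal") "structor_clonal" else "structor_wild"
    return(list(mat = "ibericus", pat = pat, ploidy = 2L, class = "F1",
                father = father, mito = "ibericus"))
  }
  if (caste == "queen")
    return(list(mat = if (species == "ibericus") "ibericus" else "structor_wild",
                pat = NA_character_, ploidy = 2L, class = "pure_maternal",
                father = "none", mito = species))
  if (caste == "male" || caste == "egg") {
    if (species == "ibericus")
      return(list(mat = "ibericus", pat = NA_character_, ploidy = 1L,
                  class = "pure_maternal", father = "none", mito = "ibericus"))
    if (father == "clonal")
      return(list(mat = NA_character_, pat = "structor_clonal", ploidy = 1L,
                  class = "pure_paternal", father = "clonal",
                  mito = "ibericus"))  # cloned from stored sperm: host mito
    if (caste == "egg")                 # androgenetic egg from wild sperm
      return(list(mat = NA_character_, pat = "structor_wild", ploidy = 1L,
                  class = "pure_paternal", father = "wild", mito = "ibericus"))
    return(list(mat = "structor_wild", pat = NA_character_, ploidy = 1L,
                class = "pure_maternal", father = "none", mito = "structor"))
  }
  if (caste == "spermatheca") {
    pat <- if (father == "wild") "structor_wild" else "structor_clonal"
    return(list(mat = "ibericus", pat = pat, ploidy = 2L, class = NA_character_,
                father = father, mito = "ibericus"))
  }
  stop("unknown caste: ", caste)
}

#' Simulate individuals from haplotype pools
#'
#' Draws every individual of the scenario's composition from the pools: F1
#' workers receive one maternal-species and one paternal haplotype, males are
#' haploid, clonal males carry the host (maternal) species' mitochondria,
#' androgenetic eggs carry only a paternal haplotype, spermatheca records are
#' two-haploid-genome mixtures. Depth is Poisson, genotype quality a rounded
#' normal; genotypes derive from the true haplotypes (error-free unless
#' `genotype_error > 0`).
#'
#' @param scenario a `SimScenario`.
#' @param pools pools built from the same scenario with [build_species_pools()].
#' @return an object of class `SimulatedCohort`: list with `cohort`
#'   (a `CohortMatrix` over all variant sites), `genes` (pool haplotype
#'   alignments), `reference` (per-gene backbones), `mito` (named character,
#'   per-individual haplotypes plus `REF_ibericus`/`REF_structor`), `truth`
#'   (the truth table) and `scenario`.
#' @export
simulate_individuals <- function(scenario, pools) {
  stopifnot(inherits(scenario, "SimScenario"), inherits(pools, "SpeciesPools"))
  set.seed(scenario$seed + 1L)
  comp <- scenario$composition
  comp <- comp[comp$count > 0, , drop = FALSE]
  if (!nrow(comp)) stop("composition requests no individuals")

  # variant site list (global positions)
  vs <- sort(unique(c(which(pools$anc$ibericus != pools$anc$structor),
                      which(pools$anc$structor != pools$lineages$structor_clonal$base),
                      unlist(lapply(pools$lineages, function(l) l$vars$pos)))))
  nv <- length(vs)

  # pool haplotype alleles at variant sites
  hapmat <- list()
  for (ln in LINEAGES) {
    li <- pools$lineages[[ln]]
    if (li$n_hap == 0) { hapmat[[ln]] <- NULL; next }
    m <- matrix(li$base[vs], nv, li$n_hap)
    if (nrow(li$vars)) {
      ridx <- match(li$vars$pos, vs)
      m[cbind(ridx, li$vars$hap)] <- li$vars$base
    }
    hapmat[[ln]] <- m
  }
  draw_hap <- function(lineage) {
    li <- pools$lineages[[lineage]]
    if (is.null(li) || li$n_hap == 0)
      stop("composition requests lineage '", lineage, "' but its pool is empty")
    sample.int(li$n_hap, 1)
  }

  prefixes <- c(worker = "WRK", male_ib = "IBM", male_cl = "CLM", male_wl = "WLM",
                queen_ib = "IBQ", queen_st = "STQ", egg = "EGG", spermatheca = "SPT")
  counters <- stats::setNames(integer(length(prefixes)), names(prefixes))
  ind <- list(); k <- 0
  for (r in seq_len(nrow(comp))) {
    rec <- sim_recipe(comp$caste[r], comp$nominal_species[r], comp$father_lineage[r])
    for (i in seq_len(comp$count[r])) {
      k <- k + 1
      key <- switch(comp$caste[r],
        worker = "worker", egg = "egg", spermatheca = "spermatheca",
        queen = if (comp$nominal_species[r] == "ibericus") "queen_ib" else "queen_st",
        male = if (comp$nominal_species[r] == "ibericus") "male_ib"
               else if (comp$father_lineage[r] == "clonal") "male_cl" else "male_wl")
      counters[key] <- counters[key] + 1L
      mat_h <- if (!is.na(rec$mat)) draw_hap(rec$mat) else NA_integer_
      pat_h <- if (!is.na(rec$pat)) draw_hap(rec$pat) else NA_integer_
      ind[[k]] <- list(
        id = sprintf("%s%03d", prefixes[key], counters[key]),
        caste = comp$caste[r], species = comp$nominal_species[r],
        ploidy = rec$ploidy, class = rec$class, father = rec$father,
        mito = rec$mito, mat_lineage = rec$mat, mat_hap = mat_h,
        pat_lineage = rec$pat, pat_hap = pat_h)
    }
  }
  n_ind <- length(ind)

  # allele characters carried by each individual at variant sites
  chars1 <- matrix(NA_character_, nv, n_ind)
  chars2 <- matrix(NA_character_, nv, n_ind)
  for (j in seq_len(n_ind)) {
    x <- ind[[j]]
    c_m <- if (!is.na(x$mat_lineage)) hapmat[[x$mat_lineage]][, x$mat_hap] else NULL
    c_p <- if (!is.na(x$pat_lineage)) hapmat[[x$pat_lineage]][, x$pat_hap] else NULL
    if (is.null(c_m)) c_m <- c_p        # haploid paternal-only
    if (is.null(c_p)) c_p <- c_m        # haploid maternal-only / diploid same-pool
    chars1[, j] <- c_m
    chars2[, j] <- c_p
  }
  # diploid same-species individuals need two independent draws; handled above
  # for hybrids; queens/spermatheca drew distinct haplotypes already via
  # mat/pat lineages -- queens use the same lineage for both copies:
  for (j in seq_len(n_ind)) {
    x <- ind[[j]]
    if (x$ploidy == 2L && !is.na(x$mat_lineage) && is.na(x$pat_lineage)) {
      h2 <- draw_hap(x$mat_lineage)
      ind[[j]]$pat_lineage <- x$mat_lineage
      ind[[j]]$pat_hap <- h2
      chars2[, j] <- hapmat[[x$mat_lineage]][, h2]
    }
  }

  if (scenario$genotype_error > 0) {
    for (m in c("chars1", "chars2")) {
      mm <- get(m)
      flip <- which(stats::runif(length(mm)) < scenario$genotype_error)
      for (f in flip) mm[f] <- sample(setdiff(DNA_BASES4, mm[f]), 1)
      assign(m, mm)
    }
  }

  ref <- pools$anc$ibericus[vs]
  alt_list <- vector("list", nv)
  a1 <- matrix(NA_integer_, nv, n_ind)
  a2 <- matrix(NA_integer_, nv, n_ind)
  for (r in seq_len(nv)) {
    alleles <- c(ref[r], setdiff(sort(unique(c(chars1[r, ], chars2[r, ]))), ref[r]))
    alt_list[[r]] <- alleles[-1]
    a1[r, ] <- match(chars1[r, ], alleles) - 1L
    a2[r, ] <- match(chars2[r, ], alleles) - 1L
  }

  dp <- matrix(stats::rpois(nv * n_ind, scenario$depth_mean), nv, n_ind)
  gq <- matrix(pmax(0, round(stats::rnorm(nv * n_ind, scenario$quality_model[["mean"]],
                                          scenario$quality_model[["sd"]]))),
               nv, n_ind)

  gl <- pools$gene_length
  sites <- data.frame(
    contig = pools$gene_ids[(vs - 1L) %/% gl + 1L],
    pos = as.integer((vs - 1L) %% gl + 1L),
    ref = ref,
    alt = vapply(alt_list, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)

  ids <- vapply(ind, `[[`, character(1), "id")
  n_ib_col <- 10L; n_st_col <- 5L
  colony <- character(n_ind)
  ib_members <- which(vapply(ind, function(x) x$mito == "ibericus" ||
                               x$species == "ibericus", logical(1)))
  st_members <- setdiff(seq_len(n_ind), ib_members)
  colony[ib_members] <- sprintf("IBcol%02d", (seq_along(ib_members) - 1L) %% n_ib_col + 1L)
  colony[st_members] <- sprintf("STcol%02d", (seq_along(st_members) - 1L) %% n_st_col + 1L)

  meta <- data.frame(
    individual_id = ids, colony_id = colony,
    caste = vapply(ind, `[[`, character(1), "caste"),
    nominal_species = vapply(ind, `[[`, character(1), "species"),
    ploidy = vapply(ind, `[[`, integer(1), "ploidy"),
    stringsAsFactors = FALSE)

  cohort <- new_cohort(sites, meta, a1, a2, dp, gq)

  hap_label <- function(lineage, hap)
    ifelse(is.na(lineage), NA_character_, sprintf("%s_h%02d", lineage, hap))
  truth <- data.frame(
    individual_id = ids,
    true_class = vapply(ind, function(x) x$class %||% NA_character_, character(1)),
    true_father_lineage = vapply(ind, `[[`, character(1), "father"),
    true_mito_species = vapply(ind, `[[`, character(1), "mito"),
    maternal_hap = mapply(hap_label,
                          vapply(ind, function(x) x$mat_lineage %||% NA_character_, character(1)),
                          vapply(ind, function(x) x$mat_hap %||% NA_integer_, integer(1))),
    paternal_hap = mapply(hap_label,
                          vapply(ind, function(x) x$pat_lineage %||% NA_character_, character(1)),
                          vapply(ind, function(x) x$pat_hap %||% NA_integer_, integer(1))),
    stringsAsFactors = FALSE)
  rownames(truth) <- NULL

  mito <- c(stats::setNames(unname(pools$mito[truth$true_mito_species]), ids),
            REF_ibericus = unname(pools$mito[["ibericus"]]),
            REF_structor = unname(pools$mito[["structor"]]))

  structure(list(cohort = cohort, genes = pool_gene_sets(pools),
                 reference = reference_sequences(pools), mito = mito,
                 truth = truth, pools = pools, scenario = scenario),
            class = "SimulatedCohort")
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' @export
print.SimulatedCohort <- function(x, ...) {
  cat("SimulatedCohort:", nrow(x$truth), "individuals,",
      n_sites(x$cohort), "variant sites,", length(x$genes), "genes\n")
  print(table(class = x$truth$true_class, useNA = "ifany"))
  invisible(x)
}

#' Simulate a full cohort in one call
#'
#' Convenience wrapper: [build_species_pools()] then [simulate_individuals()].
#'
#' @param scenario a `SimScenario` (default: the default scenario).
#' @return a `SimulatedCohort`.
#' @export
simulate_cohort <- function(scenario = sim_scenario()) {
  simulate_individuals(scenario, build_species_pools(scenario))
}

#' Write a simulated cohort to disk
#'
#' Writes the variant_store interchange files: `cohort.vcf`, `meta.tsv`,
#' `truth.tsv`, `genes/<gene>.fasta` (pool haplotype alignments),
#' `reference.fasta` (per-gene backbones), `mito.fasta` and `scenario.cfg`.
#' The file set is re-readable with [read_cohort()] / [read_gene_sequences()].
#'
#' @param sim a `SimulatedCohort`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, `out_dir`.
#' @export
write_scenario <- function(sim, out_dir) {
  stopifnot(inherits(sim, "SimulatedCohort"))
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  write_cohort(sim$cohort, file.path(out_dir, "cohort.vcf"),
               file.path(out_dir, "meta.tsv"))
  utils::write.table(sim$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gene_sequences(sim$genes, file.path(out_dir, "genes"))
  Biostrings::writeXStringSet(Biostrings::BStringSet(sim$reference),
                              file.path(out_dir, "reference.fasta"))
  Biostrings::writeXStringSet(Biostrings::BStringSet(sim$mito),
                              file.path(out_dir, "mito.fasta"))
  write_scenario_config(sim$scenario, file.path(out_dir, "scenario.cfg"))
  invisible(out_dir)
}

#' Write / read a scenario in flat key-value form
#'
#' Scalar parameters are `key = value` lines; named vectors use
#' `name=value` pairs joined by commas; composition rows repeat the
#' `composition` key with `caste,species,father_lineage,count`.
#'
#' @param scenario a `SimScenario`.
#' @param path config file path.
#' @return invisibly, `path` (writer) / a `SimScenario` (reader).
#' @export
write_scenario_config <- function(scenario, path) {
  named_fmt <- function(v) paste(names(v), format(unname(v), trim = TRUE,
                                                  scientific = FALSE), sep = "=", collapse = ",")
  lines <- c(
    paste("n_genes =", scenario$n_genes),
    paste("gene_length_codons =", scenario$gene_length_codons),
    paste("fixed_diff_density =", scenario$fixed_diff_density),
    paste("pi_s_targets =", named_fmt(scenario$pi_s_targets)),
    paste("pi_n_over_pi_s_targets =", named_fmt(scenario$pi_n_over_pi_s_targets)),
    paste("clonal_divergence =", scenario$clonal_divergence),
    paste("n_haplotypes =", named_fmt(scenario$n_haplotypes)),
    paste("mito_length =", scenario$mito_length),
    paste("mito_divergence =", scenario$mito_divergence),
    paste("depth_mean =", scenario$depth_mean),
    paste("quality_model =", named_fmt(scenario$quality_model)),
    paste("genotype_error =", scenario$genotype_error),
    paste("seed =", scenario$seed),
    vapply(seq_len(nrow(scenario$composition)), function(r)
      paste("composition =",
            paste(c(unlist(scenario$composition[r, c("caste", "nominal_species",
                                                     "father_lineage")]),
                    scenario$composition$count[r]), collapse = ",")),
      character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 0)) stop("malformed scenario config line: ",
                        lines[which(eq < 0)[1]])
  keys <- trimws(substr(lines, 1L, eq - 1L))
  vals <- trimws(substring(lines, eq + 1L))
  parse_named <- function(s) {
    parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
    stats::setNames(as.numeric(vapply(parts, `[`, character(1), 2)),
                    vapply(parts, `[`, character(1), 1))
  }
  get1 <- function(k, default) if (k %in% keys) vals[keys == k][1] else default
  comp_rows <- vals[keys == "composition"]
  comp <- if (length(comp_rows)) {
    m <- do.call(rbind, strsplit(comp_rows, ",", fixed = TRUE))
    data.frame(caste = m[, 1], nominal_species = m[, 2], father_lineage = m[, 3],
               count = as.integer(m[, 4]), stringsAsFactors = FALSE)
  } else default_composition()
  sim_scenario(
    n_genes = as.integer(get1("n_genes", 100)),
    gene_length_codons = as.integer(get1("gene_length_codons", 300)),
    fixed_diff_density = as.numeric(get1("fixed_diff_density", 0.02)),
    pi_s_targets = parse_named(get1("pi_s_targets",
      "ibericus=0.00045,structor_wild=0.0014,structor_clonal=0.00027")),
    pi_n_over_pi_s_targets = parse_named(get1("pi_n_over_pi_s_targets",
      "ibericus=0.21,structor_wild=0.21,structor_clonal=0.43")),
    clonal_divergence = as.numeric(get1("clonal_divergence", 0.005)),
    composition = comp,
    n_haplotypes = parse_named(get1("n_haplotypes",
      "ibericus=40,structor_wild=40,structor_clonal=40")),
    mito_length = as.integer(get1("mito_length", 2000)),
    mito_divergence = as.numeric(get1("mito_divergence", 0.05)),
    depth_mean = as.numeric(get1("depth_mean", 20)),
    quality_model = parse_named(get1("quality_model", "mean=60,sd=10")),
    genotype_error = as.numeric(get1("genotype_error", 0)),
    seed = as.integer(get1("seed", 1)))
}
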