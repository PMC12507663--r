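# End-to-end orchestration: simulate/load -> filter -> hybrid screen ->
# ancestry -> phasing -> placement -> mito-nuclear mismatch -> diversity,
# with truth scoring when a truth table is available.

#' Pipeline configuration
#'
#' Either a `scenario` (a `SimScenario` or a path to a scenario config file)
#' or the interchange files (`vcf` + `meta`, optionally `reference_fasta`,
#' `mito_fasta`, `truth`) must be supplied.
#'
#' @param scenario `SimScenario`, path to a scenario config, or `NULL`.
#' @param vcf,meta,reference_fasta,mito_fasta,truth input file paths
#'   (ignored when `scenario` is given).
#' @param out_dir optional output directory for report tables.
#' @param seed integer seed controlling every random choice of the run.
#' @param maternal_species,paternal_species species labels of the two sources.
#' @param min_quality,min_maf,min_called site-filter parameters
#'   (see [filter_sites()]).
#' @param min_depth phasing/consensus depth threshold.
#' @param min_separation F1 cluster-separation guard (see [classify_f1()]).
#' @param freq_floor ancestry allele-frequency floor.
#' @param ancestry_sites `"diagnostic"` (default) restricts ancestry
#'   estimation to interspecific fixed-difference sites, where both source
#'   pools are internally homogeneous and the mixture model is well
#'   specified; `"panel"` uses every filtered site.
#' @param strict_phasing mask shared-homozygous sites back to `N`.
#' @param n_bootstrap_nuclear,n_bootstrap_mito bootstrap replicates for
#'   nuclear and mitochondrial placements (0 disables support values).
#' @param clonal_threshold single-linkage cut for clonal-cluster detection
#'   (`NULL`: 3x the clonal synonymous-diversity default).
#' @param max_panel_members reference sequences per placement panel.
#' @param diversity_max_seqs,diversity_bootstrap per-lineage diversity panel
#'   size cap and gene-bootstrap replicates.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(scenario = NULL, vcf = NULL, meta = NULL,
                            reference_fasta = NULL, mito_fasta = NULL,
                            truth = NULL, out_dir = NULL, seed = 1,
                            maternal_species = "ibericus",
                            paternal_species = "structor",
                            min_quality = 10, min_maf = 0.05, min_called = 0.8,
                            min_depth = 3, min_separation = 5,
                            freq_floor = 1e-3,
                            ancestry_sites = c("diagnostic", "panel"),
                            strict_phasing = FALSE,
                            n_bootstrap_nuclear = 0, n_bootstrap_mito = 100,
                            clonal_threshold = NULL, max_panel_members = 8,
                            diversity_max_seqs = 16, diversity_bootstrap = 200) {
  ancestry_sites <- match.arg(ancestry_sites)
  cfg <- as.list(environment())
  if (is.null(scenario) && is.null(vcf))
    stop("missing required input: supply a scenario or a VCF + metadata")
  for (f in c("vcf", "meta", "reference_fasta", "mito_fasta", "truth")) {
    p <- cfg[[f]]
    if (!is.null(p) && is.character(p) && !file.exists(p))
      stop("input file for '", f, "' does not exist: ", p)
  }
  if (is.character(cfg$scenario) && !file.exists(cfg$scenario))
    stop("scenario config does not exist: ", cfg$scenario)
  class(cfg) <- "PipelineConfig"
  cfg
}

# gene sets from a list of consensus Haplomes (ids = individuals)
consensus_gene_sets <- function(haplomes) {
  ids <- vapply(haplomes, `[[`, character(1), "source_individual_id")
  genes <- Reduce(intersect, lapply(haplomes, function(h) names(h$gene_sequences)))
  lapply(genes, function(g) {
    seqs <- vapply(haplomes, function(h) h$gene_sequences[[g]], character(1))
    names(seqs) <- ids
    new_gene_set(g, seqs)
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage: cohort simulation or loading, SNP-panel
#' filtering, heterozygosity-based F1 screening, supervised ancestry,
#' maternal/paternal haplome phasing of each hybrid, nuclear and
#' mitochondrial placement with mito-nuclear mismatch flags, clonal-cluster
#' detection, paternal-lineage assignment of each worker, embryo
#' classification and per-lineage diversity. Deterministic given
#' `config$seed`; failure of one individual's placement is logged and marked
#' indeterminate rather than aborting the run.
#'
#' @param config a [pipeline_config()].
#' @return a `RunReport`: list with `individuals` (one row per input
#'   individual), `diversity`, `panel_size`, `maternal_reference`,
#'   `clonal_male_ids`, `confusion` (when truth is available), `log`,
#'   `seed`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  set.seed(config$seed)
  log <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    message(msg)
  }

  # ---- inputs -------------------------------------------------------------
  truth <- NULL; mito <- NULL; reference <- NULL
  if (!is.null(config$scenario)) {
    scen <- if (is.character(config$scenario)) read_scenario_config(config$scenario)
            else config$scenario
    sim <- simulate_cohort(scen)
    cohort <- sim$cohort; truth <- sim$truth; mito <- sim$mito
    reference <- sim$reference
    say("simulated cohort: ", nrow(truth), " individuals, ",
        n_sites(cohort), " variant sites")
  } else {
    cohort <- read_cohort(config$vcf, config$meta)
    if (!is.null(config$reference_fasta)) {
      ss <- Biostrings::readBStringSet(config$reference_fasta)
      reference <- toupper(as.character(ss))
    }
    if (!is.null(config$mito_fasta)) {
      ss <- Biostrings::readBStringSet(config$mito_fasta)
      mito <- toupper(as.character(ss))
    }
    if (!is.null(config$truth))
      truth <- utils::read.delim(config$truth, stringsAsFactors = FALSE)
    say("loaded cohort: ", n_individuals(cohort), " individuals, ",
        n_sites(cohort), " sites")
  }
  if (n_individuals(cohort) == 0) stop("no individuals")
  meta <- cohort$individuals

  # ---- SNP panel + hybrid screen -----------------------------------------
  panel <- filter_sites(cohort, min_quality = config$min_quality,
                        min_maf = config$min_maf, min_called = config$min_called)
  say("polymorphic panel: ", n_sites(panel), " of ", n_sites(cohort), " sites")
  screened <- meta$individual_id[!(meta$caste %in% c("egg", "spermatheca"))]
  profiles <- het_profiles(panel, ids = screened)
  f1 <- classify_f1(profiles, min_separation = config$min_separation)
  say(sum(f1$is_f1), " individuals flagged as F1 hybrids")

  res <- data.frame(individual_id = meta$individual_id,
                    colony_id = meta$colony_id, caste = meta$caste,
                    nominal_species = meta$nominal_species, ploidy = meta$ploidy,
                    het_proportion = NA_real_, is_f1 = NA,
                    q_maternal = NA_real_, nuclear_species = NA_character_,
                    mito_species = NA_character_, mito_nuclear_mismatch = NA,
                    father_lineage = NA_character_, embryo_class = NA_character_,
                    stringsAsFactors = FALSE)
  res$het_proportion[match(f1$individual_id, res$individual_id)] <- f1$het_proportion
  res$is_f1[match(f1$individual_id, res$individual_id)] <- f1$is_f1
  f1_ids <- f1$individual_id[f1$is_f1]

  # ---- ancestry -----------------------------------------------------------
  non_f1 <- setdiff(screened, f1_ids)
  maternal_ids <- intersect(non_f1,
    meta$individual_id[meta$nominal_species == config$maternal_species])
  paternal_ids <- intersect(non_f1,
    meta$individual_id[meta$nominal_species == config$paternal_species])
  diag_sites <- NULL
  if (length(maternal_ids) && length(paternal_ids) && length(f1_ids)) {
    # The two-source mixture model is only well specified at sites where each
    # source pool is internally homogeneous; hidden substructure inside a pool
    # (here: the two paternal-species lineages) biases q at sites the pool is
    # polymorphic for. Default: estimate on interspecific diagnostic sites.
    diag_sites <- fixed_difference_sites(panel, maternal_ids, paternal_ids)
    anc_panel <- panel
    if (config$ancestry_sites == "diagnostic" && nrow(diag_sites) >= 50) {
      keep <- paste(panel$sites$contig, panel$sites$pos) %in%
        paste(diag_sites$contig, diag_sites$pos)
      anc_panel <- subset_sites(panel, keep)
      say("ancestry panel: ", n_sites(anc_panel), " diagnostic sites")
    }
    sf <- source_allele_freqs(anc_panel, maternal_ids, paternal_ids,
                              floor = config$freq_floor)
    for (id in f1_ids) {
      q <- tryCatch(estimate_ancestry(anc_panel, id, sf)$q_maternal,
                    error = function(e) NA_real_)
      res$q_maternal[res$individual_id == id] <- q
    }
    say("ancestry estimated for ", length(f1_ids), " hybrids (mean q_maternal ",
        sprintf("%.3f", mean(res$q_maternal[res$individual_id %in% f1_ids],
                             na.rm = TRUE)), ")")
  }

  # ---- phasing of hybrids -------------------------------------------------
  paternal_haplomes <- list()
  mat_ref <- NULL
  if (!is.null(reference) && length(f1_ids)) {
    mat_ref <- select_maternal_reference(cohort, config$maternal_species, f1)
    say("maternal reference: ", mat_ref)
    for (id in f1_ids) {
      ph <- phase_individual(cohort, id, mat_ref, min_depth = config$min_depth,
                             f1_calls = f1)
      hp <- suppressWarnings(
        build_haplome_sequences(ph, reference, strict = config$strict_phasing))
      paternal_haplomes[[id]] <- hp$paternal
    }
  }

  # ---- nuclear panels and clonal cluster ----------------------------------
  consensus_cache <- list()
  consensus_of <- function(id) {
    if (is.null(consensus_cache[[id]]))
      consensus_cache[[id]] <<- consensus_sequence(cohort, id, reference,
                                                   min_depth = config$min_depth)
    consensus_cache[[id]]
  }
  clonal_ids <- character(0); wild_ids <- character(0)
  lineage_panels <- NULL; species_panels <- NULL
  if (!is.null(reference)) {
    pick_members <- function(ids) {
      males <- ids[meta$ploidy[match(ids, meta$individual_id)] == 1]
      ordered <- c(males, setdiff(ids, males))
      utils::head(ordered, config$max_panel_members)
    }
    species_panels <- list()
    for (sp in c(config$maternal_species, config$paternal_species)) {
      ids <- intersect(non_f1, meta$individual_id[meta$nominal_species == sp])
      if (length(ids))
        species_panels[[sp]] <- lapply(pick_members(ids), consensus_of)
    }
    st_males <- intersect(non_f1,
      meta$individual_id[meta$nominal_species == config$paternal_species &
                           meta$caste == "male"])
    if (length(st_males) >= 2) {
      male_seqs <- lapply(st_males, consensus_of)
      names(male_seqs) <- st_males
      thr <- config$clonal_threshold %||% (3 * 0.00027)
      cl <- detect_clonal_cluster(male_seqs, max_intra_distance = thr)
      clonal_ids <- st_males[cl$membership == cl$clonal_cluster]
      wild_ids <- setdiff(st_males, clonal_ids)
      say("clonal cluster: ", length(clonal_ids), " males; wild: ",
          length(wild_ids))
      lineage_panels <- list()
      if (length(clonal_ids))
        lineage_panels$clonal <- lapply(pick_members(clonal_ids), consensus_of)
      if (length(wild_ids))
        lineage_panels$wild <- lapply(pick_members(wild_ids), consensus_of)
    }
  }

  # ---- mito refs + per-male placements ------------------------------------
  mito_refs <- NULL
  if (!is.null(mito)) {
    if (all(c("REF_ibericus", "REF_structor") %in% names(mito))) {
      mito_refs <- list(mito[["REF_ibericus"]], mito[["REF_structor"]])
      names(mito_refs) <- c("ibericus", "structor")
    } else {
      mito_refs <- list()
      for (sp in c(config$maternal_species, config$paternal_species)) {
        qs <- intersect(non_f1, meta$individual_id[
          meta$nominal_species == sp & meta$caste == "queen"])
        qs <- intersect(qs, names(mito))
        if (length(qs)) mito_refs[[sp]] <- mito[[qs[1]]]
      }
    }
    names(mito_refs)[names(mito_refs) == "ibericus"] <- config$maternal_species
    names(mito_refs)[names(mito_refs) == "structor"] <- config$paternal_species
    for (id in intersect(meta$individual_id, names(mito))) {
      pr <- tryCatch(assign_mito(mito[[id]], mito_refs,
                                 n_bootstrap = config$n_bootstrap_mito,
                                 query_id = id),
                     error = function(e) NULL)
      if (!is.null(pr))
        res$mito_species[res$individual_id == id] <- pr$assigned_group
    }
  }

  males <- meta$individual_id[meta$caste == "male"]
  if (!is.null(species_panels) && length(species_panels) >= 2) {
    for (id in setdiff(males, f1_ids)) {
      pr <- tryCatch(
        assign_by_nearest_panel(consensus_of(id), species_panels,
                                n_bootstrap = config$n_bootstrap_nuclear,
                                query_id = id),
        error = function(e) NULL)
      res$nuclear_species[res$individual_id == id] <-
        if (is.null(pr)) NA_character_ else pr$assigned_group
      mt <- res$mito_species[res$individual_id == id]
      if (!is.null(pr) && !is.na(mt)) {
        flag <- detect_mito_nuclear_mismatch(
          pr, list(assigned_group = mt), individual_id = id)
        res$mito_nuclear_mismatch[res$individual_id == id] <- flag$is_mismatch
      }
    }
    say("nuclear species assigned for ", length(setdiff(males, f1_ids)), " males")
  }

  # ---- paternal lineage of each hybrid ------------------------------------
  if (!is.null(lineage_panels) && length(lineage_panels) >= 2 &&
      length(paternal_haplomes)) {
    for (id in names(paternal_haplomes)) {
      pr <- tryCatch(
        assign_by_nearest_panel(paternal_haplomes[[id]], lineage_panels,
                                n_bootstrap = config$n_bootstrap_nuclear,
                                query_id = id),
        error = function(e) NULL)
      res$father_lineage[res$individual_id == id] <-
        if (is.null(pr)) NA_character_ else pr$assigned_group
    }
    say("paternal lineage assigned for ", length(paternal_haplomes), " hybrids")
  }

  # ---- embryo classification ----------------------------------------------
  eggs <- meta$individual_id[meta$caste == "egg"]
  if (length(eggs) && length(maternal_ids) && length(paternal_ids)) {
    if (is.null(diag_sites))
      diag_sites <- fixed_difference_sites(panel, maternal_ids, paternal_ids)
    for (id in eggs) {
      ec <- tryCatch(classify_embryo(cohort, id, diag_sites),
                     error = function(e) list(class = "indeterminate"))
      res$embryo_class[res$individual_id == id] <- ec$class
    }
    say(length(eggs), " eggs classified on ", nrow(diag_sites),
        " diagnostic sites")
  }

  # ---- per-lineage diversity ----------------------------------------------
  div <- NULL
  if (!is.null(reference)) {
    lineage_sets <- list()
    if (length(clonal_ids) >= 2)
      lineage_sets[["structor_clonal"]] <- clonal_ids
    if (length(wild_ids) >= 2)
      lineage_sets[["structor_wild"]] <- wild_ids
    mq <- intersect(maternal_ids, meta$individual_id[meta$caste == "queen"])
    if (length(mq) >= 2) lineage_sets[[config$maternal_species]] <- mq
    ests <- list()
    for (ln in names(lineage_sets)) {
      ids <- lineage_sets[[ln]]
      if (length(ids) > config$diversity_max_seqs)
        ids <- sort(sample(ids, config$diversity_max_seqs))
      gs <- consensus_gene_sets(lapply(ids, consensus_of))
      ests[[ln]] <- pi_with_ci(gs, n_bootstrap = config$diversity_bootstrap)
    }
    if (length(ests)) {
      div <- diversity_report(ests)
      say("diversity estimated for ", nrow(div), " lineages")
    }
  }

  # ---- truth scoring -------------------------------------------------------
  confusion <- NULL
  if (!is.null(truth)) {
    tr <- truth[match(res$individual_id, truth$individual_id), ]
    confusion <- list()
    scr <- res$individual_id %in% screened
    confusion$f1 <- table(truth = tr$true_class[scr] == "F1",
                          called = res$is_f1[scr])
    wk <- !is.na(res$father_lineage)
    if (any(wk))
      confusion$father_lineage <- table(truth = tr$true_father_lineage[wk],
                                        called = res$father_lineage[wk])
    mm <- !is.na(res$mito_nuclear_mismatch)
    if (any(mm))
      confusion$mismatch <- table(truth = tr$true_father_lineage[mm] == "clonal" &
                                    tr$true_class[mm] == "pure_paternal",
                                  called = res$mito_nuclear_mismatch[mm])
  }

  report <- structure(list(individuals = res, diversity = div,
                           panel_size = n_sites(panel),
                           maternal_reference = mat_ref,
                           clonal_male_ids = clonal_ids,
                           wild_male_ids = wild_ids,
                           confusion = confusion, log = log,
                           seed = config$seed), class = "RunReport")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(res, file.path(config$out_dir, "individuals.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(div))
      utils::write.table(div, file.path(config$out_dir, "diversity.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(c(paste("seed:", config$seed), log),
               file.path(config$out_dir, "manifest.txt"))
  }
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport:", nrow(x$individuals), "individuals; panel of",
      x$panel_size, "sites\n")
  cat("  F1 flagged:", sum(x$individuals$is_f1, na.rm = TRUE), "\n")
  if (length(x$clonal_male_ids))
    cat("  clonal males:", length(x$clonal_male_ids), "\n")
  invisible(x)
}

#' Group-level summary of the hybrid screen
#'
#' Mean heterozygosity of the F1-flagged and non-flagged groups, the
#' two-sided rank-sum p-value of their contrast, and mean maternal ancestry
#' per group.
#'
#' @param report a `RunReport`.
#' @return data.frame with one row per group plus attributes `p_value` and
#'   `mean_ratio`.
#' @export
summarize_fig1 <- function(report) {
  df <- report$individuals
  df <- df[!is.na(df$is_f1), ]
  groups <- split(df, ifelse(df$is_f1, "F1_hybrid", "non_hybrid"))
  out <- do.call(rbind, lapply(names(groups), function(g) {
    data.frame(group = g, n = nrow(groups[[g]]),
               mean_het = mean(groups[[g]]$het_proportion, na.rm = TRUE),
               mean_q_maternal = mean(groups[[g]]$q_maternal, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  p <- NA_real_
  if (length(groups) == 2) {
    if (any(vapply(groups, nrow, integer(1)) < 2)) {
      warning("a group has fewer than 2 members; rank-sum test skipped")
    } else {
      p <- compare_groups(groups[[1]]$het_proportion, groups[[2]]$het_proportion)
    }
  }
  attr(out, "p_value") <- p
  attr(out, "mean_ratio") <- if (nrow(out) == 2)
    max(out$mean_het) / max(min(out$mean_het), .Machine$double.eps) else NA_real_
  out
}
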