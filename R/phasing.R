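# Rule-based separation of maternal and paternal alleles of a hybrid genome
# against a homozygous, low-diversity maternal reference individual, plus
# reconstruction of per-gene haplome and consensus sequences.

PHASE_RULES <- c("HET_MATCH", "HOM_SHARED", "MAT_REF_HET", "NO_MATCH",
                 "LOW_DEPTH", "MISSING")

# vectorized rule table over parallel nucleotide/depth vectors
phase_calls <- function(h1, h2, m1, m2, dp_h, dp_m, min_depth = 3) {
  n <- length(h1)
  dp_h[is.na(dp_h)] <- 0; dp_m[is.na(dp_m)] <- 0
  mat <- rep(NA_character_, n); pat <- rep(NA_character_, n)
  rule <- rep(NA_character_, n)

  low <- dp_h < min_depth | dp_m < min_depth
  rule[low] <- "LOW_DEPTH"
  todo <- !low

  miss <- todo & (is.na(h1) | is.na(m1))
  rule[miss] <- "MISSING"
  todo <- todo & !miss

  mat_het <- todo & (m1 != m2)
  rule[mat_het] <- "MAT_REF_HET"
  todo <- todo & !mat_het

  hyb_het <- todo & (h1 != h2)
  match1 <- hyb_het & (m1 == h1)
  match2 <- hyb_het & !match1 & (m1 == h2)
  rule[match1 | match2] <- "HET_MATCH"
  mat[match1] <- h1[match1]; pat[match1] <- h2[match1]
  mat[match2] <- h2[match2]; pat[match2] <- h1[match2]
  rule[hyb_het & !match1 & !match2] <- "NO_MATCH"
  todo <- todo & !hyb_het

  shared <- todo & (h1 == m1)
  rule[shared] <- "HOM_SHARED"
  mat[shared] <- h1[shared]; pat[shared] <- h1[shared]
  rule[todo & !shared] <- "NO_MATCH"

  mat[is.na(mat)] <- "N"; pat[is.na(pat)] <- "N"
  list(maternal = mat, paternal = pat, rule = rule)
}

#' Phase one site of a hybrid against a maternal reference
#'
#' Applies the deterministic rule table: a site heterozygous in the hybrid
#' (e.g. A/G) whose maternal reference is homozygous for one of the two
#' alleles (e.g. A/A) yields that allele as maternal and the other as
#' paternal. Both alleles are `N` when either call has depth below
#' `min_depth`, when either call is missing, when the maternal reference is
#' heterozygous, or when no allele matches the reference. A site homozygous
#' in both hybrid and reference for the same allele is assigned to both
#' haplomes (`HOM_SHARED`; both parents necessarily carry it) -- an extension
#' of the het-only rule that a strict mode downstream can mask back to `N`.
#'
#' @param hybrid_call,maternal_ref_call lists with `alleles` (character
#'   vector of 2 nucleotides, or `NA`) and `depth`.
#' @param min_depth minimum read depth required in both calls.
#' @return a `PhasedSite`: list with `maternal_allele`, `paternal_allele`
#'   and `rule_applied`.
#' @export
phase_site <- function(hybrid_call, maternal_ref_call, min_depth = 3) {
  al <- function(x) {
    a <- x$alleles
    if (is.null(a) || length(a) == 0 || all(is.na(a))) c(NA_character_, NA_character_)
    else if (length(a) == 1) c(a, a) else a[1:2]
  }
  h <- al(hybrid_call); m <- al(maternal_ref_call)
  r <- phase_calls(h[1], h[2], m[1], m[2], hybrid_call$depth %||% 0,
                   maternal_ref_call$depth %||% 0, min_depth)
  structure(list(maternal_allele = r$maternal, paternal_allele = r$paternal,
                 rule_applied = r$rule), class = "PhasedSite")
}

#' Phase a hybrid individual site by site
#'
#' Applies [phase_site()]'s rule table at every SNP of the cohort (indel
#' sites are excluded) for one hybrid against a homozygous maternal
#' reference individual -- by design the highest-coverage non-hybrid queen of
#' the maternal species (see [select_maternal_reference()]).
#'
#' @param cohort a `CohortMatrix` (typically indel-free; remaining indel
#'   sites are dropped here).
#' @param hybrid_id,maternal_ref_id individual ids.
#' @param min_depth minimum depth in both individuals.
#' @param f1_calls optional [classify_f1()] result; if the reference is
#'   flagged as F1 the call errors (an F1 reference is invalid).
#' @return data.frame of class `PhasedSites` with columns `contig`, `pos`,
#'   `maternal_allele`, `paternal_allele`, `rule`; the per-rule summary is in
#'   `attr(, "rule_counts")` and the phased fraction in
#'   `attr(, "assigned_fraction")`.
#' @export
phase_individual <- function(cohort, hybrid_id, maternal_ref_id, min_depth = 3,
                             f1_calls = NULL) {
  if (!is.null(f1_calls)) {
    row <- f1_calls[f1_calls$individual_id == maternal_ref_id, , drop = FALSE]
    if (nrow(row) && isTRUE(row$is_f1[1]))
      stop("maternal reference ", maternal_ref_id,
           " is flagged as an F1 hybrid: invalid reference")
  }
  keep <- !site_is_indel(cohort)
  if (!all(keep)) cohort <- subset_sites(cohort, keep)
  h <- call_nucleotides(cohort, hybrid_id)
  m <- call_nucleotides(cohort, maternal_ref_id)
  r <- phase_calls(h$n1, h$n2, m$n1, m$n2, h$dp, m$dp, min_depth)
  out <- data.frame(contig = cohort$sites$contig, pos = cohort$sites$pos,
                    maternal_allele = r$maternal, paternal_allele = r$paternal,
                    rule = r$rule, stringsAsFactors = FALSE)
  class(out) <- c("PhasedSites", "data.frame")
  attr(out, "hybrid_id") <- hybrid_id
  attr(out, "maternal_ref_id") <- maternal_ref_id
  attr(out, "rule_counts") <- table(factor(r$rule, levels = PHASE_RULES))
  attr(out, "assigned_fraction") <- mean(r$maternal != "N")
  out
}

#' Pick the maternal reference individual
#'
#' The highest-mean-depth queen of the maternal species that is not flagged
#' as an F1 hybrid.
#'
#' @param cohort a `CohortMatrix`.
#' @param species maternal species label.
#' @param f1_calls optional [classify_f1()] result used to exclude hybrids.
#' @return an individual id.
#' @export
select_maternal_reference <- function(cohort, species = "ibericus",
                                      f1_calls = NULL) {
  meta <- cohort$individuals
  cand <- meta$caste == "queen" & meta$nominal_species == species
  if (!is.null(f1_calls)) {
    flagged <- f1_calls$individual_id[f1_calls$is_f1]
    cand <- cand & !(meta$individual_id %in% flagged)
  }
  if (!any(cand)) stop("no eligible non-hybrid ", species, " queen in cohort")
  depth <- colMeans(cohort$dp)[cand]
  meta$individual_id[cand][which.max(depth)]
}

#' Reconstruct per-gene haplome sequences from phased sites
#'
#' Substitutes phased alleles into the maternal species' reference gene
#' backbones (`N` at unassigned sites); genes whose reconstructed sequence
#' exceeds `max_gap_fraction` of `N`/gap characters are excluded from the
#' haplome. Site contigs must be gene ids of the backbone; sites outside any
#' gene are counted and skipped with a warning.
#'
#' @param phased a `PhasedSites` data.frame from [phase_individual()].
#' @param backbone named character vector, gene id -> reference sequence.
#' @param max_gap_fraction gene-exclusion threshold on the N/gap fraction.
#' @param strict if `TRUE`, `HOM_SHARED` sites are masked back to `N`,
#'   reproducing the literal het-only assignment rule.
#' @return list with elements `maternal` and `paternal`, each a `Haplome`
#'   (fields `source_individual_id`, `role`, `gene_sequences`,
#'   `assigned_fraction`, `dropped_genes`).
#' @export
build_haplome_sequences <- function(phased, backbone, max_gap_fraction = 0.5,
                                    strict = FALSE) {
  mat_al <- phased$maternal_allele
  pat_al <- phased$paternal_allele
  if (strict) {
    mask <- phased$rule == "HOM_SHARED"
    mat_al[mask] <- "N"; pat_al[mask] <- "N"
  }
  outside <- !(phased$contig %in% names(backbone))
  inside <- which(!outside)
  # positions beyond the gene length also count as outside
  too_far <- inside[phased$pos[inside] > nchar(backbone[phased$contig[inside]])]
  if (length(too_far)) {
    outside[too_far] <- TRUE
    inside <- which(!outside)
  }
  if (any(outside))
    warning(sum(outside), " phased site(s) fall outside the gene backbones; skipped")

  build_role <- function(alleles, role) {
    seqs <- character(0); dropped <- character(0)
    for (g in names(backbone)) {
      ch <- strsplit(backbone[[g]], "")[[1]]
      rows <- inside[phased$contig[inside] == g]
      if (length(rows)) ch[phased$pos[rows]] <- alleles[rows]
      frac_gap <- mean(ch %in% c("N", "-"))
      if (frac_gap > max_gap_fraction) dropped <- c(dropped, g)
      else seqs[[g]] <- paste(ch, collapse = "")
    }
    structure(list(source_individual_id = attr(phased, "hybrid_id") %||% NA_character_,
                   role = role, gene_sequences = seqs,
                   assigned_fraction = mean(alleles[inside] != "N"),
                   dropped_genes = dropped),
              class = "Haplome")
  }
  list(maternal = build_role(mat_al, "maternal"),
       paternal = build_role(pat_al, "paternal"))
}

#' @export
print.Haplome <- function(x, ...) {
  cat("Haplome:", x$source_individual_id, "/", x$role, "-",
      length(x$gene_sequences), "genes,",
      sprintf("%.1f%%", 100 * x$assigned_fraction), "of panel sites assigned")
  if (length(x$dropped_genes)) cat(";", length(x$dropped_genes), "genes dropped")
  cat("\n")
  invisible(x)
}

#' Consensus gene sequences of a non-hybrid individual
#'
#' Homozygous calls are written into the reference backbone; heterozygous
#' positions are treated as missing data (`N`), positions with depth below
#' `min_depth` become gaps, missing calls become `N`, and genes with more
#' than `max_gap_fraction` gaps/N are excluded.
#'
#' @param cohort a `CohortMatrix`.
#' @param individual_id individual to reconstruct.
#' @param backbone named character vector, gene id -> reference sequence.
#' @param min_depth minimum depth for a base call.
#' @param max_gap_fraction gene-exclusion threshold.
#' @return a `Haplome` with role `"consensus"`.
#' @export
consensus_sequence <- function(cohort, individual_id, backbone, min_depth = 3,
                               max_gap_fraction = 0.5) {
  keep <- !site_is_indel(cohort)
  if (!all(keep)) cohort <- subset_sites(cohort, keep)
  x <- call_nucleotides(cohort, individual_id)
  base <- ifelse(is.na(x$n1), "N", ifelse(x$n1 != x$n2, "N", x$n1))
  base[x$dp < min_depth] <- "-"
  inside <- cohort$sites$contig %in% names(backbone) &
    cohort$sites$pos <= nchar(backbone[cohort$sites$contig])
  seqs <- character(0); dropped <- character(0)
  for (g in names(backbone)) {
    ch <- strsplit(backbone[[g]], "")[[1]]
    rows <- which(inside & cohort$sites$contig == g)
    if (length(rows)) ch[cohort$sites$pos[rows]] <- base[rows]
    frac_gap <- mean(ch %in% c("N", "-"))
    if (frac_gap > max_gap_fraction) dropped <- c(dropped, g)
    else seqs[[g]] <- paste(ch, collapse = "")
  }
  structure(list(source_individual_id = individual_id, role = "consensus",
                 gene_sequences = seqs,
                 assigned_fraction = mean(base[inside] != "N" & base[inside] != "-"),
                 dropped_genes = dropped),
            class = "Haplome")
}

#' Write haplomes as FASTA
#'
#' Headers follow `<individual>__<role>`, one record per gene is
#' concatenated in gene order.
#'
#' @param haplomes list of `Haplome`.
#' @param path output FASTA path.
#' @return invisibly, `path`.
#' @export
write_haplomes <- function(haplomes, path) {
  seqs <- vapply(haplomes, function(h)
    paste(h$gene_sequences[sort(names(h$gene_sequences))], collapse = ""),
    character(1))
  names(seqs) <- vapply(haplomes, function(h)
    paste0(h$source_individual_id, "__", h$role), character(1))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Write a per-site phasing audit table
#'
#' @param phased a `PhasedSites` data.frame.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_phasing_audit <- function(phased, path) {
  utils::write.table(as.data.frame(phased), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
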