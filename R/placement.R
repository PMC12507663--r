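# Distance-based placement of haplomes and mitochondrial haplotypes onto
# species/lineage panels, mito-nuclear mismatch detection, clonal-cluster
# discovery and diagnostic-site embryo classification.

# coerce a sequence argument (Haplome, named per-gene vector, or single
# string) to one character vector of single bases, genes concatenated in
# sorted-name order so all parties line up
seq_chars <- function(x) {
  if (inherits(x, "Haplome")) x <- x$gene_sequences
  if (is.list(x)) x <- unlist(x)
  if (is.character(x) && length(x) > 1) {
    if (!is.null(names(x))) x <- x[sort(names(x))]
    x <- paste(x, collapse = "")
  }
  strsplit(x, "")[[1]]
}

#' Pairwise p-distance between two aligned sequences
#'
#' Proportion of differing positions among jointly called (unambiguous
#' `A/C/G/T`) positions; `N` and gap positions are excluded from the
#' denominator. The distance is undefined (`NA`, flagged) when the overlap is
#' below `min_overlap`.
#'
#' @param seq_a,seq_b equal-length sequences (strings, per-gene named vectors
#'   or `Haplome` objects).
#' @param min_overlap minimum number of jointly called sites.
#' @return list with `distance` and `overlap`.
#' @export
p_distance <- function(seq_a, seq_b, min_overlap = 100) {
  a <- seq_chars(seq_a); b <- seq_chars(seq_b)
  if (length(a) != length(b))
    stop("sequence length mismatch: ", length(a), " vs ", length(b))
  valid <- a %in% DNA_BASES4 & b %in% DNA_BASES4
  overlap <- sum(valid)
  d <- if (overlap >= min_overlap) sum(a != b & valid) / overlap else NA_real_
  list(distance = d, overlap = overlap)
}

#' Pairwise p-distance matrix
#'
#' @param seqs named list (or named character vector) of aligned sequences.
#' @param min_overlap minimum joint overlap for a defined distance.
#' @return a `DistanceMatrix`: list with `labels`, `values` (symmetric
#'   p-distance matrix, zero diagonal) and `pairwise_overlap`.
#' @export
p_distance_matrix <- function(seqs, min_overlap = 100) {
  labels <- names(seqs)
  if (is.null(labels)) labels <- paste0("seq", seq_along(seqs))
  chars <- lapply(seqs, seq_chars)
  L <- unique(lengths(chars))
  if (length(L) != 1) stop("sequences must be of equal length")
  n <- length(chars)
  m <- matrix(unlist(chars), nrow = L, ncol = n)
  validm <- matrix(m %in% DNA_BASES4, nrow = L)
  # restrict per-pair work to columns that can differ or have missingness
  all_valid <- rowSums(validm) == n
  all_equal <- rowSums(m == m[, 1]) == n
  const <- all_valid & all_equal
  n_const <- sum(const)
  act <- which(!const)
  values <- matrix(0, n, n, dimnames = list(labels, labels))
  overlap <- matrix(n_const + length(act), n, n, dimnames = list(labels, labels))
  for (i in seq_len(max(n - 1, 0))) for (j in (i + 1):n) {
    v <- validm[act, i] & validm[act, j]
    ov <- n_const + sum(v)
    dd <- if (ov >= min_overlap) sum(m[act, i] != m[act, j] & v) / ov else NA_real_
    values[i, j] <- values[j, i] <- dd
    overlap[i, j] <- overlap[j, i] <- ov
  }
  diag(values) <- 0
  diag(overlap) <- colSums(validm)
  structure(list(labels = labels, values = values, pairwise_overlap = overlap),
            class = "DistanceMatrix")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (which recovers additive trees exactly);
#' negative branch lengths are clamped to zero, with the excess transferred
#' to the sibling branch so pairwise path lengths are preserved as far as
#' possible.
#'
#' @param dm a `DistanceMatrix` (or a plain symmetric matrix with dimnames).
#' @return an unrooted `phylo` tree (write with [ape::write.tree()]).
#' @export
nj_tree <- function(dm) {
  values <- if (inherits(dm, "DistanceMatrix")) dm$values else as.matrix(dm)
  if (nrow(values) < 3) stop("neighbor joining needs at least 3 taxa")
  if (anyNA(values)) stop("distance matrix contains undefined entries")
  tr <- ape::nj(values)
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sib <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(sib)) {
      s <- sib[1]
      tr$edge.length[s] <- tr$edge.length[s] + tr$edge.length[e]
    }
    tr$edge.length[e] <- 0
  }
  tr
}

#' Assign a query sequence to the nearest panel
#'
#' The query is assigned to the panel (named group of reference sequences)
#' with the smallest mean p-distance; support is the fraction of
#' site-bootstrap replicates (columns where the query is called, resampled
#' with replacement) that recover the same panel. Distance ties are broken
#' toward `"unassigned"`.
#'
#' @param query a `Haplome`, named per-gene vector, or single sequence.
#' @param panels named list; each element is a list of member sequences (any
#'   of the accepted forms).
#' @param n_bootstrap bootstrap replicates (0 disables support computation).
#' @param min_margin minimum distance gap between best and second-best panel;
#'   at or below it the result is `"unassigned"`.
#' @param min_overlap minimum joint overlap per member distance.
#' @param query_id label for the result.
#' @return a `PlacementResult`: list with `query_id`, `assigned_group`,
#'   `margin`, `support`, `panel_distances`.
#' @export
assign_by_nearest_panel <- function(query, panels, n_bootstrap = 200,
                                    min_margin = 0, min_overlap = 100,
                                    query_id = NULL) {
  stopifnot(length(panels) >= 1, all(lengths(panels) >= 1))
  if (is.null(query_id))
    query_id <- if (inherits(query, "Haplome"))
      paste0(query$source_individual_id, "__", query$role) else "query"
  qc <- seq_chars(query)
  act <- which(qc %in% DNA_BASES4)
  members <- list(); grp <- character(0)
  for (p in names(panels)) {
    ms <- panels[[p]]
    if (!is.list(ms) || inherits(ms, "Haplome")) ms <- list(ms)
    members <- c(members, ms)
    grp <- c(grp, rep(p, length(ms)))
  }
  J <- length(members)
  M <- matrix(0, length(act), J)   # mismatch indicators on query-called columns
  V <- matrix(0, length(act), J)   # joint-validity indicators
  for (j in seq_len(J)) {
    mc <- seq_chars(members[[j]])
    if (length(mc) != length(qc))
      stop("panel member length ", length(mc), " does not match query length ",
           length(qc))
    mc <- mc[act]
    v <- mc %in% DNA_BASES4
    V[, j] <- v
    M[, j] <- v & mc != qc[act]
  }
  ov <- colSums(V)
  d_member <- ifelse(ov >= min_overlap, colSums(M) / ov, NA_real_)
  panel_d <- tapply(d_member, grp, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) NA_real_ else mean(x)
  })
  panel_d <- panel_d[names(panels)]

  res <- list(query_id = query_id, assigned_group = "unassigned",
              margin = NA_real_, support = NA_real_,
              panel_distances = panel_d)
  class(res) <- "PlacementResult"
  if (all(is.na(panel_d))) return(res)

  o <- order(panel_d)
  best <- names(panel_d)[o[1]]
  margin <- if (length(panel_d) > 1 && !is.na(panel_d[o[2]]))
    panel_d[o[2]] - panel_d[o[1]] else Inf
  res$margin <- unname(margin)
  if (margin <= min_margin) return(res)
  res$assigned_group <- best

  if (n_bootstrap > 0 && length(act) > 0) {
    W <- stats::rmultinom(n_bootstrap, length(act), rep(1, length(act)))
    num <- crossprod(M, W)          # J x B mismatch counts
    den <- crossprod(V, W)          # J x B overlap counts
    db <- num / den
    db[den < min_overlap] <- NA
    wins <- apply(db, 2, function(col) {
      pd <- tapply(col, grp, function(x) {
        x <- x[!is.na(x)]
        if (!length(x)) NA_real_ else mean(x)
      })
      if (all(is.na(pd))) return(NA_character_)
      names(pd)[which.min(pd)]
    })
    res$support <- mean(!is.na(wins) & wins == best)
  }
  res
}

#' @export
print.PlacementResult <- function(x, ...) {
  cat("PlacementResult:", x$query_id, "->", x$assigned_group)
  if (!is.na(x$margin)) cat(sprintf(" (margin %.3g", x$margin))
  if (!is.na(x$support)) cat(sprintf(", support %.2f", x$support))
  if (!is.na(x$margin)) cat(")")
  cat("\n")
  invisible(x)
}

#' Assign a mitochondrial haplotype to a species
#'
#' [assign_by_nearest_panel()] specialized to mitochondrial reference
#' haplotypes (lower default overlap, mito sequences being short).
#'
#' @param query mitochondrial sequence of the focal individual.
#' @param refs named list (or character vector), species label -> reference
#'   mito haplotype(s).
#' @inheritParams assign_by_nearest_panel
#' @return a `PlacementResult`.
#' @export
assign_mito <- function(query, refs, n_bootstrap = 200, min_margin = 0,
                        min_overlap = 50, query_id = NULL) {
  if (is.character(refs)) refs <- as.list(refs)
  refs <- lapply(refs, function(r) if (is.list(r)) r else list(r))
  assign_by_nearest_panel(query, refs, n_bootstrap = n_bootstrap,
                          min_margin = min_margin, min_overlap = min_overlap,
                          query_id = query_id)
}

#' Detect a mito-nuclear mismatch
#'
#' Flags an individual whose nuclear genome and mitochondrial haplotype are
#' assigned to different species -- the signature of a male cloned from
#' allospecific sperm inside a host colony.
#'
#' @param nuclear,mito `PlacementResult` objects for the same individual.
#' @param individual_id optional id for the flag.
#' @return a `MismatchFlag`: list with `individual_id`, `nuclear_species`,
#'   `mito_species`, `is_mismatch` (`NA` = indeterminate when either
#'   placement is unassigned).
#' @export
detect_mito_nuclear_mismatch <- function(nuclear, mito, individual_id = NULL) {
  if (is.null(individual_id)) individual_id <- nuclear$query_id
  nuc <- nuclear$assigned_group
  mit <- mito$assigned_group
  mismatch <- if (nuc == "unassigned" || mit == "unassigned") NA else nuc != mit
  structure(list(individual_id = individual_id, nuclear_species = nuc,
                 mito_species = mit, is_mismatch = mismatch),
            class = "MismatchFlag")
}

#' Single-linkage clonal-cluster detection
#'
#' Clusters sequences by single linkage at `max_intra_distance` and reports
#' the cluster with the lowest mean pairwise distance as "clonal-like". The
#' default threshold is three times the clonal lineage's expected synonymous
#' diversity (0.00027), the regime in which near-identical cloned genomes
#' separate from a wild outcrossing pool.
#'
#' @param seqs named list of sequences (>= 2).
#' @param max_intra_distance single-linkage cut height.
#' @param min_overlap minimum joint overlap per pair.
#' @return list with `membership` (named integer vector), `cluster_stats`
#'   (data.frame: cluster, size, mean_distance), `clonal_cluster` (id of the
#'   lowest-mean-distance cluster with >= 2 members, else the largest
#'   zero-distance cluster) and the `threshold` used.
#' @export
detect_clonal_cluster <- function(seqs, max_intra_distance = 3 * 0.00027,
                                  min_overlap = 100) {
  if (length(seqs) < 2) stop("need at least 2 sequences")
  dm <- p_distance_matrix(seqs, min_overlap = min_overlap)
  vals <- dm$values
  if (anyNA(vals)) {
    warning("undefined distances (overlap too small) treated as maximal")
    vals[is.na(vals)] <- max(vals, na.rm = TRUE) + 1
  }
  hc <- stats::hclust(stats::as.dist(vals), method = "single")
  membership <- stats::cutree(hc, h = max_intra_distance)
  stats_df <- do.call(rbind, lapply(sort(unique(membership)), function(k) {
    idx <- which(membership == k)
    md <- if (length(idx) < 2) 0 else mean(vals[idx, idx][lower.tri(vals[idx, idx])])
    data.frame(cluster = k, size = length(idx), mean_distance = md)
  }))
  multi <- stats_df[stats_df$size >= 2, , drop = FALSE]
  clonal <- if (nrow(multi)) multi$cluster[which.min(multi$mean_distance)]
            else stats_df$cluster[which.max(stats_df$size)]
  list(membership = membership, cluster_stats = stats_df,
       clonal_cluster = clonal, threshold = max_intra_distance)
}

#' Identify interspecific fixed-difference (diagnostic) sites
#'
#' Sites at which two reference groups carry disjoint, fixed alleles; these
#' are the diagnostic sites used for embryo classification and ancestry
#' sanity checks.
#'
#' @param cohort a `CohortMatrix`.
#' @param maternal_ids,paternal_ids pure individuals of the two species.
#' @param min_copies minimum called allele copies per group at a site.
#' @return data.frame with `contig`, `pos`, `maternal_allele`,
#'   `paternal_allele` (allele indices as characters of the cohort's allele
#'   numbering are resolved to nucleotides).
#' @export
fixed_difference_sites <- function(cohort, maternal_ids, paternal_ids,
                                   min_copies = 10) {
  al <- site_alleles(cohort)
  grab <- function(ids) {
    idx <- match(ids, cohort$individuals$individual_id)
    if (anyNA(idx)) stop("unknown individual(s) in reference group")
    cbind(cohort$a1[, idx, drop = FALSE], cohort$a2[, idx, drop = FALSE])
  }
  am <- grab(maternal_ids); ap <- grab(paternal_ids)
  fixed_allele <- function(row) {
    row <- row[!is.na(row)]
    if (length(row) < min_copies) return(NA_integer_)
    u <- unique(row)
    if (length(u) == 1) u else NA_integer_
  }
  fm <- apply(am, 1, fixed_allele)
  fp <- apply(ap, 1, fixed_allele)
  keep <- which(!is.na(fm) & !is.na(fp) & fm != fp)
  data.frame(contig = cohort$sites$contig[keep], pos = cohort$sites$pos[keep],
             maternal_allele = vapply(keep, function(r) al[[r]][fm[r] + 1L], character(1)),
             paternal_allele = vapply(keep, function(r) al[[r]][fp[r] + 1L], character(1)),
             stringsAsFactors = FALSE)
}

#' Classify an embryo from diagnostic sites
#'
#' At interspecific fixed-difference sites, an egg laid androgenetically
#' carries only paternal-species alleles; an F1 egg is heterozygous; an
#' unfertilized (male-destined) egg carries only maternal-species alleles.
#'
#' @param cohort a `CohortMatrix` containing the egg.
#' @param individual_id the egg's id.
#' @param diagnostic data.frame from [fixed_difference_sites()].
#' @param min_sites minimum called diagnostic sites for a call.
#' @param pure_threshold minimum fraction of called diagnostic sites carrying
#'   only one species' alleles for a `maternal_only` / `paternal_only` call.
#' @param het_threshold minimum heterozygous fraction for a `hybrid` call.
#' @return list with `individual_id`, `class` (one of `maternal_only`,
#'   `paternal_only`, `hybrid`, `indeterminate`), `n_called`, and the three
#'   observed fractions.
#' @export
classify_embryo <- function(cohort, individual_id, diagnostic, min_sites = 20,
                            pure_threshold = 0.99, het_threshold = 0.90) {
  key <- paste(cohort$sites$contig, cohort$sites$pos)
  rows <- match(paste(diagnostic$contig, diagnostic$pos), key)
  ok <- !is.na(rows)
  rows <- rows[ok]
  diag_m <- diagnostic$maternal_allele[ok]
  diag_p <- diagnostic$paternal_allele[ok]
  x <- call_nucleotides(cohort, individual_id)
  n1 <- x$n1[rows]; n2 <- x$n2[rows]
  called <- !is.na(n1)
  n_called <- sum(called)
  res <- list(individual_id = individual_id, class = "indeterminate",
              n_called = n_called, frac_maternal_only = NA_real_,
              frac_paternal_only = NA_real_, frac_het = NA_real_)
  if (n_called < min_sites) return(res)
  n1 <- n1[called]; n2 <- n2[called]
  dm <- diag_m[called]; dp_ <- diag_p[called]
  mat_only <- n1 == dm & n2 == dm
  pat_only <- n1 == dp_ & n2 == dp_
  het <- (n1 == dm & n2 == dp_) | (n1 == dp_ & n2 == dm)
  res$frac_maternal_only <- mean(mat_only)
  res$frac_paternal_only <- mean(pat_only)
  res$frac_het <- mean(het)
  res$class <- if (res$frac_paternal_only >= pure_threshold) "paternal_only"
    else if (res$frac_maternal_only >= pure_threshold) "maternal_only"
    else if (res$frac_het >= het_threshold) "hybrid"
    else "indeterminate"
  res
}
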