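# Codon bookkeeping for synonymous/nonsynonymous diversity, standard genetic
# code. Tables are built once at install time from Biostrings::GENETIC_CODE.

codon_env <- local({
  gc_tab <- Biostrings::GENETIC_CODE
  names(gc_tab) <- gsub("U", "T", names(gc_tab))
  sense <- names(gc_tab)[gc_tab != "*"]

  syn_subs <- list(); nonsyn_subs <- list()
  syn_sites <- numeric(length(sense)); names(syn_sites) <- sense
  for (cd in sense) {
    ch <- strsplit(cd, "")[[1]]
    ss <- vector("list", 3); ns <- vector("list", 3)
    tot <- 0
    for (p in 1:3) {
      alts <- setdiff(c("A", "C", "G", "T"), ch[p])
      muts <- vapply(alts, function(b) {
        x <- ch; x[p] <- b; paste(x, collapse = "")
      }, character(1))
      aa <- gc_tab[muts]
      is_stop <- aa == "*"
      is_syn <- !is_stop & aa == gc_tab[cd]
      ss[[p]] <- alts[is_syn]
      ns[[p]] <- alts[!is_syn & !is_stop]
      # synonymous fraction per position, stop-bound changes excluded from the
      # denominator; positions always contribute one site in total
      denom <- 3 - sum(is_stop)
      tot <- tot + if (denom > 0) sum(is_syn) / denom else 0
    }
    syn_subs[[cd]] <- ss; nonsyn_subs[[cd]] <- ns
    syn_sites[cd] <- tot
  }
  e <- new.env(parent = emptyenv())
  e$AA <- gc_tab
  e$SENSE <- sense
  e$SYN_SUBS <- syn_subs
  e$NONSYN_SUBS <- nonsyn_subs
  e$SYN_SITES <- syn_sites
  e$NONSYN_SITES <- 3 - syn_sites
  e$pair_cache <- new.env(parent = emptyenv())
  e
})

#' Synonymous and nonsynonymous site counts of a codon
#'
#' Per codon position, the synonymous fraction is the number of the three
#' single-base changes that preserve the amino acid, divided by the number of
#' changes that do not create a stop codon; each position contributes one site
#' in total, so `syn + nonsyn = 3` for every sense codon.
#'
#' @param codon a 3-letter codon over `A,C,G,T` (case-insensitive).
#' @return list with `syn_sites`, `nonsyn_sites` and `counted` (FALSE for
#'   codons containing ambiguous characters, which contribute zero sites, and
#'   for stop codons, which are excluded with a warning).
#' @export
count_syn_nonsyn_sites <- function(codon) {
  codon <- toupper(codon)
  if (!codon %in% names(codon_env$AA) ||
      !all(strsplit(codon, "")[[1]] %in% c("A", "C", "G", "T")))
    return(list(syn_sites = 0, nonsyn_sites = 0, counted = FALSE))
  if (codon_env$AA[[codon]] == "*") {
    warning("stop codon ", codon, " excluded from site counting")
    return(list(syn_sites = 0, nonsyn_sites = 0, counted = FALSE))
  }
  list(syn_sites = unname(codon_env$SYN_SITES[codon]),
       nonsyn_sites = unname(codon_env$NONSYN_SITES[codon]),
       counted = TRUE)
}

# classify the differences between two sense codons into synonymous /
# nonsynonymous counts, averaging over minimal mutational paths and excluding
# paths that traverse a stop codon. Returns c(syn, nonsyn) or NULL when every
# path goes through a stop.
codon_pair_diffs <- function(a, b) {
  if (a == b) return(c(0, 0))
  key <- paste0(a, b)
  hit <- codon_env$pair_cache[[key]]
  if (!is.null(hit)) return(if (length(hit) == 1 && is.na(hit)) NULL else hit)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  dpos <- which(ca != cb)
  perms <- if (length(dpos) == 1) list(dpos) else {
    if (length(dpos) == 2) list(dpos, rev(dpos)) else {
      out <- list(); k <- 0
      for (i in dpos) for (j in setdiff(dpos, i)) {
        k <- k + 1; out[[k]] <- c(i, j, setdiff(dpos, c(i, j)))
      }
      out
    }
  }
  acc <- matrix(NA_real_, length(perms), 2)
  for (pi_ in seq_along(perms)) {
    cur <- ca; syn <- 0; nonsyn <- 0; ok <- TRUE
    for (p in perms[[pi_]]) {
      nxt <- cur; nxt[p] <- cb[p]
      c1 <- paste(cur, collapse = ""); c2 <- paste(nxt, collapse = "")
      if (codon_env$AA[[c2]] == "*") { ok <- FALSE; break }
      if (codon_env$AA[[c2]] == codon_env$AA[[c1]]) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    if (ok) acc[pi_, ] <- c(syn, nonsyn)
  }
  acc <- acc[stats::complete.cases(acc), , drop = FALSE]
  res <- if (nrow(acc) == 0) NULL else colMeans(acc)
  codon_env$pair_cache[[key]] <- if (is.null(res)) NA else res
  res
}

split_codons <- function(seq) {
  L <- nchar(seq)
  substring(seq, seq(1, L, 3), seq(3, L, 3))
}

#' Pairwise synonymous/nonsynonymous nucleotide diversity
#'
#' Nei–Gojobori-style pairwise diversity over a panel of codon-aligned gene
#' sequences: for every unordered sequence pair and comparable codon (both
#' codons unambiguous sense codons), differences are classified as synonymous
#' or nonsynonymous (multi-difference codons averaged over minimal mutational
#' paths, stop-traversing paths excluded), and
#' `pi_s = sum(syn diffs) / sum(syn sites)` over all pairs (`pi_n` analogous).
#' Codons with `N` or gaps in either sequence are skipped for that pair.
#'
#' @param genes list of `GeneSequenceSet` (must be codon-aligned,
#'   `codon_frame = TRUE`).
#' @param ids sequence ids to compare (default: ids common to all genes).
#' @return a `DiversityEstimate` with point values `pi_s`, `pi_n`, `ratio`
#'   (`NaN` with `ratio_defined = FALSE` when `pi_s` is 0), the per-gene
#'   accumulator table used for gene bootstrap, `n_sequences` and `n_genes`.
#' @export
pairwise_pi <- function(genes, ids = NULL) {
  if (inherits(genes, "GeneSequenceSet")) genes <- list(genes)
  if (is.null(ids)) {
    ids <- Reduce(intersect, lapply(genes, function(g) names(g$sequences)))
  }
  if (length(ids) < 2) stop("need at least 2 sequences")
  per_gene <- data.frame(gene = character(0), syn_diffs = numeric(0),
                         nonsyn_diffs = numeric(0), syn_sites = numeric(0),
                         nonsyn_sites = numeric(0))
  any_codon <- FALSE
  for (g in genes) {
    if (!g$codon_frame)
      stop("gene ", g$gene_id, " is not codon-aligned (length not divisible by 3)")
    seqs <- g$sequences[ids]
    cods <- lapply(seqs, split_codons)
    valid <- lapply(cods, function(cv) cv %in% codon_env$SENSE)
    svec <- lapply(cods, function(cv) {
      s <- codon_env$SYN_SITES[cv]; s[is.na(s)] <- 0; unname(s)
    })
    sd_ <- nd_ <- ss_ <- ns_ <- 0
    n <- length(ids)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      comp <- valid[[i]] & valid[[j]]
      if (!any(comp)) next
      any_codon <- TRUE
      drop_cod <- logical(length(comp))
      dif <- comp & (cods[[i]] != cods[[j]])
      for (k in which(dif)) {
        d <- codon_pair_diffs(cods[[i]][k], cods[[j]][k])
        if (is.null(d)) { drop_cod[k] <- TRUE; next }
        sd_ <- sd_ + d[1]; nd_ <- nd_ + d[2]
      }
      use <- comp & !drop_cod
      s_pair <- (sum(svec[[i]][use]) + sum(svec[[j]][use])) / 2
      tot_pair <- 3 * sum(use)
      ss_ <- ss_ + s_pair
      ns_ <- ns_ + (tot_pair - s_pair)
    }
    per_gene <- rbind(per_gene, data.frame(
      gene = g$gene_id, syn_diffs = sd_, nonsyn_diffs = nd_,
      syn_sites = ss_, nonsyn_sites = ns_))
  }
  if (!any_codon) stop("no comparable codons between the requested sequences")
  pi_from_table(per_gene, n_sequences = length(ids))
}

pi_from_table <- function(per_gene, n_sequences) {
  pi_s <- with(per_gene, if (sum(syn_sites) > 0) sum(syn_diffs) / sum(syn_sites) else 0)
  pi_n <- with(per_gene, if (sum(nonsyn_sites) > 0) sum(nonsyn_diffs) / sum(nonsyn_sites) else 0)
  ratio <- if (pi_s > 0) pi_n / pi_s else NaN
  structure(list(pi_s = pi_s, pi_n = pi_n, ratio = ratio,
                 ratio_defined = pi_s > 0,
                 ci_low = c(pi_s = NA_real_, pi_n = NA_real_, ratio = NA_real_),
                 ci_high = c(pi_s = NA_real_, pi_n = NA_real_, ratio = NA_real_),
                 ci_available = FALSE,
                 n_sequences = n_sequences, n_genes = nrow(per_gene),
                 per_gene = per_gene),
            class = "DiversityEstimate")
}

#' @export
print.DiversityEstimate <- function(x, ...) {
  cat(sprintf("DiversityEstimate: pi_s = %.5g, pi_n = %.5g, pi_n/pi_s = %.4g (%d seqs, %d genes)\n",
              x$pi_s, x$pi_n, x$ratio, x$n_sequences, x$n_genes))
  if (x$ci_available)
    cat(sprintf("  95%% CI: pi_s [%.5g, %.5g], ratio [%.4g, %.4g]\n",
                x$ci_low["pi_s"], x$ci_high["pi_s"],
                x$ci_low["ratio"], x$ci_high["ratio"]))
  invisible(x)
}

#' Diversity with gene-bootstrap confidence intervals
#'
#' Percentile bootstrap over genes (genes resampled with replacement, the
#' pooled `pi_s`, `pi_n` and their ratio recomputed per replicate).
#'
#' @inheritParams pairwise_pi
#' @param n_bootstrap number of bootstrap replicates.
#' @param seed optional integer seed for the resampling.
#' @param conf confidence level.
#' @return a `DiversityEstimate` with `ci_low` / `ci_high` filled in
#'   (`ci_available = FALSE` with a warning when only one gene is supplied).
#' @export
pi_with_ci <- function(genes, ids = NULL, n_bootstrap = 1000, seed = NULL,
                       conf = 0.95) {
  est <- pairwise_pi(genes, ids)
  if (est$n_genes < 2) {
    warning("single gene: bootstrap CI unavailable")
    return(est)
  }
  if (!is.null(seed)) set.seed(seed)
  pg <- est$per_gene
  reps <- matrix(NA_real_, n_bootstrap, 3,
                 dimnames = list(NULL, c("pi_s", "pi_n", "ratio")))
  for (b in seq_len(n_bootstrap)) {
    idx <- sample.int(nrow(pg), nrow(pg), replace = TRUE)
    ss <- sum(pg$syn_sites[idx]); ns <- sum(pg$nonsyn_sites[idx])
    ps <- if (ss > 0) sum(pg$syn_diffs[idx]) / ss else 0
    pn <- if (ns > 0) sum(pg$nonsyn_diffs[idx]) / ns else 0
    reps[b, ] <- c(ps, pn, if (ps > 0) pn / ps else NA_real_)
  }
  al <- (1 - conf) / 2
  est$ci_low <- apply(reps, 2, stats::quantile, probs = al, na.rm = TRUE)
  est$ci_high <- apply(reps, 2, stats::quantile, probs = 1 - al, na.rm = TRUE)
  names(est$ci_low) <- names(est$ci_high) <- c("pi_s", "pi_n", "ratio")
  est$ci_available <- TRUE
  est
}

#' Write a per-lineage diversity report table
#'
#' @param estimates named list of `DiversityEstimate` (names = lineage labels).
#' @param path output TSV path, or `NULL` to just return the data.frame.
#' @return data.frame with one row per lineage.
#' @export
diversity_report <- function(estimates, path = NULL) {
  fmt_ci <- function(e, what) {
    if (!e$ci_available) return(NA_character_)
    sprintf("%.6g-%.6g", e$ci_low[what], e$ci_high[what])
  }
  df <- data.frame(
    lineage = names(estimates),
    n_sequences = vapply(estimates, `[[`, numeric(1), "n_sequences"),
    n_genes = vapply(estimates, `[[`, numeric(1), "n_genes"),
    pi_s = vapply(estimates, `[[`, numeric(1), "pi_s"),
    pi_s_CI = vapply(estimates, fmt_ci, character(1), "pi_s"),
    pi_n = vapply(estimates, `[[`, numeric(1), "pi_n"),
    pi_n_CI = vapply(estimates, fmt_ci, character(1), "pi_n"),
    ratio = vapply(estimates, `[[`, numeric(1), "ratio"),
    ratio_CI = vapply(estimates, fmt_ci, character(1), "ratio"),
    row.names = NULL)
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
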