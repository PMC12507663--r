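# Heterozygosity-based F1 screening and supervised two-source ancestry.

#' Per-individual heterozygosity profile
#'
#' Counts heterozygous calls on the filtered polymorphic site panel and
#' divides by the total panel size (not by the individual's called sites),
#' matching the screening statistic used for hybrid detection. An alternative
#' per-called-sites denominator is available for sensitivity analysis.
#'
#' @param cohort a `CohortMatrix`, already filtered with [filter_sites()].
#' @param individual_id individual to profile.
#' @param denominator `"panel"` (default) or `"called"`.
#' @return a `HetProfile`: list with `individual_id`, `het_sites`,
#'   `panel_size`, `het_proportion`, `ploidy` and `note` (set for haploids,
#'   which cannot be heterozygous).
#' @export
het_proportion <- function(cohort, individual_id,
                           denominator = c("panel", "called")) {
  denominator <- match.arg(denominator)
  i <- cohort_ind_index(cohort, individual_id)
  ploidy <- cohort$individuals$ploidy[i]
  a1 <- cohort$a1[, i]; a2 <- cohort$a2[, i]
  called <- !is.na(a1)
  het <- sum(a1 != a2, na.rm = TRUE)
  note <- NULL
  if (ploidy == 1) {
    if (het > 0)
      warning(individual_id, ": heterozygous calls at a ploidy-1 individual; ",
              "counted as 0")
    het <- 0L
    note <- "haploid: heterozygosity fixed at 0"
  }
  denom <- if (denominator == "panel") n_sites(cohort) else sum(called)
  structure(list(individual_id = individual_id, het_sites = het,
                 panel_size = n_sites(cohort),
                 het_proportion = if (denom > 0) het / denom else 0,
                 ploidy = ploidy, note = note),
            class = "HetProfile")
}

#' Heterozygosity profiles for a set of individuals
#'
#' @inheritParams het_proportion
#' @param ids individual ids (default: all individuals except spermatheca
#'   records, which are pooled sperm, not genotypes of one individual).
#' @return data.frame with columns `individual_id`, `het_sites`, `panel_size`,
#'   `het_proportion`, `ploidy`.
#' @export
het_profiles <- function(cohort, ids = NULL, denominator = c("panel", "called")) {
  denominator <- match.arg(denominator)
  if (is.null(ids)) {
    keep <- cohort$individuals$caste != "spermatheca"
    ids <- cohort$individuals$individual_id[keep]
  }
  rows <- lapply(ids, function(id) {
    p <- suppressWarnings(het_proportion(cohort, id, denominator))
    data.frame(individual_id = p$individual_id, het_sites = p$het_sites,
               panel_size = p$panel_size, het_proportion = p$het_proportion,
               ploidy = p$ploidy, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify first-generation hybrids from heterozygosity
#'
#' One-dimensional two-cluster split at the largest gap between sorted
#' heterozygosity proportions; the upper cluster is flagged as F1 only when
#' the ratio of cluster means exceeds `min_separation` (a guard against
#' flagging noise when no real hybrid group exists).
#'
#' @param profiles data.frame from [het_profiles()] (or a list of
#'   `HetProfile`).
#' @param min_separation minimum upper/lower cluster-mean ratio for flagging.
#' @return data.frame with `individual_id`, `het_proportion`, `is_f1`,
#'   `cluster_mean_low`, `cluster_mean_high`, `separation`.
#' @export
classify_f1 <- function(profiles, min_separation = 5) {
  if (inherits(profiles, "HetProfile")) profiles <- list(profiles)
  if (is.list(profiles) && !is.data.frame(profiles))
    profiles <- do.call(rbind, lapply(profiles, function(p)
      data.frame(individual_id = p$individual_id,
                 het_proportion = p$het_proportion, stringsAsFactors = FALSE)))
  if (nrow(profiles) < 2) stop("need at least 2 profiles to classify")
  v <- profiles$het_proportion
  o <- order(v)
  sv <- v[o]
  gaps <- diff(sv)
  out <- data.frame(individual_id = profiles$individual_id,
                    het_proportion = v, is_f1 = FALSE,
                    cluster_mean_low = mean(v), cluster_mean_high = mean(v),
                    separation = 1, stringsAsFactors = FALSE)
  if (all(gaps == 0)) {
    warning("all heterozygosity values identical; no individuals flagged")
    return(out)
  }
  cut <- which.max(gaps)                      # split after sorted index `cut`
  low <- sv[seq_len(cut)]; high <- sv[(cut + 1):length(sv)]
  m_low <- mean(low); m_high <- mean(high)
  sep <- if (m_low > 0) m_high / m_low else Inf
  out$cluster_mean_low <- m_low
  out$cluster_mean_high <- m_high
  out$separation <- sep
  if (sep > min_separation)
    out$is_f1 <- v >= sv[cut + 1]
  out
}

#' Per-site allele frequencies of two source pools
#'
#' Empirical allele frequencies of a maternal-species and a paternal-species
#' reference group, clamped away from 0 and 1 by `floor` so that fixed
#' differences cannot produce infinite log-likelihoods.
#'
#' @param cohort a filtered `CohortMatrix`.
#' @param maternal_ids,paternal_ids ids of pure individuals of each source.
#' @param floor allele-frequency floor.
#' @return list with matrices `maternal` and `paternal`
#'   (sites x alleles, allele k in column k + 1) and the `floor` used.
#' @export
source_allele_freqs <- function(cohort, maternal_ids, paternal_ids,
                                floor = 1e-3) {
  # allele columns are sized from the whole cohort so both matrices share
  # the same layout regardless of which alleles each pool happens to carry
  maxa <- max(cohort$a1, cohort$a2, 0L, na.rm = TRUE)
  group_freq <- function(ids) {
    idx <- match(ids, cohort$individuals$individual_id)
    if (anyNA(idx)) stop("unknown individual(s): ",
                         paste(ids[is.na(idx)], collapse = ", "))
    a <- cbind(cohort$a1[, idx, drop = FALSE], cohort$a2[, idx, drop = FALSE])
    f <- vapply(seq_len(nrow(a)), function(s) {
      r <- a[s, ]
      r <- r[!is.na(r)]
      cnt <- tabulate(r + 1L, nbins = maxa + 1L)
      if (sum(cnt) == 0) rep(NA_real_, maxa + 1L) else cnt / sum(cnt)
    }, numeric(maxa + 1L))
    f <- matrix(f, ncol = maxa + 1L, byrow = TRUE)
    pmin(pmax(f, floor), 1 - floor)
  }
  list(maternal = group_freq(maternal_ids), paternal = group_freq(paternal_ids),
       floor = floor)
}

#' Supervised two-source ancestry estimate
#'
#' Maximum-likelihood admixture proportion for one individual given per-site
#' allele frequencies of two source pools: `q` maximizes the product over
#' sites and allele copies of `q * p_M + (1 - q) * p_P`, where `p_M`, `p_P`
#' are the carried allele's frequencies in the maternal and paternal pools.
#'
#' @param cohort a filtered `CohortMatrix`.
#' @param individual_id individual to estimate.
#' @param source_freqs result of [source_allele_freqs()].
#' @param tol optimization tolerance on `q` in `[0, 1]`.
#' @return an `AncestryEstimate`: list with `individual_id`, `q_maternal`,
#'   `log_likelihood`, `n_sites_used`.
#' @export
estimate_ancestry <- function(cohort, individual_id, source_freqs, tol = 1e-6) {
  i <- cohort_ind_index(cohort, individual_id)
  pm_mat <- source_freqs$maternal
  pp_mat <- source_freqs$paternal
  n <- n_sites(cohort)
  idx <- cbind(rep(seq_len(n), 2), c(cohort$a1[, i], cohort$a2[, i]) + 1L)
  ok <- !is.na(idx[, 2])
  idx <- idx[ok, , drop = FALSE]
  pm <- pm_mat[idx]; pp <- pp_mat[idx]
  ok2 <- !is.na(pm) & !is.na(pp)
  pm <- pm[ok2]; pp <- pp[ok2]
  if (!length(pm) || all(abs(pm - pp) < .Machine$double.eps))
    stop("panel uninformative: source pools have identical frequencies at all carried alleles")
  ll <- function(q) sum(log(q * pm + (1 - q) * pp))
  opt <- stats::optimize(ll, interval = c(0, 1), maximum = TRUE, tol = tol)
  # optimize never evaluates the exact boundaries; snap when a boundary wins
  cand_q <- c(opt$maximum, 0, 1)
  cand_ll <- c(opt$objective, ll(0), ll(1))
  best <- which.max(cand_ll)
  structure(list(individual_id = individual_id, q_maternal = cand_q[best],
                 log_likelihood = cand_ll[best], n_sites_used = length(pm) / 2),
            class = "AncestryEstimate")
}

#' Two-sided Wilcoxon rank-sum comparison of two groups
#'
#' Thin wrapper around the standard rank-sum test, included for report
#' parity with the heterozygosity group contrast.
#'
#' @param values_a,values_b numeric vectors (both non-empty).
#' @return the two-sided p-value.
#' @export
compare_groups <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) stop("both groups must be non-empty")
  suppressWarnings(stats::wilcox.test(values_a, values_b,
                                      alternative = "two.sided")$p.value)
}
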