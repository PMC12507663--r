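#' @keywords internal
"_PACKAGE"

DNA_BASES4 <- c("A", "C", "G", "T")

#' Construct a cohort genotype matrix
#'
#' A `CohortMatrix` holds bi- or multi-allelic genotype calls (allele indices,
#' read depth, genotype quality) for a set of individuals over an ordered site
#' panel, together with per-individual metadata. Sites are 1-based, VCF-style,
#' and must be strictly increasing by (contig, position).
#'
#' @param sites data.frame with columns `contig`, `pos`, `ref`, `alt`
#'   (`alt` is a comma-separated string of alternate alleles).
#' @param individuals data.frame with columns `individual_id`, `colony_id`,
#'   `caste` (one of queen, worker, male, egg, spermatheca), `nominal_species`
#'   and `ploidy` (1 or 2).
#' @param a1,a2 integer matrices (sites x individuals) of allele indices
#'   (0 = REF, 1 = first ALT, ...); `NA` marks a missing call. A missing call
#'   must be missing in both matrices.
#' @param dp integer matrix of per-call read depths.
#' @param gq numeric matrix of per-call genotype qualities.
#' @return An object of class `CohortMatrix`.
#' @export
new_cohort <- function(sites, individuals, a1, a2, dp, gq) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  obj <- structure(
    list(sites = sites, individuals = individuals,
         a1 = a1, a2 = a2, dp = dp, gq = gq),
    class = "CohortMatrix")
  validate_cohort(obj)
  obj
}

validate_cohort <- function(x) {
  stopifnot(inherits(x, "CohortMatrix"))
  ns <- nrow(x$sites); ni <- nrow(x$individuals)
  for (m in c("a1", "a2", "dp", "gq")) {
    d <- dim(x[[m]])
    if (is.null(d) || d[1] != ns || d[2] != ni)
      stop("matrix '", m, "' does not match site x individual dimensions")
  }
  req <- c("contig", "pos", "ref", "alt")
  if (!all(req %in% names(x$sites)))
    stop("sites table must have columns: ", paste(req, collapse = ", "))
  reqi <- c("individual_id", "colony_id", "caste", "nominal_species", "ploidy")
  if (!all(reqi %in% names(x$individuals)))
    stop("individuals table must have columns: ", paste(reqi, collapse = ", "))
  if (anyDuplicated(x$individuals$individual_id))
    stop("duplicated individual_id in metadata")
  if (any(x$sites$pos < 1)) stop("positions must be >= 1 (1-based, VCF convention)")
  # strictly increasing (contig, pos); contigs must not be interleaved
  ct <- x$sites$contig
  runs <- rle(ct)$values
  if (anyDuplicated(runs)) stop("sites of one contig must be contiguous")
  for (cg in runs) {
    p <- x$sites$pos[ct == cg]
    if (any(diff(p) <= 0)) stop("site positions not strictly increasing on contig ", cg)
  }
  bad <- is.na(x$a1) != is.na(x$a2)
  if (any(bad)) stop("half-missing genotype calls: both allele indices must be missing together")
  pl <- x$individuals$ploidy
  if (!all(pl %in% c(1, 2))) stop("ploidy must be 1 or 2")
  het1 <- which(pl == 1)
  if (length(het1)) {
    h <- x$a1[, het1, drop = FALSE] != x$a2[, het1, drop = FALSE]
    if (any(h, na.rm = TRUE))
      warning("heterozygous calls at ploidy-1 individuals (kept; likely genotyping artifacts)")
  }
  invisible(x)
}

#' @export
print.CohortMatrix <- function(x, ...) {
  cat("CohortMatrix:", nrow(x$sites), "sites x", nrow(x$individuals), "individuals\n")
  cat("  contigs:", length(unique(x$sites$contig)), "\n")
  cat("  castes:", paste(names(table(x$individuals$caste)), table(x$individuals$caste),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

n_sites <- function(cohort) nrow(cohort$sites)
n_individuals <- function(cohort) nrow(cohort$individuals)

#' Alleles of each site
#'
#' @param cohort a `CohortMatrix`.
#' @return list (one element per site) of character vectors `c(REF, ALT...)`,
#'   so allele index k maps to element k + 1.
#' @export
site_alleles <- function(cohort) {
  alt <- strsplit(cohort$sites$alt, ",", fixed = TRUE)
  alt[cohort$sites$alt == "" | is.na(cohort$sites$alt)] <- list(character(0))
  mapply(function(r, a) c(r, a), cohort$sites$ref, alt,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Is a site an indel?
#'
#' True iff any of its alleles has length different from 1.
#' @param cohort a `CohortMatrix`.
#' @return logical vector over sites.
#' @export
site_is_indel <- function(cohort) {
  vapply(site_alleles(cohort), function(a) any(nchar(a) != 1L), logical(1))
}

cohort_ind_index <- function(cohort, individual_id) {
  i <- match(individual_id, cohort$individuals$individual_id)
  if (is.na(i)) stop("individual '", individual_id, "' not found in cohort")
  i
}

# restrict a cohort to a subset of site rows (same individuals)
subset_sites <- function(cohort, keep) {
  if (is.logical(keep)) keep <- which(keep)
  if (!length(keep)) stop("site subset is empty")
  out <- cohort
  out$sites <- cohort$sites[keep, , drop = FALSE]
  rownames(out$sites) <- NULL
  for (m in c("a1", "a2", "dp", "gq"))
    out[[m]] <- cohort[[m]][keep, , drop = FALSE]
  out
}

# nucleotide characters (two vectors over sites) carried by one individual
call_nucleotides <- function(cohort, individual_id) {
  i <- cohort_ind_index(cohort, individual_id)
  al <- site_alleles(cohort)
  maxn <- max(lengths(al))
  amat <- matrix(NA_character_, length(al), maxn)
  for (k in seq_len(maxn)) {
    has <- lengths(al) >= k
    amat[has, k] <- vapply(al[has], `[[`, character(1), k)
  }
  idx1 <- cohort$a1[, i] + 1L
  idx2 <- cohort$a2[, i] + 1L
  n <- n_sites(cohort)
  list(n1 = amat[cbind(seq_len(n), idx1)],
       n2 = amat[cbind(seq_len(n), idx2)],
       dp = cohort$dp[, i], gq = cohort$gq[, i])
}

#' Read a genotyped cohort from VCF + metadata
#'
#' Parses per-sample GT, DP and GQ fields of a VCF (v4.2) and joins them with
#' an individual metadata table. Missing genotypes (`./.` or `.`) are kept as
#' missing calls.
#'
#' @param vcf_path path to a VCF file (plain text or gzipped).
#' @param meta_path path to a tab-separated metadata table with header
#'   `individual_id, colony_id, caste, nominal_species, ploidy` listing every
#'   sample in the VCF.
#' @return a [new_cohort()] `CohortMatrix` with individuals in VCF sample order.
#' @export
read_cohort <- function(vcf_path, meta_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  reqi <- c("individual_id", "colony_id", "caste", "nominal_species", "ploidy")
  if (!all(reqi %in% names(meta)))
    stop("metadata must have columns: ", paste(reqi, collapse = ", "))
  samples <- colnames(v@gt)[-1]
  absent <- setdiff(samples, meta$individual_id)
  if (length(absent))
    stop("sample(s) in VCF absent from metadata: ", paste(absent, collapse = ", "))
  meta <- meta[match(samples, meta$individual_id), , drop = FALSE]
  rownames(meta) <- NULL

  gt <- vcfR::extract.gt(v, "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, "DP", as.numeric = TRUE))
  gq <- suppressWarnings(vcfR::extract.gt(v, "GQ", as.numeric = TRUE))
  if (is.null(gt)) stop("VCF has no per-sample GT field")
  fix_df <- data.frame(contig = fix[, "CHROM"],
                       pos = as.integer(fix[, "POS"]),
                       ref = fix[, "REF"],
                       alt = ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]),
                       stringsAsFactors = FALSE)
  bad_pos <- which(is.na(fix_df$pos))
  if (length(bad_pos))
    stop("malformed VCF record at data line ", bad_pos[1], ": unparseable POS")

  # parse GT strings: "0/1", "0|1", ".", "./.", or haploid "0"
  gs <- gsub("|", "/", as.vector(gt), fixed = TRUE)
  gs[is.na(gs)] <- "."
  parts <- strsplit(gs, "/", fixed = TRUE)
  one <- vapply(parts, `[`, character(1), 1)
  two <- vapply(parts, function(p) if (length(p) >= 2) p[2] else p[1], character(1))
  a1 <- suppressWarnings(as.integer(one)); a2 <- suppressWarnings(as.integer(two))
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  dm <- dim(gt)
  a1 <- matrix(a1, dm[1], dm[2]); a2 <- matrix(a2, dm[1], dm[2])
  storage.mode(dp) <- "integer"
  dp[is.na(dp)] <- 0L
  new_cohort(fix_df, meta, a1, a2, dp, gq)
}

#' Write a cohort to VCF + metadata
#'
#' Emits a minimal VCF v4.2 with per-sample `GT:DP:GQ` fields (readable back
#' with [read_cohort()]) and, optionally, the metadata table.
#'
#' @param cohort a `CohortMatrix`.
#' @param vcf_path output VCF path (plain text).
#' @param meta_path optional output path for the metadata TSV.
#' @return invisibly, `vcf_path`.
#' @export
write_cohort <- function(cohort, vcf_path, meta_path = NULL) {
  ids <- cohort$individuals$individual_id
  hdr <- c("##fileformat=VCFv4.2",
           "##source=xenopop",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                   "FORMAT", ids), collapse = "\t"))
  g1 <- ifelse(is.na(cohort$a1), ".", as.character(cohort$a1))
  g2 <- ifelse(is.na(cohort$a2), ".", as.character(cohort$a2))
  gq <- cohort$gq
  gqs <- ifelse(is.na(gq), ".", format(gq, trim = TRUE, scientific = FALSE))
  cells <- paste0(g1, "/", g2, ":", cohort$dp, ":", gqs)
  dim(cells) <- dim(cohort$a1)
  body <- paste(cohort$sites$contig, cohort$sites$pos, ".",
                cohort$sites$ref,
                ifelse(cohort$sites$alt == "", ".", cohort$sites$alt),
                ".", "PASS", ".", "GT:DP:GQ",
                apply(cells, 1, paste, collapse = "\t"),
                sep = "\t")
  if (n_sites(cohort) == 0) body <- character(0)
  writeLines(c(hdr, body), vcf_path)
  if (!is.null(meta_path))
    utils::write.table(cohort$individuals, meta_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(vcf_path)
}

#' Filter a cohort to the polymorphic SNP panel
#'
#' Applies the standard screening filters: per-call genotype-quality masking
#' (calls with quality at or below `min_quality` become missing, i.e. only
#' quality strictly greater than the threshold survives), indel removal,
#' minor-allele-frequency and per-site missingness thresholds. MAF is computed
#' over called allele copies only; for multi-allelic sites the second most
#' frequent allele defines the MAF. `min_called` is the minimum fraction of
#' individuals with a non-missing call for a site to be retained.
#'
#' @param cohort a `CohortMatrix`.
#' @param min_quality genotype-quality threshold; calls with `GQ <= min_quality`
#'   are set missing. Calls without a quality value are also masked.
#' @param drop_indels drop sites whose alleles are not all single bases.
#' @param min_maf minimum minor-allele frequency among called allele copies.
#' @param min_called minimum fraction of individuals called at a site.
#' @return the filtered `CohortMatrix` (the polymorphic site panel).
#' @export
filter_sites <- function(cohort, min_quality = 10, drop_indels = TRUE,
                         min_maf = 0.05, min_called = 0.8) {
  if (n_sites(cohort) == 0 || n_individuals(cohort) == 0)
    stop("cohort is empty")
  mask <- is.na(cohort$gq) | cohort$gq <= min_quality
  cohort$a1[mask] <- NA_integer_
  cohort$a2[mask] <- NA_integer_

  keep <- rep(TRUE, n_sites(cohort))
  if (drop_indels) keep <- keep & !site_is_indel(cohort)

  called <- !is.na(cohort$a1)
  keep <- keep & (rowMeans(called) >= min_called)

  maf <- apply(cbind(cohort$a1, cohort$a2), 1, function(r) {
    r <- r[!is.na(r)]
    if (!length(r)) return(0)
    tab <- sort(tabulate(r + 1L), decreasing = TRUE)
    tab <- tab[tab > 0]
    if (length(tab) < 2) return(0)
    tab[2] / sum(tab)
  })
  keep <- keep & (maf >= min_maf)

  if (!any(keep))
    stop("all sites removed by filtering; review min_maf/min_called/min_quality")
  subset_sites(cohort, keep)
}

#' Read per-gene aligned sequences
#'
#' Reads one aligned FASTA per gene from a directory; sequences are upper-cased
#' and validated to a common length within each gene.
#'
#' @param fasta_dir directory containing `*.fa` / `*.fasta` files, one per gene
#'   (gene id = file name without extension).
#' @return list of `GeneSequenceSet` objects (fields `gene_id`, `sequences`
#'   (named character vector over `A,C,G,T,N,-`), `codon_frame`).
#' @export
read_gene_sequences <- function(fasta_dir) {
  files <- sort(list.files(fasta_dir, pattern = "\\.(fa|fasta)$", full.names = TRUE))
  if (!length(files)) stop("no FASTA files found in ", fasta_dir)
  lapply(files, function(f) {
    ss <- Biostrings::readBStringSet(f)
    seqs <- toupper(as.character(ss))
    gene_id <- sub("\\.(fa|fasta)$", "", basename(f))
    new_gene_set(gene_id, seqs)
  })
}

#' @rdname read_gene_sequences
#' @param gene_id gene identifier.
#' @param sequences named character vector of aligned sequences.
#' @export
new_gene_set <- function(gene_id, sequences) {
  sequences <- toupper(sequences)
  w <- unique(nchar(sequences))
  if (length(w) > 1)
    stop("ragged alignment in gene ", gene_id, ": lengths ", paste(w, collapse = ", "))
  structure(list(gene_id = gene_id, sequences = sequences,
                 codon_frame = (length(w) == 1 && w %% 3 == 0)),
            class = "GeneSequenceSet")
}

#' @export
print.GeneSequenceSet <- function(x, ...) {
  cat("GeneSequenceSet", x$gene_id, ":", length(x$sequences), "sequences x",
      if (length(x$sequences)) nchar(x$sequences[[1]]) else 0, "bp; codon_frame =",
      x$codon_frame, "\n")
  invisible(x)
}

#' Write per-gene FASTA files
#'
#' @param genes list of `GeneSequenceSet`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_gene_sequences <- function(genes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in genes) {
    ss <- Biostrings::BStringSet(g$sequences)
    Biostrings::writeXStringSet(ss, file.path(dir, paste0(g$gene_id, ".fasta")))
  }
  invisible(dir)
}
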