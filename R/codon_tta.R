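#' Scan a CDS for in-frame TTA codons
#'
#' Only frame-0 codons are inspected, so a `TTA` spanning a codon boundary
#' never counts.  Matching is case-insensitive; codons containing
#' ambiguity characters never match.  TTA (UUA on the mRNA) is the only
#' leucine codon made solely of A and T, hence rare in GC-rich genomes and
#' the target of the bldA tRNA in streptomycetes.
#'
#' @param cds Nucleotide string, length >= 3.
#' @return List of class `tta_report`: `tta_codon_indices` (1-based codon
#'   positions), `first_tta_relative` (`(first - 1) / codon_count`, or `NA`
#'   when no TTA), and `codon_count` (including any stop codon).
#' @export
scan_tta <- function(cds) {
  if (is.na(cds) || nchar(cds) < 3)
    abort_fmt("scan_tta: CDS shorter than one codon")
  cds <- toupper(cds)
  n_codon <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  idx <- which(codons == "TTA")
  structure(list(
    tta_codon_indices = idx,
    first_tta_relative = if (length(idx)) (idx[1] - 1) / n_codon else
      NA_real_,
    codon_count = n_codon),
    class = "tta_report")
}

#' Count genes carrying at least one in-frame TTA codon
#'
#' @param genome A `genome`.
#' @param replicon_filter Optional character vector of replicon ids to
#'   restrict to (e.g. the chromosome only).
#' @return Integer count.
#' @export
count_tta_genes <- function(genome, replicon_filter = NULL) {
  genes <- genome$genes
  if (!is.null(replicon_filter))
    genes <- genes[genes$replicon_id %in% replicon_filter, ]
  sum(vapply(genes$cds, function(cds) {
    !is.na(cds) && nchar(cds) >= 3 &&
      length(scan_tta(cds)$tta_codon_indices) > 0
  }, logical(1), USE.NAMES = FALSE))
}

#' Fill TTA flags on a profile matrix
#'
#' Sets `tta_in_target` for every non-absent call by scanning the target
#' gene's CDS, and records which reference genes themselves carry a TTA.
#'
#' @param matrix A `profile_matrix`.
#' @param registry The registry it was built from.
#' @return The matrix with flags populated (and a `ref_tta` logical vector
#'   attached).
#' @export
add_tta_flags <- function(matrix, registry) {
  gene_has_tta <- function(g, gid) {
    cds <- g$genes[gid, "cds"]
    !is.na(cds) && nchar(cds) >= 3 &&
      length(scan_tta(cds)$tta_codon_indices) > 0
  }
  calls <- matrix$calls
  for (i in seq_len(nrow(calls))) {
    if (calls$status[i] == "absent") next
    g <- registry$genomes[[calls$genome_id[i]]]
    calls$tta_in_target[i] <- gene_has_tta(g, calls$target_gene_id[i])
  }
  matrix$calls <- calls
  ref <- registry$genomes[[registry$reference_id]]
  matrix$ref_tta <- setNames(
    vapply(matrix$genes, function(gid) gene_has_tta(ref, gid), logical(1)),
    matrix$genes)
  matrix
}

#' Conserved-TTA table across orthologues
#'
#' For each reference gene with at least one orthologue, tabulates how many
#' of its orthologues carry an in-frame TTA codon.  Denominators count only
#' genomes where the orthologue exists (sub-threshold hits excluded by
#' default), so fractions like "6/12" vary per gene.  A gene is `included`
#' when at least `min_other` non-reference genomes have a TTA-bearing
#' orthologue.
#'
#' @param matrix A `profile_matrix` with TTA flags populated.
#' @param min_other Inclusion threshold (default 5).
#' @param count_sub_threshold Count sub-threshold hits in the denominator
#'   and numerator (default FALSE).
#' @return Data frame with `ref_gene_id`, `ref_has_tta`, `n_orthologues`,
#'   `n_with_tta`, `fraction_text`, `included`.
#' @export
conserved_tta_table <- function(matrix, min_other = 5L,
                                count_sub_threshold = FALSE) {
  statuses <- "orthologue"
  if (count_sub_threshold) statuses <- c(statuses, "sub_threshold")
  calls <- matrix$calls[matrix$calls$status %in% statuses, ]
  if (nrow(calls) && anyNA(calls$tta_in_target))
    abort_fmt(paste("tta_in_target flags are not populated;",
                    "run add_tta_flags() first"))
  rows <- lapply(matrix$genes, function(gid) {
    sub <- calls[calls$ref_gene_id == gid, ]
    if (!nrow(sub)) return(NULL)
    n <- nrow(sub)
    k <- sum(sub$tta_in_target)
    data.frame(ref_gene_id = gid,
               ref_has_tta = isTRUE(matrix$ref_tta[[gid]]),
               n_orthologues = n, n_with_tta = k,
               fraction_text = sprintf("%d/%d", k, n),
               included = k >= min_other,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(ref_gene_id = character(), ref_has_tta = logical(),
                      n_orthologues = integer(), n_with_tta = integer(),
                      fraction_text = character(), included = logical())
  out
}

#' Test 5' positional bias of TTA codons
#'
#' In streptomycetes TTA codons cluster towards the start of genes.  For
#' every TTA-containing gene the position of its first TTA is expressed as
#' a fraction of codon length; the test counts genes whose first TTA falls
#' in the first third and compares against the uniform null (proportion
#' 1/3) with a one-sided exact binomial test.
#'
#' @param genome A `genome` with CDSs.
#' @param replicon_filter Optional replicon restriction.
#' @return List with `n_tta_genes`, `k_first_third`, `p_value`.
#' @export
positional_bias_test <- function(genome, replicon_filter = NULL) {
  genes <- genome$genes
  if (!is.null(replicon_filter))
    genes <- genes[genes$replicon_id %in% replicon_filter, ]
  firsts <- vapply(genes$cds, function(cds) {
    if (is.na(cds) || nchar(cds) < 3) return(NA_real_)
    scan_tta(cds)$first_tta_relative
  }, numeric(1), USE.NAMES = FALSE)
  firsts <- firsts[!is.na(firsts)]
  n <- length(firsts)
  if (n == 0)
    abort_fmt("positional_bias_test: no TTA-containing genes in genome %s",
              genome$genome_id)
  k <- sum(firsts < 1 / 3)
  p <- stats::binom.test(k, n, p = 1 / 3, alternative = "greater")$p.value
  list(n_tta_genes = n, k_first_third = k, p_value = p)
}

#' Write the conserved-TTA table as TSV
#' @param table Output of [conserved_tta_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tta_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
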