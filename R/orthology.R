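#' Orthology acceptance thresholds
#'
#' A reciprocal best hit is promoted to an orthologue call only when it
#' reaches a minimum percent identity and a minimum alignment overlap as a
#' fraction of the shorter protein; reciprocal hits below these criteria
#' are retained as sub-threshold ("grey box") calls.  Defaults are 40%
#' identity and 0.6 overlap fraction.
#'
#' @param min_identity_pct Minimum percent identity, in (0, 100].
#' @param min_overlap_fraction_of_shorter Minimum overlap / length of the
#'   shorter protein, in (0, 1].
#' @return An object of class `orthology_thresholds`.
#' @export
orthology_thresholds <- function(min_identity_pct = 40,
                                 min_overlap_fraction_of_shorter = 0.6) {
  stopifnot(min_identity_pct > 0, min_identity_pct <= 100,
            min_overlap_fraction_of_shorter > 0,
            min_overlap_fraction_of_shorter <= 1)
  structure(list(min_identity_pct = min_identity_pct,
                 min_overlap_fraction_of_shorter =
                   min_overlap_fraction_of_shorter),
            class = "orthology_thresholds")
}

meets_thresholds <- function(al, qlen, tlen, thresholds) {
  al$identity_pct >= thresholds$min_identity_pct &&
    al$overlap >= thresholds$min_overlap_fraction_of_shorter * min(qlen, tlen)
}

empty_call <- function(ref_gene_id, genome_id, status = "absent",
                       target_gene_id = NA_character_, alignment = NULL) {
  data.frame(ref_gene_id = ref_gene_id, genome_id = genome_id,
             status = status, target_gene_id = target_gene_id,
             score = if (is.null(alignment)) NA_integer_ else alignment$score,
             identity_pct = if (is.null(alignment)) NA_real_ else
               alignment$identity_pct,
             overlap = if (is.null(alignment)) NA_integer_ else
               alignment$overlap,
             coverage_query = if (is.null(alignment)) NA_real_ else
               alignment$coverage_query,
             coverage_target = if (is.null(alignment)) NA_real_ else
               alignment$coverage_target,
             tta_in_target = NA,
             stringsAsFactors = FALSE)
}

#' Reciprocal-best-hit orthology calls between two genomes
#'
#' For each reference gene the best hit in the target genome is computed;
#' if that target gene's own best hit back into the reference is the
#' original gene, the pair is reciprocal and is classified `orthologue`
#' (thresholds met) or `sub_threshold` (reciprocal but below criteria);
#' otherwise the call is `absent`.  Backward best hits are cached so each
#' target gene is searched at most once.
#'
#' @param ref,target `genome` objects with distinct ids.
#' @param scheme A [scoring_scheme()].
#' @param thresholds An [orthology_thresholds()].
#' @param gene_subset Optional reference gene ids to restrict to.
#' @param prefilter Passed to [best_hit()].
#' @return Data frame of calls, one row per reference gene.
#' @export
reciprocal_best_hits <- function(ref, target, scheme = scoring_scheme(),
                                 thresholds = orthology_thresholds(),
                                 gene_subset = NULL, prefilter = TRUE) {
  if (identical(ref$genome_id, target$genome_id))
    abort_fmt("reciprocal_best_hits: ref and target are the same genome")
  if (!nrow(ref$genes) || !nrow(target$genes))
    abort_fmt("reciprocal_best_hits: empty proteome")
  genes <- gene_subset %||% ref$genes$gene_id
  unknown <- setdiff(genes, ref$genes$gene_id)
  if (length(unknown))
    abort_fmt("unknown reference gene id(s): %s",
              paste(unknown, collapse = ", "))
  back_cache <- new.env(parent = emptyenv())
  calls <- lapply(genes, function(gid) {
    fwd <- best_hit(ref$genes[gid, ], target, scheme, prefilter = prefilter)
    if (is.null(fwd)) return(empty_call(gid, target$genome_id))
    tid <- fwd$gene_id
    back <- if (exists(tid, envir = back_cache)) get(tid, envir = back_cache)
    else {
      b <- best_hit(target$genes[tid, ], ref, scheme, prefilter = prefilter)
      assign(tid, b, envir = back_cache)
      b
    }
    if (is.null(back) || back$gene_id != gid)
      return(empty_call(gid, target$genome_id))
    status <- if (meets_thresholds(fwd$alignment,
                                   nchar(ref$genes[gid, "protein"]),
                                   nchar(target$genes[tid, "protein"]),
                                   thresholds)) "orthologue" else
                                     "sub_threshold"
    empty_call(gid, target$genome_id, status, tid, fwd$alignment)
  })
  do.call(rbind, calls)
}

#' Build the reference-anchored orthology profile matrix
#'
#' Runs [reciprocal_best_hits()] of the registry's reference genome against
#' every other genome and assembles the complete three-state call matrix
#' (genes x genomes, genomes in taxon-group display order).  TTA flags are
#' populated from the target CDSs when available.
#'
#' @param registry A [genome_registry()].
#' @param gene_subset Optional reference gene ids (rows); default all.
#' @param scheme,thresholds,prefilter As in [reciprocal_best_hits()].
#' @param scan_tta_flags Fill `tta_in_target` for non-absent calls.
#' @return An object of class `profile_matrix`: list with `reference_id`,
#'   `genes`, `genomes`, and a `calls` data frame with one row per
#'   (gene, genome) cell.
#' @export
build_profile <- function(registry, gene_subset = NULL,
                          scheme = scoring_scheme(),
                          thresholds = orthology_thresholds(),
                          prefilter = TRUE, scan_tta_flags = TRUE) {
  ref <- registry$genomes[[registry$reference_id]]
  genes <- gene_subset %||% ref$genes$gene_id
  unknown <- setdiff(genes, ref$genes$gene_id)
  if (length(unknown))
    abort_fmt("unknown gene id(s) in subset: %s",
              paste(unknown, collapse = ", "))
  targets <- registry_genome_order(registry)
  calls <- do.call(rbind, lapply(targets, function(tid) {
    reciprocal_best_hits(ref, registry$genomes[[tid]], scheme, thresholds,
                         gene_subset = genes, prefilter = prefilter)
  }))
  pm <- structure(list(reference_id = registry$reference_id, genes = genes,
                       genomes = targets, calls = calls,
                       thresholds = thresholds),
                  class = "profile_matrix")
  if (scan_tta_flags) pm <- add_tta_flags(pm, registry)
  pm
}

#' @export
print.profile_matrix <- function(x, ...) {
  tab <- table(factor(x$calls$status,
                      c("orthologue", "sub_threshold", "absent")))
  cat(sprintf(
    "<profile_matrix> ref %s: %d genes x %d genomes (%d orthologue, %d sub-threshold, %d absent)\n",
    x$reference_id, length(x$genes), length(x$genomes),
    tab[["orthologue"]], tab[["sub_threshold"]], tab[["absent"]]))
  invisible(x)
}

profile_cell <- function(matrix, gene_id, genome_id) {
  i <- matrix$calls$ref_gene_id == gene_id &
    matrix$calls$genome_id == genome_id
  matrix$calls[i, , drop = FALSE]
}

#' Presence/absence vector of one reference gene across genomes
#'
#' @param matrix A `profile_matrix`.
#' @param gene_id Reference gene id (must be a matrix row).
#' @param count_sub_threshold Treat sub-threshold reciprocal hits as
#'   presence (default FALSE).
#' @return Named integer vector (0/1) over the matrix's genomes.
#' @export
presence_vector <- function(matrix, gene_id, count_sub_threshold = FALSE) {
  if (!gene_id %in% matrix$genes)
    abort_fmt("gene %s not in profile matrix", gene_id)
  rows <- matrix$calls[matrix$calls$ref_gene_id == gene_id, ]
  ok <- rows$status == "orthologue"
  if (count_sub_threshold) ok <- ok | rows$status == "sub_threshold"
  setNames(as.integer(ok), rows$genome_id)[matrix$genomes]
}

#' Write a profile matrix as TSV
#'
#' One row per reference gene, one column per genome; cells are
#' `O:<identity>` for orthologues, `S:<identity>` for sub-threshold hits
#' and `-` for absences, with identity rounded to one decimal.
#'
#' @param matrix A `profile_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile_tsv <- function(matrix, path) {
  cell_txt <- function(st, id) switch(st,
    orthologue = sprintf("O:%.1f", id),
    sub_threshold = sprintf("S:%.1f", id),
    "-")
  wide <- matrix(
    "-", nrow = length(matrix$genes), ncol = length(matrix$genomes),
    dimnames = list(matrix$genes, matrix$genomes))
  for (i in seq_len(nrow(matrix$calls))) {
    row <- matrix$calls[i, ]
    wide[row$ref_gene_id, row$genome_id] <-
      cell_txt(row$status, row$identity_pct)
  }
  df <- data.frame(gene = rownames(wide), wide, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
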