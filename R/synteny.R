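#' Gene neighbourhood on a replicon
#'
#' Up to `w` genes on each side of a gene, on the same replicon, in gene
#' order; truncated at replicon ends.  Replicons are treated as linear
#' arrays (circularity is not modelled).
#'
#' @param genome A `genome`.
#' @param gene_id Focal gene.
#' @param w Window half-width (non-negative integer).
#' @return Character vector of neighbour gene ids (excluding the focal
#'   gene), in positional order.
#' @export
neighborhood <- function(genome, gene_id, w) {
  if (!gene_id %in% genome$genes$gene_id)
    abort_fmt("gene %s not in genome %s", gene_id, genome$genome_id)
  w <- as.integer(w)
  if (w == 0L) return(character(0))
  rec <- genome$genes[gene_id, ]
  repl <- genome$genes[genome$genes$replicon_id == rec$replicon_id, ]
  repl <- repl[order(repl$ordinal), ]
  pos <- rec$ordinal
  keep <- abs(repl$ordinal - pos) <= w & repl$ordinal != pos
  repl$gene_id[keep]
}

#' Local synteny around an orthologue pair
#'
#' Conservation of the immediate gene neighbourhood around an orthologue
#' pair, used as corroborating evidence for orthology.  Each of the up to
#' `2w` reference neighbours contributes when its own orthologue in the
#' target genome lies within `w` gene positions of the partner gene on the
#' same replicon (strand-agnostic, either side).  Neighbours whose call is
#' sub-threshold count by default, since weak hits are exactly the cases
#' synteny is asked to rescue.
#'
#' @param matrix A `profile_matrix` over the registry.
#' @param registry The `genome_registry`.
#' @param ref_gene_id Reference gene (must have a non-absent call in
#'   `genome_id`).
#' @param genome_id Target genome.
#' @param w Window half-width (default 5).
#' @param s_min Minimum shared neighbours for a "has local synteny"
#'   verdict (default 2).
#' @param count_sub_threshold Count sub-threshold neighbour calls
#'   (default TRUE).
#' @return List of class `synteny_result`: `ref_gene_id`, `genome_id`,
#'   `window`, `shared_neighbors`, `has_local_synteny`.
#' @export
synteny_score <- function(matrix, registry, ref_gene_id, genome_id,
                          w = 5L, s_min = 2L, count_sub_threshold = TRUE) {
  cell <- profile_cell(matrix, ref_gene_id, genome_id)
  if (!nrow(cell) || cell$status == "absent")
    abort_fmt("no reciprocal hit for %s in %s: synteny undefined",
              ref_gene_id, genome_id)
  ref <- registry$genomes[[registry$reference_id]]
  tgt <- registry$genomes[[genome_id]]
  partner <- tgt$genes[cell$target_gene_id, ]
  ok_status <- "orthologue"
  if (count_sub_threshold) ok_status <- c(ok_status, "sub_threshold")

  shared <- 0L
  for (nb in neighborhood(ref, ref_gene_id, w)) {
    nb_cell <- profile_cell(matrix, nb, genome_id)
    if (!nrow(nb_cell) || !(nb_cell$status %in% ok_status)) next
    nb_tgt <- tgt$genes[nb_cell$target_gene_id, ]
    if (nb_tgt$replicon_id == partner$replicon_id &&
        abs(nb_tgt$ordinal - partner$ordinal) <= w &&
        nb_tgt$gene_id != partner$gene_id)
      shared <- shared + 1L
  }
  structure(list(ref_gene_id = ref_gene_id, genome_id = genome_id,
                 window = as.integer(w), shared_neighbors = shared,
                 has_local_synteny = shared >= s_min),
            class = "synteny_result")
}

#' Synteny verdicts for every non-absent cell of a gene's profile row
#'
#' @param matrix,registry As in [synteny_score()].
#' @param ref_gene_id Reference gene.
#' @param ... Passed to [synteny_score()].
#' @return Data frame, one row per genome with a reciprocal hit.
#' @export
synteny_profile <- function(matrix, registry, ref_gene_id, ...) {
  rows <- matrix$calls[matrix$calls$ref_gene_id == ref_gene_id &
                         matrix$calls$status != "absent", ]
  out <- lapply(rows$genome_id, function(gid) {
    s <- synteny_score(matrix, registry, ref_gene_id, gid, ...)
    data.frame(ref_gene_id = ref_gene_id, genome_id = gid,
               shared_neighbors = s$shared_neighbors,
               has_local_synteny = s$has_local_synteny,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out) %||%
    data.frame(ref_gene_id = character(), genome_id = character(),
               shared_neighbors = integer(), has_local_synteny = logical())
}
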