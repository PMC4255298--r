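#' Construct a gene record
#'
#' A gene record couples a protein sequence with its coding sequence (CDS,
#' already in coding orientation) and its ordinal position along a replicon.
#'
#' @param gene_id Identifier, unique within its genome.
#' @param protein Amino-acid sequence (non-empty string).
#' @param cds Nucleotide sequence in coding orientation, or `NA` if absent.
#' @param replicon_id Replicon (chromosome/plasmid) identifier.
#' @param ordinal 0-based position in gene order along the replicon.
#' @param strand `"+"` or `"-"`; metadata only, the CDS is authoritative.
#' @return A one-row data frame of class `gene_record` with a `partial`
#'   flag set when the CDS length is not a multiple of 3.
#' @export
gene_record <- function(gene_id, protein, cds = NA_character_,
                        replicon_id = "chr", ordinal = 0L, strand = "+") {
  if (!nzchar(protein)) abort_fmt("gene %s: empty protein sequence", gene_id)
  if (!is.na(cds)) {
    bad <- gsub("[ACGTNacgtn]", "", cds)
    if (nzchar(bad))
      abort_fmt("gene %s: non-nucleotide character '%s' in CDS",
                gene_id, substr(bad, 1, 1))
  }
  partial <- !is.na(cds) && nchar(cds) %% 3L != 0L
  structure(
    data.frame(gene_id = gene_id, protein = toupper(protein),
               cds = if (is.na(cds)) NA_character_ else toupper(cds),
               replicon_id = replicon_id, ordinal = as.integer(ordinal),
               strand = strand, partial = partial,
               stringsAsFactors = FALSE),
    class = c("gene_record", "data.frame"))
}

#' Construct a genome
#'
#' @param genome_id Genome identifier.
#' @param genes Data frame with the `gene_record` columns, one row per gene,
#'   in gene order.
#' @param taxon_group Group label used for display ordering and colouring.
#' @return An object of class `genome`.
#' @export
genome <- function(genome_id, genes, taxon_group = "ungrouped") {
  stopifnot(is.data.frame(genes), nrow(genes) > 0)
  if (anyDuplicated(genes$gene_id))
    abort_fmt("genome %s: duplicated gene ids (%s)", genome_id,
              genes$gene_id[duplicated(genes$gene_id)][1])
  for (rep in unique(genes$replicon_id)) {
    ords <- sort(genes$ordinal[genes$replicon_id == rep])
    if (!identical(ords, seq(0L, length(ords) - 1L)))
      abort_fmt("genome %s: ordinals on replicon %s are not consecutive",
                genome_id, rep)
  }
  rownames(genes) <- genes$gene_id
  structure(list(genome_id = genome_id, taxon_group = taxon_group,
                 genes = genes),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s [%s]: %d genes on %d replicon(s)\n",
              x$genome_id, x$taxon_group, nrow(x$genes),
              length(unique(x$genes$replicon_id))))
  invisible(x)
}

#' Read a genome from protein FASTA, CDS FASTA and an annotation table
#'
#' The annotation table is a headered TSV with columns `gene_id`,
#' `replicon_id`, `start`, `end`, `strand` (1-based inclusive coordinates,
#' as in GFF).  Gene ordinals are assigned from row order within each
#' replicon.  Minus-strand CDSs must already be reverse-complemented into
#' coding orientation in the CDS FASTA; the `strand` column is metadata.
#'
#' @param protein_fasta,cds_fasta Paths to FASTA files with matching ids.
#' @param annotation Path to the annotation TSV.
#' @param genome_id Genome id; defaults to the annotation file stem.
#' @param taxon_group Group label.
#' @param validate Check translation of every complete CDS (default TRUE).
#' @return A `genome`.
#' @export
read_genome <- function(protein_fasta, cds_fasta, annotation,
                        genome_id = NULL, taxon_group = "ungrouped",
                        validate = TRUE) {
  prot <- Biostrings::readAAStringSet(protein_fasta)
  cds <- Biostrings::readDNAStringSet(cds_fasta)
  names(prot) <- sub("\\s.*$", "", names(prot))
  names(cds) <- sub("\\s.*$", "", names(cds))
  ann <- read.delim(annotation, stringsAsFactors = FALSE)
  need <- c("gene_id", "replicon_id", "start", "end", "strand")
  if (!all(need %in% names(ann)))
    abort_fmt("annotation lacks column(s): %s",
              paste(setdiff(need, names(ann)), collapse = ", "))

  missing_cds <- setdiff(names(prot), names(cds))
  if (length(missing_cds))
    abort_fmt("id(s) present in protein FASTA but absent from CDS FASTA: %s",
              paste(missing_cds, collapse = ", "))
  missing_ann <- setdiff(names(prot), ann$gene_id)
  if (length(missing_ann))
    abort_fmt("id(s) present in FASTA but absent from annotation: %s",
              paste(missing_ann, collapse = ", "))
  missing_fa <- setdiff(ann$gene_id, names(prot))
  if (length(missing_fa))
    abort_fmt("id(s) present in annotation but absent from protein FASTA: %s",
              paste(missing_fa, collapse = ", "))

  ord <- stats::ave(seq_len(nrow(ann)), ann$replicon_id,
                    FUN = function(i) seq_along(i) - 1L)
  rows <- lapply(seq_len(nrow(ann)), function(i) {
    id <- ann$gene_id[i]
    gene_record(id, as.character(prot[[id]]), as.character(cds[[id]]),
                ann$replicon_id[i], ord[i], ann$strand[i])
  })
  g <- genome(genome_id %||% sub("\\.[^.]*$", "", basename(annotation)),
              do.call(rbind, rows), taxon_group)
  if (validate) {
    for (i in seq_len(nrow(g$genes))) {
      rec <- g$genes[i, ]
      if (!is.na(rec$cds) && !rec$partial) {
        v <- validate_translation(rec)
        if (!v$ok)
          abort_fmt("gene %s: %s", rec$gene_id, v$message)
      }
    }
  }
  g
}

#' Write a genome back to the input formats
#'
#' Emits protein FASTA, CDS FASTA and the annotation TSV so that
#' `read_genome()` on the output reproduces sequences and gene order
#' exactly.  Start/end coordinates are synthesised from cumulative CDS
#' lengths when the genome was built in memory.
#'
#' @param g A `genome`.
#' @param dir Output directory (created if needed).
#' @param prefix File name stem; defaults to the genome id.
#' @return Invisibly, the three paths written.
#' @export
write_genome <- function(g, dir, prefix = g$genome_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- g$genes
  paths <- file.path(dir, paste0(prefix, c(".faa", ".fna", ".tsv")))
  prot <- Biostrings::AAStringSet(setNames(genes$protein, genes$gene_id))
  Biostrings::writeXStringSet(prot, paths[1])
  cds <- Biostrings::DNAStringSet(setNames(genes$cds, genes$gene_id))
  Biostrings::writeXStringSet(cds, paths[2])
  pos <- cumsum(c(1L, utils::head(nchar(genes$cds) + 100L, -1L)))
  ann <- data.frame(gene_id = genes$gene_id, replicon_id = genes$replicon_id,
                    start = pos, end = pos + nchar(genes$cds) - 1L,
                    strand = genes$strand)
  write.table(ann, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(setNames(paths, c("protein", "cds", "annotation")))
}

#' Validate that a CDS translates to its protein
#'
#' Translation uses the bacterial genetic code (table 11).  The terminal
#' stop codon is excluded from the comparison; an internal stop fails with
#' the offending codon index.  Codons containing ambiguity characters
#' translate to `X`, and `X` on either side is accepted.
#'
#' @param rec A `gene_record` (one-row data frame with `protein`, `cds`).
#' @param report Return a list with details rather than just a logical.
#' @return List with `ok`, `message`, and `mismatch_at` (codon index of the
#'   first disagreement, or `NA`).
#' @export
validate_translation <- function(rec, report = TRUE) {
  cds <- rec$cds
  if (is.na(cds) || nchar(cds) < 3)
    abort_fmt("gene %s: CDS shorter than one codon", rec$gene_id)
  gc <- genetic_code_11()
  n_codon <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"          # ambiguity-containing codon
  has_stop <- aa[n_codon] == "*"
  coding <- if (has_stop) aa[-n_codon] else aa
  internal <- which(coding == "*")
  out <- function(ok, message, at = NA_integer_)
    list(ok = ok, message = message, mismatch_at = at)
  if (length(internal))
    return(out(FALSE, sprintf("internal stop codon at codon %d", internal[1]),
               internal[1]))
  pr <- strsplit(rec$protein, "")[[1]]
  if (length(coding) != length(pr))
    return(out(FALSE, sprintf("translated length %d != protein length %d",
                              length(coding), length(pr))))
  agree <- coding == pr | coding == "X" | pr == "X"
  if (all(agree)) return(out(TRUE, "translation matches"))
  at <- which(!agree)[1]
  out(FALSE, sprintf("mismatch at residue %d (%s vs %s)", at, coding[at],
                     pr[at]), at)
}

#' Read a rooted species tree from Newick
#'
#' The Newick string is interpreted as rooted at its outermost node; a
#' basal polytomy is accepted as a rooted multifurcation.  Branch lengths
#' are optional but must be non-negative when present.
#'
#' @param path Path to a Newick file, or a Newick string via `text`.
#' @param text Newick string (alternative to `path`).
#' @return An [ape::phylo] tree.
#' @export
read_tree <- function(path = NULL, text = NULL) {
  tr <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tr)) abort_fmt("unparseable Newick input")
  if (anyDuplicated(tr$tip.label))
    abort_fmt("duplicate leaf label(s): %s",
              paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                    collapse = ", "))
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    abort_fmt("negative branch length in tree")
  tr
}

#' Construct a genome registry
#'
#' @param genomes A list of `genome` objects.
#' @param reference_id Id of the reference genome (must be in `genomes`).
#' @param group_order Display order of taxon-group labels; defaults to
#'   order of first appearance.
#' @return An object of class `genome_registry`.
#' @export
genome_registry <- function(genomes, reference_id, group_order = NULL) {
  names(genomes) <- vapply(genomes, `[[`, "", "genome_id")
  if (!reference_id %in% names(genomes))
    abort_fmt("reference genome %s not in registry", reference_id)
  groups <- vapply(genomes, `[[`, "", "taxon_group")
  group_order <- group_order %||% unique(unname(groups))
  structure(list(reference_id = reference_id, genomes = genomes,
                 group_order = group_order),
            class = "genome_registry")
}

#' @export
print.genome_registry <- function(x, ...) {
  cat(sprintf("<genome_registry> %d genomes, reference %s, %d groups\n",
              length(x$genomes), x$reference_id, length(x$group_order)))
  invisible(x)
}

#' Genome ids of a registry in taxon-group display order
#' @param registry A `genome_registry`.
#' @param include_reference Keep the reference genome in the ordering.
#' @return Character vector of genome ids.
#' @export
registry_genome_order <- function(registry, include_reference = FALSE) {
  groups <- vapply(registry$genomes, `[[`, "", "taxon_group")
  ids <- names(registry$genomes)
  ids <- ids[order(match(groups, registry$group_order),
                   match(ids, names(registry$genomes)))]
  if (!include_reference) ids <- setdiff(ids, registry$reference_id)
  ids
}

#' Read a genome registry from JSON
#'
#' The JSON lists `reference_id` and an array `genomes` of records with
#' `genome_id`, `protein_fasta`, `cds_fasta`, `annotation`, `taxon_group`.
#' Relative paths are resolved against the JSON file's directory.
#'
#' @param path Path to the registry JSON.
#' @return A `genome_registry`.
#' @export
read_registry <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(path)
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  gs <- lapply(seq_len(nrow(spec$genomes)), function(i) {
    row <- spec$genomes[i, ]
    read_genome(resolve(row$protein_fasta), resolve(row$cds_fasta),
                resolve(row$annotation), genome_id = row$genome_id,
                taxon_group = row$taxon_group)
  })
  genome_registry(gs, spec$reference_id,
                  group_order = spec$group_order %||% NULL)
}
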