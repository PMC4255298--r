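#' Parameters for the genome-evolution simulator
#'
#' The simulator evolves protein families down a rooted species tree with
#' branch lengths.  Per unit branch length, a family copy is lost with
#' probability `p_loss` and duplicated with probability `p_dup` (so an
#' edge of length b applies each with probability `1 - (1 - p)^b`).  Each
#' site substitutes with probability `1 - exp(-subst_intensity * b)`,
#' replacement uniform over the 19 other residues — a deliberately simple
#' chain whose pairwise identity has a closed form, so alignment and
#' orthology stages can be checked against theory.  CDSs are produced by
#' back-translation with uniform synonymous codon choice, except that
#' leucine is encoded as TTA with probability `tta_rate`; every CDS ends
#' with TAA and internal stops are never generated.
#'
#' @param tree Rooted [ape::phylo] with branch lengths.
#' @param n_families Number of root gene families.
#' @param len_mean,len_sd Protein length distribution (normal, truncated
#'   at 30 residues).
#' @param p_loss,p_dup Per-unit-branch-length loss/duplication
#'   probabilities, in `[0, 1)`.
#' @param subst_intensity Per-site substitution intensity per unit branch
#'   length.
#' @param tta_rate Probability a leucine codon is encoded as TTA.
#' @param taxon_groups Optional named vector leaf -> group label.
#' @param seed Mandatory integer seed; all randomness flows from it.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(tree, n_families = 40L, len_mean = 120L,
                       len_sd = 25L, p_loss = 0.3, p_dup = 0,
                       subst_intensity = 1.2, tta_rate = 0.015,
                       taxon_groups = NULL, seed) {
  if (missing(seed)) abort_fmt("sim_params: seed is mandatory")
  if (is.null(tree$edge.length)) abort_fmt("tree must have branch lengths")
  stopifnot(p_loss >= 0, p_loss < 1, p_dup >= 0, p_dup < 1,
            tta_rate >= 0, tta_rate < 1, subst_intensity >= 0)
  structure(list(tree = tree, n_families = as.integer(n_families),
                 len_mean = len_mean, len_sd = len_sd, p_loss = p_loss,
                 p_dup = p_dup, subst_intensity = subst_intensity,
                 tta_rate = tta_rate, taxon_groups = taxon_groups,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Bundled demo simulation recipe
#'
#' A 12-leaf rooted tree with a reference-containing clade, two
#' progressively more distant clades and a lone outgroup — echoing the
#' grouped structure of real actinobacterial genome panels — with 40
#' families, no duplications, and substitution intensity giving well over
#' 60% mean pairwise identity.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [sim_params()].
#' @return A `sim_params`.
#' @export
demo_params <- function(seed, ...) {
  nwk <- paste0(
    "(((S_ref:0.04,(S1:0.03,S2:0.03):0.02):0.04,",
    "((K1:0.05,K2:0.05):0.03,(M1:0.05,M2:0.05):0.03):0.03):0.02,",
    "((C1:0.06,C2:0.06):0.03,(R1:0.07,R2:0.07):0.03):0.04,O1:0.12);")
  groups <- c(S_ref = "reference_clade", S1 = "reference_clade",
              S2 = "reference_clade",
              K1 = "near_clade", K2 = "near_clade", M1 = "near_clade",
              M2 = "near_clade",
              C1 = "far_clade", C2 = "far_clade", R1 = "far_clade",
              R2 = "far_clade", O1 = "outgroup")
  sim_params(read_tree(text = nwk), taxon_groups = groups, seed = seed, ...)
}

# substitute sites of an integer-coded protein along one edge
mutate_protein <- function(prot, p_sub) {
  hit <- which(runif(length(prot)) < p_sub)
  if (length(hit)) {
    r <- sample.int(19L, length(hit), replace = TRUE)
    prot[hit] <- r + (r >= prot[hit])   # uniform over the 19 others
  }
  prot
}

# back-translate an integer-coded protein; returns list(cds, has_tta)
back_translate <- function(prot, codon_table, tta_rate) {
  aa <- AA_STANDARD[prot]
  has_tta <- FALSE
  codons <- vapply(aa, function(a) {
    opts <- codon_table[[a]]
    if (a == "L") {
      if (runif(1) < tta_rate) {
        has_tta <<- TRUE
        return("TTA")
      }
      opts <- setdiff(opts, "TTA")
    }
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, "")
  list(cds = paste(c(codons, "TAA"), collapse = ""), has_tta = has_tta)
}

#' Simulate a genome collection with full evolutionary truth tables
#'
#' @param params A [sim_params()].
#' @return Object of class `synthetic_dataset`: `registry` (a
#'   [genome_registry()] with the first tip as reference), `tree`, and
#'   `truth` with elements `presence` (family x leaf 0/1 matrix),
#'   `ortholog_pairs`, `loss_events`, `duplication_events`, `tta_genes`
#'   and `realized_identity` (per family per leaf pair, primary copies).
#' @export
simulate_genomes <- function(params) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(params$seed)

  tree <- params$tree
  ntip <- ape::Ntip(tree)
  kids <- tree_children(tree)
  esig <- edge_signatures(tree)
  edge_of_child <- setNames(seq_len(nrow(tree$edge)), tree$edge[, 2])
  codon_table <- codons_for_aa()
  fam_ids <- sprintf("f%02d", seq_len(params$n_families))

  losses <- list(); dups <- list()
  # leaf_copies[[leaf]][[family]] = list of list(copy, prot)
  leaf_copies <- rep(list(setNames(vector("list", params$n_families),
                                   fam_ids)), ntip)

  for (fi in seq_len(params$n_families)) {
    L <- max(30L, as.integer(round(rnorm(1, params$len_mean,
                                         params$len_sd))))
    root_prot <- sample.int(20L, L, replace = TRUE)
    next_copy <- 2L
    descend <- function(node, copies) {
      if (node <= ntip) {
        leaf_copies[[node]][[fam_ids[fi]]] <<- copies
        return(invisible())
      }
      for (child in kids[[node]]) {
        b <- tree$edge.length[edge_of_child[[as.character(child)]]]
        p_loss_e <- 1 - (1 - params$p_loss)^b
        p_dup_e <- 1 - (1 - params$p_dup)^b
        p_sub_e <- 1 - exp(-params$subst_intensity * b)
        out <- list()
        for (cp in copies) {
          if (runif(1) < p_loss_e) {
            losses[[length(losses) + 1L]] <<- data.frame(
              family = fam_ids[fi], copy = cp$copy,
              edge = esig[edge_of_child[[as.character(child)]]],
              stringsAsFactors = FALSE)
            next
          }
          if (runif(1) < p_dup_e) {
            newcp <- list(copy = sprintf("c%d", next_copy),
                          prot = mutate_protein(cp$prot, p_sub_e))
            next_copy <<- next_copy + 1L
            dups[[length(dups) + 1L]] <<- data.frame(
              family = fam_ids[fi], parent_copy = cp$copy,
              new_copy = newcp$copy,
              edge = esig[edge_of_child[[as.character(child)]]],
              stringsAsFactors = FALSE)
            out[[length(out) + 1L]] <-
              list(copy = cp$copy, prot = mutate_protein(cp$prot, p_sub_e))
            out[[length(out) + 1L]] <- newcp
          } else {
            out[[length(out) + 1L]] <-
              list(copy = cp$copy, prot = mutate_protein(cp$prot, p_sub_e))
          }
        }
        if (length(out)) descend(child, out)   # empty: subtree loses family
      }
      invisible()
    }
    descend(ntip + 1L, list(list(copy = "c1", prot = root_prot)))
  }

  # assemble leaf genomes: root family order, duplicates adjacent
  genomes <- list()
  tta_rows <- list()
  presence <- matrix(0L, params$n_families, ntip,
                     dimnames = list(fam_ids, tree$tip.label))
  prot_store <- list()  # [[family]][[leaf]] = primary integer protein
  for (li in seq_len(ntip)) {
    leaf <- tree$tip.label[li]
    recs <- list()
    for (fi in seq_len(params$n_families)) {
      copies <- leaf_copies[[li]][[fam_ids[fi]]]
      if (!length(copies)) next
      presence[fi, li] <- 1L
      ord <- order(vapply(copies, function(cp)
        as.integer(sub("^c", "", cp$copy)), 1L))
      for (cp in copies[ord]) {
        gid <- if (cp$copy == "c1") sprintf("%s_%s", leaf, fam_ids[fi])
        else sprintf("%s_%s_d%s", leaf, fam_ids[fi],
                     sub("^c", "", cp$copy))
        bt <- back_translate(cp$prot, codon_table, params$tta_rate)
        recs[[length(recs) + 1L]] <- gene_record(
          gid, paste(AA_STANDARD[cp$prot], collapse = ""), bt$cds,
          "chr", length(recs), "+")
        if (bt$has_tta)
          tta_rows[[length(tta_rows) + 1L]] <- data.frame(
            genome_id = leaf, gene_id = gid, stringsAsFactors = FALSE)
        if (cp$copy == "c1")
          prot_store[[fam_ids[fi]]][[leaf]] <- cp$prot
      }
    }
    grp <- if (!is.null(params$taxon_groups))
      params$taxon_groups[[leaf]] else "simulated"
    genomes[[leaf]] <- genome(leaf, do.call(rbind, recs), grp)
  }

  # truth tables derived from bookkeeping, independent of any alignment
  pair_rows <- list(); ident_rows <- list()
  for (fi in fam_ids) {
    leaves <- names(prot_store[[fi]])
    if (length(leaves) < 2) next
    for (i in seq_len(length(leaves) - 1)) for (j in (i + 1):length(leaves)) {
      a <- leaves[i]; b <- leaves[j]
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        family = fi, genome_a = a, gene_a = sprintf("%s_%s", a, fi),
        genome_b = b, gene_b = sprintf("%s_%s", b, fi),
        stringsAsFactors = FALSE)
      ident_rows[[length(ident_rows) + 1L]] <- data.frame(
        family = fi, genome_a = a, genome_b = b,
        identity = mean(prot_store[[fi]][[a]] == prot_store[[fi]][[b]]),
        stringsAsFactors = FALSE)
    }
  }
  bind <- function(x, proto) do.call(rbind, x) %||% proto
  truth <- list(
    presence = presence,
    ortholog_pairs = bind(pair_rows, data.frame(
      family = character(), genome_a = character(), gene_a = character(),
      genome_b = character(), gene_b = character())),
    loss_events = bind(losses, data.frame(
      family = character(), copy = character(), edge = character())),
    duplication_events = bind(dups, data.frame(
      family = character(), parent_copy = character(),
      new_copy = character(), edge = character())),
    tta_genes = bind(tta_rows, data.frame(
      genome_id = character(), gene_id = character())),
    realized_identity = bind(ident_rows, data.frame(
      family = character(), genome_a = character(),
      genome_b = character(), identity = numeric())))

  structure(list(
    registry = genome_registry(genomes, reference_id = tree$tip.label[1],
                               group_order = unique(unname(
                                 vapply(genomes, `[[`, "", "taxon_group")))),
    tree = tree, truth = truth, params = params),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d genomes, %d families, %d loss / %d duplication event(s)\n",
    length(x$registry$genomes), x$params$n_families,
    nrow(x$truth$loss_events), nrow(x$truth$duplication_events)))
  invisible(x)
}

#' Presence vector of a family from simulation bookkeeping
#'
#' @param dataset A `synthetic_dataset`.
#' @param family_id Family id (e.g. `"f01"`).
#' @return Named 0/1 vector over leaves, by simulator truth (independent
#'   of any alignment).
#' @export
truth_presence_vector <- function(dataset, family_id) {
  if (!family_id %in% rownames(dataset$truth$presence))
    abort_fmt("unknown family: %s", family_id)
  dataset$truth$presence[family_id, ]
}

#' Write a synthetic dataset to disk in the pipeline input formats
#'
#' Emits per-genome protein FASTA, CDS FASTA and annotation TSV, a
#' registry JSON, the species tree as Newick, and the truth tables as
#' JSON.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory.
#' @return Invisibly, the registry JSON path.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(names(dataset$registry$genomes), function(gid) {
    g <- dataset$registry$genomes[[gid]]
    write_genome(g, dir)
    data.frame(genome_id = gid, protein_fasta = paste0(gid, ".faa"),
               cds_fasta = paste0(gid, ".fna"),
               annotation = paste0(gid, ".tsv"),
               taxon_group = g$taxon_group, stringsAsFactors = FALSE)
  })
  reg_path <- file.path(dir, "registry.json")
  jsonlite::write_json(list(reference_id = dataset$registry$reference_id,
                            group_order = dataset$registry$group_order,
                            genomes = do.call(rbind, rows)),
                       reg_path, auto_unbox = TRUE, pretty = TRUE)
  ape::write.tree(dataset$tree, file.path(dir, "species_tree.nwk"))
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(reg_path)
}
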