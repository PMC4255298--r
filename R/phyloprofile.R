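# tree helpers ---------------------------------------------------------------

# children of every node, from the edge table
tree_children <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  kids <- vector("list", n_node)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1]]] <- c(kids[[tree$edge[i, 1]]], tree$edge[i, 2])
  kids
}

# leaf labels below each node (tips included), as a list indexed by node id
node_leafsets <- function(tree) {
  ntip <- ape::Ntip(tree)
  kids <- tree_children(tree)
  sets <- vector("list", ntip + tree$Nnode)
  walk <- function(v) {
    if (v <= ntip) {
      sets[[v]] <<- tree$tip.label[v]
    } else {
      for (k in kids[[v]]) walk(k)
      sets[[v]] <<- unlist(lapply(kids[[v]], function(k) sets[[k]]))
    }
  }
  walk(ntip + 1L)
  sets
}

#' Canonical signature of a tree edge
#'
#' An edge is identified by the sorted set of leaf labels below it, which
#' is stable across tree representations; used to compare reconstructed
#' loss edges with simulated ones.
#'
#' @param tree An [ape::phylo].
#' @return Character vector, one signature per row of `tree$edge`.
#' @export
edge_signatures <- function(tree) {
  sets <- node_leafsets(tree)
  vapply(tree$edge[, 2], function(child)
    paste(sort(sets[[child]]), collapse = ","), "")
}

check_presence_vector <- function(tree, presence) {
  if (is.logical(presence)) presence <- as.integer(presence)
  if (is.null(names(presence)))
    abort_fmt("presence vector must be named by leaf label")
  missing <- setdiff(tree$tip.label, names(presence))
  if (length(missing))
    abort_fmt("presence vector lacks leaf/leaves: %s",
              paste(missing, collapse = ", "))
  extra <- setdiff(names(presence), tree$tip.label)
  if (length(extra))
    abort_fmt("presence vector names not in tree: %s",
              paste(extra, collapse = ", "))
  presence[tree$tip.label]
}

# Dollo / Fitch ---------------------------------------------------------------

#' Dollo parsimony gain/loss reconstruction of a presence vector
#'
#' Under Dollo parsimony a gene is gained exactly once and may be lost any
#' number of times — the standard formalisation of "present in the common
#' ancestor, lost independently in several lines".  The gain is placed on
#' the edge above the MRCA of the present leaves (the stem edge of the
#' root when all leaves are present); losses are the stem edges of the
#' maximal all-absent subtrees inside the gain clade, which is the minimal
#' loss set for that gain placement.
#'
#' @param tree A rooted [ape::phylo]; leaf labels are genome ids.
#' @param presence Named 0/1 (or logical) vector over all leaves.
#' @return List of class `gain_loss` with `gain_edge` (leaf-set
#'   signature), `gain_node`, `loss_edges` (signatures), `n_losses`, and
#'   `internal_states` (named `present`/`absent` per node id).
#' @export
dollo_gain_loss <- function(tree, presence) {
  presence <- check_presence_vector(tree, presence)
  present_leaves <- names(presence)[presence == 1]
  if (!length(present_leaves))
    abort_fmt("all-absent presence vector: nothing to reconstruct")
  ntip <- ape::Ntip(tree)
  sets <- node_leafsets(tree)
  kids <- tree_children(tree)
  gain_node <- if (length(present_leaves) == 1L)
    match(present_leaves, tree$tip.label)
  else ape::getMRCA(tree, present_leaves)

  n_node <- ntip + tree$Nnode
  state <- rep(NA_character_, n_node)
  # inside the gain clade a node is present iff its subtree retains the gene
  mark <- function(v) {
    has <- if (v <= ntip) presence[[tree$tip.label[v]]] == 1L
    else any(vapply(kids[[v]], function(k) mark(k), logical(1)))
    state[v] <<- if (has) "present" else "absent"
    has
  }
  mark(gain_node)
  state[is.na(state)] <- "absent"   # outside the gain clade

  losses <- character(0)
  in_clade <- function(v) v == gain_node ||
    all(sets[[v]] %in% sets[[gain_node]])
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; c <- tree$edge[i, 2]
    if (state[p] == "present" && state[c] == "absent" && in_clade(p))
      losses <- c(losses, paste(sort(sets[[c]]), collapse = ","))
  }
  structure(list(
    gain_node = gain_node,
    gain_edge = paste(sort(sets[[gain_node]]), collapse = ","),
    loss_edges = sort(losses),
    n_losses = length(losses),
    internal_states = setNames(state, seq_len(n_node))),
    class = "gain_loss")
}

#' @export
print.gain_loss <- function(x, ...) {
  cat(sprintf("<gain_loss> gain above {%s}; %d loss edge(s)\n",
              x$gain_edge, x$n_losses))
  invisible(x)
}

#' Minimum number of unrestricted presence/absence changes (Fitch)
#'
#' Small-parsimony count of binary state changes with gains and losses
#' both allowed, computed bottom-up (Hartigan's generalisation, so
#' multifurcating nodes are handled exactly).
#'
#' @inheritParams dollo_gain_loss
#' @return Integer change count.
#' @export
fitch_changes <- function(tree, presence) {
  presence <- check_presence_vector(tree, presence)
  if (!any(presence == 1))
    abort_fmt("all-absent presence vector: nothing to reconstruct")
  ntip <- ape::Ntip(tree)
  kids <- tree_children(tree)
  cost <- 0L
  # returns the set of optimal states at v as logical c(absent, present)
  solve <- function(v) {
    if (v <= ntip) {
      s <- presence[[tree$tip.label[v]]] == 1L
      return(c(!s, s))
    }
    votes <- c(0L, 0L)
    for (k in kids[[v]]) {
      sk <- solve(k)
      votes <- votes + sk
    }
    m <- max(votes)
    cost <<- cost + (length(kids[[v]]) - m)
    votes == m
  }
  solve(ntip + 1L)
  cost
}

# congruence ------------------------------------------------------------------

#' Congruence of two presence vectors
#'
#' Jaccard similarity of the presence sets and the fraction of agreeing
#' positions.  Two all-absent vectors have Jaccard 1 by convention (their
#' presence sets are identical).
#'
#' @param u,v Named 0/1 vectors over the same genome universe.
#' @return List with `jaccard` and `matching`.
#' @export
congruence <- function(u, v) {
  if (!setequal(names(u), names(v)) || is.null(names(u)))
    abort_fmt("congruence: vectors must be named over the same universe")
  v <- v[names(u)]
  u <- as.integer(u); v2 <- as.integer(v)
  inter <- sum(u == 1 & v2 == 1)
  union <- sum(u == 1 | v2 == 1)
  list(jaccard = if (union == 0) 1 else inter / union,
       matching = mean(u == v2))
}

# divergence profiling --------------------------------------------------------

# protein sequence of a reference gene's counterpart in a genome
ortholog_protein <- function(matrix, registry, gene_id, genome_id,
                             allow_sub_threshold = FALSE) {
  if (genome_id == registry$reference_id)
    return(registry$genomes[[genome_id]]$genes[gene_id, "protein"])
  cell <- profile_cell(matrix, gene_id, genome_id)
  ok <- c("orthologue", if (allow_sub_threshold) "sub_threshold")
  if (!nrow(cell) || !(cell$status %in% ok))
    abort_fmt("no orthologue of %s in %s", gene_id, genome_id)
  registry$genomes[[genome_id]]$genes[cell$target_gene_id, "protein"]
}

#' Identity of concatenated universal-protein controls between two genomes
#'
#' Concatenates the orthologues of the control genes in the stated, fixed
#' order in each genome and reports the percent identity of the local
#' alignment of the two concatenations.  The control set is meant to be a
#' panel of slowly evolving universal proteins (e.g. AtpD, DnaA, DnaG,
#' DnaK, GyrB, RecA, RpoB) that calibrates the expected divergence of a
#' genome pair.
#'
#' @param matrix A `profile_matrix`.
#' @param registry The registry.
#' @param genome_a,genome_b Genome ids (either may be the reference).
#' @param control_genes Ordered reference gene ids; order is normative.
#' @param scheme A [scoring_scheme()].
#' @return Percent identity (numeric scalar).
#' @export
concat_control_identity <- function(matrix, registry, genome_a, genome_b,
                                    control_genes,
                                    scheme = scoring_scheme()) {
  concat <- function(gid) paste(vapply(
    control_genes, function(g) ortholog_protein(matrix, registry, g, gid),
    ""), collapse = "")
  al <- local_align(concat(genome_a), concat(genome_b), scheme)
  if (is.null(al)) abort_fmt("control concatenations do not align")
  al$identity_pct
}

#' Divergence profile of a protein against the universal-protein control
#'
#' For every genome pair, the percent identity of the protein's
#' orthologues is divided by the identity of the concatenated control for
#' the same pair.  Ratios well below 1 flag proteins diverging much faster
#' than housekeeping proteins — the signature of candidate speciation
#' agents.
#'
#' @param matrix,registry,scheme As in [concat_control_identity()].
#' @param gene_id Reference gene to profile (must have orthologues in all
#'   listed genomes).
#' @param genome_ids Genomes to compare pairwise (may include the
#'   reference).
#' @param control_genes Ordered control gene ids.
#' @return Object of class `divergence_profile`: matrices `identity`,
#'   `control_identity`, `ratio` over the genome pairs.
#' @export
divergence_profile <- function(matrix, registry, gene_id, genome_ids,
                               control_genes, scheme = scoring_scheme()) {
  n <- length(genome_ids)
  prot <- vapply(genome_ids, function(g)
    ortholog_protein(matrix, registry, gene_id, g), "")
  idm <- ctrl <- matrix(NA_real_, n, n,
                        dimnames = list(genome_ids, genome_ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    al <- local_align(prot[i], prot[j], scheme)
    idm[i, j] <- idm[j, i] <- if (is.null(al)) 0 else al$identity_pct
    ctrl[i, j] <- ctrl[j, i] <- concat_control_identity(
      matrix, registry, genome_ids[i], genome_ids[j], control_genes, scheme)
  }
  diag(idm) <- diag(ctrl) <- 100
  structure(list(gene_id = gene_id, identity = idm,
                 control_identity = ctrl, ratio = idm / ctrl),
            class = "divergence_profile")
}

# paralogue families ----------------------------------------------------------

#' One-way paralogue-family search with a probe protein
#'
#' Collects every gene (not just best hits) in every registry genome whose
#' local alignment to the probe reaches the family thresholds; reciprocity
#' is deliberately not required, matching a one-way probe search through
#' whole proteomes.  The probe's own genome is included.
#'
#' @param probe A `gene_record` (e.g. one row of a genome's `genes`).
#' @param registry A `genome_registry`.
#' @param scheme A [scoring_scheme()].
#' @param min_identity_pct Family identity threshold (default 30).
#' @param min_coverage_of_probe Minimum alignment overlap as a fraction of
#'   probe length (default 0.6).
#' @return Object of class `paralog_family` with `probe_gene_id` and a
#'   `members` data frame (genome_id, gene_id, score, identity_pct,
#'   overlap, coverage_probe, protein).
#' @export
paralog_family <- function(probe, registry, scheme = scoring_scheme(),
                           min_identity_pct = 30,
                           min_coverage_of_probe = 0.6) {
  rows <- list()
  for (gid in names(registry$genomes)) {
    g <- registry$genomes[[gid]]
    for (i in seq_len(nrow(g$genes))) {
      al <- local_align(probe$protein, g$genes$protein[i], scheme)
      if (is.null(al)) next
      covp <- al$overlap / nchar(probe$protein)
      if (al$identity_pct >= min_identity_pct &&
          covp >= min_coverage_of_probe)
        rows[[length(rows) + 1L]] <- data.frame(
          genome_id = gid, gene_id = g$genes$gene_id[i],
          score = al$score, identity_pct = al$identity_pct,
          overlap = al$overlap, coverage_probe = covp,
          protein = g$genes$protein[i], stringsAsFactors = FALSE)
    }
  }
  members <- do.call(rbind, rows) %||%
    data.frame(genome_id = character(), gene_id = character(),
               score = integer(), identity_pct = numeric(),
               overlap = integer(), coverage_probe = numeric(),
               protein = character())
  structure(list(probe_gene_id = probe$gene_id, members = members),
            class = "paralog_family")
}

#' @export
print.paralog_family <- function(x, ...) {
  cat(sprintf("<paralog_family> probe %s: %d member(s) in %d genome(s)\n",
              x$probe_gene_id, nrow(x$members),
              length(unique(x$members$genome_id))))
  invisible(x)
}

# neighbour joining -----------------------------------------------------------

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou--Nei neighbour joining via [ape::nj()]; negative branch lengths
#' (which NJ can produce on non-additive matrices) are clamped to zero
#' with a message.
#'
#' @param d A symmetric distance matrix or [stats::dist].
#' @return Unrooted [ape::phylo] with branch lengths.
#' @export
nj_from_distances <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) abort_fmt("neighbour joining needs >= 3 taxa")
  if (anyNA(d)) abort_fmt("undefined distance in matrix")
  tr <- ape::nj(as.dist(d))
  neg <- tr$edge.length < 0
  if (any(neg)) {
    message(sprintf("nj_from_distances: clamped %d negative branch length(s) to 0",
                    sum(neg)))
    tr$edge.length[neg] <- 0
  }
  tr
}

#' Neighbour-joining tree of a paralogue family
#'
#' Pairwise p-distances (1 - identity fraction of the all-vs-all local
#' alignments) feed Saitou--Nei neighbour joining.  A Poisson correction
#' `-log(1 - p)` is available for saturated families.
#'
#' @param family A [paralog_family()] with >= 3 members.
#' @param scheme A [scoring_scheme()].
#' @param correction `"p"` (default) or `"poisson"`.
#' @return Unrooted [ape::phylo]; tips are `genome_id:gene_id`.
#' @export
nj_tree <- function(family, scheme = scoring_scheme(), correction = "p") {
  m <- family$members
  if (nrow(m) < 3)
    abort_fmt("nj_tree: need >= 3 family members, got %d", nrow(m))
  labs <- paste(m$genome_id, m$gene_id, sep = ":")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    al <- local_align(m$protein[i], m$protein[j], scheme)
    if (is.null(al))
      abort_fmt("no alignment between %s and %s: distance undefined",
                labs[i], labs[j])
    p <- 1 - al$matches / al$overlap
    if (correction == "poisson") {
      if (p >= 1) abort_fmt("saturated distance between %s and %s",
                            labs[i], labs[j])
      p <- -log(1 - p)
    }
    d[i, j] <- d[j, i] <- p
  }
  nj_from_distances(d)
}
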