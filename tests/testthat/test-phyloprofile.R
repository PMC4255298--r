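test_that("Dollo reconstruction handles the canonical four-leaf cases", {
  tr <- read_tree(text = "((A,B),(C,D));")
  all_present <- dollo_gain_loss(tr, c(A = 1, B = 1, C = 1, D = 1))
  expect_equal(all_present$n_losses, 0L)
  expect_equal(all_present$gain_edge, "A,B,C,D")   # root stem

  ac <- dollo_gain_loss(tr, c(A = 1, B = 0, C = 1, D = 0))
  expect_equal(ac$gain_edge, "A,B,C,D")
  expect_equal(sort(ac$loss_edges), c("B", "D"))
  expect_equal(ac$n_losses, 2L)

  ab <- dollo_gain_loss(tr, c(A = 1, B = 1, C = 0, D = 0))
  expect_equal(ab$gain_edge, "A,B")
  expect_equal(ab$n_losses, 0L)

  expect_error(dollo_gain_loss(tr, c(A = 0, B = 0, C = 0, D = 0)),
               "all-absent")
})

test_that("Dollo loss counts equal the exhaustive single-gain oracle", {
  set.seed(51)
  for (rep in 1:12) {
    n <- sample(4:7, 1)
    tr <- ape::rtree(n)
    for (code in sample(1:(2^n - 1), min(25, 2^n - 1))) {
      v <- setNames(as.integer(intToBits(code)[1:n]), tr$tip.label)
      d <- dollo_gain_loss(tr, v)
      expect_equal(d$n_losses, oracle_min_losses(tr, v))
      # removing the loss subtrees from the gain clade leaves the present set
      gain_leaves <- strsplit(d$gain_edge, ",")[[1]]
      lost_leaves <- unlist(strsplit(d$loss_edges, ","))
      expect_setequal(setdiff(gain_leaves, lost_leaves),
                      names(v)[v == 1])
    }
  }
})

test_that("Fitch change counts match phangorn's parsimony", {
  tr <- read_tree(text = "((A,B),(C,D));")
  expect_equal(fitch_changes(tr, c(A = 1, B = 1, C = 1, D = 1)), 0L)
  expect_equal(fitch_changes(tr, c(A = 1, B = 0, C = 1, D = 0)), 2L)
  expect_equal(fitch_changes(tr, c(A = 0, B = 0, C = 1, D = 0)), 1L)
  skip_if_not_installed("phangorn")
  set.seed(52)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    v <- setNames(sample(0:1, n, replace = TRUE), tr$tip.label)
    if (!any(v == 1)) v[1] <- 1L
    dat <- phangorn::phyDat(matrix(as.character(v), ncol = 1,
                                   dimnames = list(names(v), NULL)),
                            type = "USER", levels = c("0", "1"))
    expect_equal(fitch_changes(tr, v),
                 as.integer(phangorn::parsimony(tr, dat)))
  }
})

test_that("Fitch never needs more than one change beyond Dollo", {
  set.seed(53)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    v <- setNames(sample(0:1, n, replace = TRUE), tr$tip.label)
    if (!any(v == 1)) v[1] <- 1L
    expect_lte(fitch_changes(tr, v),
               1L + dollo_gain_loss(tr, v)$n_losses)
  }
})

test_that("congruence follows set arithmetic and its invariants", {
  u <- c(a = 1, b = 1, c = 0, d = 0)
  v <- c(a = 1, b = 0, c = 1, d = 0)
  expect_equal(congruence(u, v)$jaccard, 1 / 3)
  expect_equal(congruence(u, u), list(jaccard = 1, matching = 1))
  disj <- congruence(c(a = 1, b = 0, c = 0), c(a = 0, b = 1, c = 0))
  expect_equal(disj$jaccard, 0)
  expect_equal(disj$matching, 1 / 3)     # only the shared zero agrees
  none <- congruence(c(a = 0, b = 0), c(a = 0, b = 0))
  expect_equal(none$jaccard, 1)          # both-empty convention
  expect_equal(congruence(u, v)$jaccard, congruence(v, u)$jaccard)
  expect_error(congruence(u, c(x = 1, y = 0, z = 1, w = 0)), "universe")
})

test_that("control concatenation identity is 100 for identical genomes", {
  set.seed(54)
  p <- setNames(vapply(1:6, function(i) random_protein(50), ""),
                paste0("r", 1:6))
  ref <- make_genome("REF", p)
  copy <- make_genome("COPY", setNames(p, paste0("c", 1:6)),
                      taxon_group = "t2")
  reg <- genome_registry(list(ref, copy), "REF")
  pm <- build_profile(reg, scan_tta_flags = FALSE)
  expect_equal(concat_control_identity(pm, reg, "REF", "COPY",
                                       c("r1", "r2", "r3")), 100)
  expect_error(concat_control_identity(pm, reg, "REF", "COPY",
                                       c("r1", "zz")), "zz")
})

test_that("control identity tracks the simulator's realized divergence", {
  ds <- tiny_dataset(seed = 55, n_families = 10)
  pm <- build_profile(ds$registry)
  controls <- paste0(ds$registry$reference_id, "_",
                     sprintf("f%02d", 1:5))
  controls <- controls[controls %in% pm$genes]
  # keep controls with orthologue everywhere
  keep <- vapply(controls, function(g)
    all(presence_vector(pm, g) == 1), logical(1))
  controls <- controls[keep]
  skip_if(length(controls) < 3)
  got <- concat_control_identity(pm, ds$registry,
                                 ds$registry$reference_id, "E", controls)
  fams <- sub("^.*_f", "f", controls)
  ri <- ds$truth$realized_identity
  want <- 100 * mean(ri$identity[ri$family %in% fams &
                                   ((ri$genome_a == "A" & ri$genome_b == "E") |
                                      (ri$genome_a == "E" & ri$genome_b == "A"))])
  expect_lt(abs(got - want), 2)
})

test_that("divergence ratios sit near one for rate-homogeneous proteins", {
  ds <- tiny_dataset(seed = 56, n_families = 8, p_loss = 0)
  pm <- build_profile(ds$registry)
  ref <- ds$registry$reference_id
  controls <- paste0(ref, "_", sprintf("f%02d", 1:3))
  genomes <- c(ref, "C", "D", "E")
  dp <- divergence_profile(pm, ds$registry, paste0(ref, "_f04"),
                           genomes, controls)
  off <- dp$ratio[upper.tri(dp$ratio)]
  expect_true(all(off > 0.8 & off < 1.25))
  expect_gt(mean(off), 0.9)
  expect_lt(mean(off), 1.1)
  # self-consistency: a control gene against the control panel
  dpc <- divergence_profile(pm, ds$registry, controls[1], genomes, controls)
  offc <- dpc$ratio[upper.tri(dpc$ratio)]
  expect_true(all(offc > 0.8 & offc < 1.25))
})

test_that("a family evolved at 3x the control rate has mean ratio below one", {
  slow <- tiny_dataset(seed = 57, n_families = 6, p_loss = 0)
  fast <- tiny_dataset(seed = 570, n_families = 1, p_loss = 0,
                       subst_intensity = 3.6)
  # splice the fast-evolving family into the rate-homogeneous genomes as an
  # extra gene ("fx") per genome
  genomes <- lapply(names(slow$registry$genomes), function(gid) {
    g <- slow$registry$genomes[[gid]]
    fastg <- fast$registry$genomes[[gid]]$genes
    fastg$gene_id <- paste0(gid, "_fx")
    rownames(fastg) <- fastg$gene_id
    merged <- rbind(g$genes, fastg)
    merged$ordinal <- seq_len(nrow(merged)) - 1L
    genome(gid, merged, g$taxon_group)
  })
  reg <- genome_registry(genomes, slow$registry$reference_id)
  pm <- build_profile(reg)
  ref <- reg$reference_id
  controls <- paste0(ref, "_", sprintf("f%02d", 1:4))
  dp <- divergence_profile(pm, reg, paste0(ref, "_fx"),
                           c(ref, "C", "D", "E"), controls)
  off <- dp$ratio[upper.tri(dp$ratio)]
  expect_lt(mean(off), 1)
})

test_that("one-way probe searches recover whole paralogue families", {
  ds <- tiny_dataset(seed = 58, n_families = 6, p_dup = 0.9,
                     p_loss = 0)
  reg <- ds$registry
  ref <- reg$genomes[[reg$reference_id]]
  probe <- ref$genes[paste0(reg$reference_id, "_f01"), ]
  fam <- paralog_family(probe, reg)
  expect_true(probe$gene_id %in% fam$members$gene_id)
  expect_equal(
    fam$members$identity_pct[fam$members$gene_id == probe$gene_id], 100)
  # simulator truth: every emitted copy of family f01 should be recovered
  # at these identity levels (>= 60% pairwise, threshold 30%)
  truth_members <- unlist(lapply(reg$genomes, function(g)
    grep("_f01($|_d)", g$genes$gene_id, value = TRUE)), use.names = FALSE)
  expect_setequal(fam$members$gene_id, truth_members)
  # unrelated families contribute no members
  other <- fam$members$gene_id[!grepl("_f01($|_d)", fam$members$gene_id)]
  expect_length(other, 0)
})

test_that("neighbour joining reproduces closed forms and additive trees", {
  d3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- nj_from_distances(d3)
  bl <- setNames(tr3$edge.length, tr3$tip.label[tr3$edge[, 2]])
  expect_equal(bl[["A"]], 0.5)   # (dAB + dAC - dBC) / 2
  expect_equal(bl[["B"]], 1.5)
  expect_equal(bl[["C"]], 2.5)

  d4 <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d4["A", "B"] <- d4["B", "A"] <- 3
  d4["C", "D"] <- d4["D", "C"] <- 7
  d4["A", "C"] <- d4["C", "A"] <- 5
  d4["A", "D"] <- d4["D", "A"] <- 6
  d4["B", "C"] <- d4["C", "B"] <- 6
  d4["B", "D"] <- d4["D", "B"] <- 7
  tr4 <- nj_from_distances(d4)
  # split AB|CD with internal edge 1, and the matrix is reproduced exactly
  expect_equal(unname(as.matrix(stats::cophenetic(tr4))[rownames(d4),
                                                        colnames(d4)]),
               unname(d4), tolerance = 1e-12)
  internal <- tr4$edge[, 2] > ape::Ntip(tr4)
  expect_equal(tr4$edge.length[internal], 1)
})

test_that("all-identical family members give a zero-length star tree", {
  members <- data.frame(genome_id = c("A", "B", "C"),
                        gene_id = c("g1", "g2", "g3"),
                        score = 1L, identity_pct = 100, overlap = 10L,
                        coverage_probe = 1,
                        protein = rep("MKVLWREHAG", 3))
  fam <- structure(list(probe_gene_id = "g1", members = members),
                   class = "paralog_family")
  tr <- nj_tree(fam)
  expect_true(all(tr$edge.length == 0))
  expect_error(nj_tree(structure(list(probe_gene_id = "g",
                                      members = members[1:2, ]),
                                 class = "paralog_family")),
               ">= 3")
})
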