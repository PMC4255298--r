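ref_proteins <- function(seed = 21, n = 8, len = 60) {
  set.seed(seed)
  setNames(vapply(seq_len(n), function(i) random_protein(len), ""),
           sprintf("r%02d", seq_len(n)))
}

test_that("a renamed byte-copy genome yields all-orthologue calls", {
  p <- ref_proteins()
  ref <- make_genome("REF", p)
  tgt <- make_genome("TGT", setNames(p, sub("^r", "t", names(p))))
  calls <- reciprocal_best_hits(ref, tgt)
  expect_true(all(calls$status == "orthologue"))
  expect_true(all(calls$identity_pct == 100))
  expect_equal(calls$target_gene_id, sub("^r", "t", names(p)))
})

test_that("deleting a gene from the target gives an absent call", {
  p <- ref_proteins()
  ref <- make_genome("REF", p)
  tgt <- make_genome("TGT", setNames(p[-3], paste0("t", seq_len(7))))
  calls <- reciprocal_best_hits(ref, tgt)
  expect_equal(calls$status[calls$ref_gene_id == "r03"], "absent")
  expect_equal(sum(calls$status == "orthologue"), 7)
})

test_that("an out-paralogue pulling the forward hit breaks reciprocity", {
  set.seed(22)
  base <- random_protein(80)
  # the target carries a closer partner for tgtA, so refA's forward hit
  # (tgtB, closest to refA) answers back to refB-like decoy
  refA <- base
  decoy <- paste0(substr(base, 1, 70), random_protein(10))
  ref <- make_genome("REF", c(a = refA, d = decoy))
  # tgt gene closest to decoy, nothing close to refA alone
  tgt <- make_genome("TGT", c(x = decoy))
  calls <- reciprocal_best_hits(ref, tgt, prefilter = FALSE)
  expect_equal(calls$status[calls$ref_gene_id == "a"], "absent")
  expect_equal(calls$status[calls$ref_gene_id == "d"], "orthologue")
})

test_that("RBH calls match an exhaustive all-vs-all oracle on a simulation", {
  ds <- tiny_dataset(seed = 23, n_families = 10)
  reg <- ds$registry
  ref <- reg$genomes[[reg$reference_id]]
  tgt <- reg$genomes[["D"]]
  calls <- reciprocal_best_hits(ref, tgt)
  # oracle: all-vs-all score matrix, reciprocal argmax
  scheme <- scoring_scheme()
  smat <- matrix(0, nrow(ref$genes), nrow(tgt$genes),
                 dimnames = list(ref$genes$gene_id, tgt$genes$gene_id))
  for (i in seq_len(nrow(ref$genes)))
    for (j in seq_len(nrow(tgt$genes))) {
      al <- local_align(ref$genes$protein[i], tgt$genes$protein[j], scheme)
      smat[i, j] <- if (is.null(al)) 0 else al$score
    }
  for (g in ref$genes$gene_id) {
    fwd <- colnames(smat)[which.max(smat[g, ])]
    recip <- rownames(smat)[which.max(smat[, fwd])] == g
    got <- calls[calls$ref_gene_id == g, ]
    if (recip) expect_equal(got$target_gene_id, fwd)
    else expect_equal(got$status, "absent")
  }
})

test_that("orthologue pairs are symmetric under role swap", {
  ds <- tiny_dataset(seed = 24, n_families = 8)
  reg <- ds$registry
  a <- reg$genomes[["A"]]; e <- reg$genomes[["E"]]
  ab <- reciprocal_best_hits(a, e)
  ba <- reciprocal_best_hits(e, a)
  pairs_ab <- with(ab[ab$status == "orthologue", ],
                   sort(paste(ref_gene_id, target_gene_id)))
  pairs_ba <- with(ba[ba$status == "orthologue", ],
                   sort(paste(target_gene_id, ref_gene_id)))
  expect_equal(pairs_ab, pairs_ba)
})

test_that("raising the identity threshold only shrinks the orthologue set", {
  ds <- tiny_dataset(seed = 25, n_families = 10)
  reg <- ds$registry
  ref <- reg$genomes[[reg$reference_id]]
  tgt <- reg$genomes[["E"]]
  lo <- reciprocal_best_hits(ref, tgt,
                             thresholds = orthology_thresholds(40, 0.6))
  hi <- reciprocal_best_hits(ref, tgt,
                             thresholds = orthology_thresholds(80, 0.6))
  set_lo <- lo$ref_gene_id[lo$status == "orthologue"]
  set_hi <- hi$ref_gene_id[hi$status == "orthologue"]
  expect_true(all(set_hi %in% set_lo))
  # no call may jump from sub_threshold/absent to orthologue
  expect_false(any(hi$status == "orthologue" & lo$status != "orthologue"))
})

test_that("build_profile yields a complete matrix in registry order", {
  ds <- tiny_dataset(seed = 26, n_families = 5)
  pm <- build_profile(ds$registry)
  expect_equal(nrow(pm$calls), length(pm$genes) * length(pm$genomes))
  expect_setequal(pm$genomes,
                  setdiff(names(ds$registry$genomes),
                          ds$registry$reference_id))
  expect_error(build_profile(ds$registry, gene_subset = "nope"),
               "unknown gene")
})

test_that("a reference-only gene profiles as an all-absent row", {
  p <- ref_proteins(seed = 27, n = 4)
  ref <- make_genome("REF", c(p, only = random_protein(60)))
  tgt <- make_genome("TGT", setNames(p, paste0("t", 1:4)), taxon_group = "t2")
  reg <- genome_registry(list(ref, tgt), "REF")
  pm <- build_profile(reg, scan_tta_flags = FALSE)
  expect_true(all(pm$calls$status[pm$calls$ref_gene_id == "only"] ==
                    "absent"))
})

test_that("presence vectors recount the matrix and honour the grey flag", {
  ds <- tiny_dataset(seed = 28, n_families = 8)
  pm <- build_profile(ds$registry)
  # force one call to sub_threshold to exercise the flag
  i <- which(pm$calls$status == "orthologue")[1]
  pm$calls$status[i] <- "sub_threshold"
  gene <- pm$calls$ref_gene_id[i]; gm <- pm$calls$genome_id[i]
  strict <- presence_vector(pm, gene)
  loose <- presence_vector(pm, gene, count_sub_threshold = TRUE)
  expect_equal(strict[[gm]], 0L)
  expect_equal(loose[[gm]], 1L)
  expect_equal(sum(loose != strict), 1L)
  # recount oracle over every row
  for (g in pm$genes) {
    pv <- presence_vector(pm, g)
    for (gm2 in pm$genomes) {
      cell <- pm$calls[pm$calls$ref_gene_id == g &
                         pm$calls$genome_id == gm2, ]
      expect_equal(pv[[gm2]], as.integer(cell$status == "orthologue"))
    }
  }
  expect_error(presence_vector(pm, "nope"), "not in profile")
})

test_that("profile TSV serialisation is deterministic", {
  ds <- tiny_dataset(seed = 29, n_families = 5)
  pm <- build_profile(ds$registry)
  dir <- withr::local_tempdir()
  p1 <- write_profile_tsv(pm, file.path(dir, "m1.tsv"))
  p2 <- write_profile_tsv(pm, file.path(dir, "m2.tsv"))
  expect_identical(readLines(p1), readLines(p2))
  first <- strsplit(readLines(p1)[2], "\t")[[1]]
  expect_match(first[2], "^[OS]:[0-9.]+$|^-$")
})
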