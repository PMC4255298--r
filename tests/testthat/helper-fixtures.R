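# Fixture builders, all generated in code.

# genome from a named character vector of proteins (CDSs optional)
make_genome <- function(genome_id, proteins, cds = NULL,
                        taxon_group = "test") {
  recs <- lapply(seq_along(proteins), function(i) {
    gene_record(names(proteins)[i], proteins[[i]],
                if (is.null(cds)) NA_character_ else cds[[i]],
                "chr", i - 1L, "+")
  })
  genome(genome_id, do.call(rbind, recs), taxon_group)
}

# back-translate a protein deterministically (first codon of each residue,
# never TTA), ending with TAA; handy when tests need valid CDSs
simple_cds <- function(protein) {
  gc <- Biostrings::getGeneticCode("11")
  by_aa <- split(names(gc), gc)
  aa <- strsplit(protein, "")[[1]]
  codons <- vapply(aa, function(a) setdiff(sort(by_aa[[a]]), "TTA")[1], "")
  paste(c(codons, "TAA"), collapse = "")
}

# small two-clade dataset reused by several module tests
tiny_dataset <- function(seed = 7, n_families = 12, ...) {
  nwk <- "(((A:0.04,B:0.04):0.03,C:0.06):0.03,(D:0.05,E:0.05):0.04);"
  simulate_genomes(sim_params(read_tree(text = nwk),
                              n_families = n_families, seed = seed, ...))
}
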