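# one annotated genome + reference proteins, shared across blocks
tmpl <- genome_template()
set.seed(71)
ref_genome <- simulate_root_genome(tmpl, taxon = "ref")
prot_refs <- protein_reference(ref_genome)

test_that("the invertebrate mitochondrial code is applied (table 5)", {
  expect_equal(translate_mt("AGA"), "S")   # Ser, not Arg/stop
  expect_equal(translate_mt("AGG"), "S")
  expect_equal(translate_mt("ATA"), "M")   # Met, not Ile
  expect_equal(translate_mt("TGA"), "W")   # Trp, not stop
  expect_equal(translate_mt("ATGAAATAA"), "MK")  # terminal stop dropped
  expect_equal(translate_mt("ATGTAAAAA"), "M*K") # internal stop retained
})

test_that("self-annotation: translated search recovers the template exactly", {
  hits <- extract_genes(ref_genome, prot_refs)
  expect_equal(nrow(hits), 13)
  expect_length(attr(hits, "missing"), 0)
  cds_tab <- tmpl[tmpl$type == "CDS", ]
  m <- merge(hits, cds_tab, by.x = "gene", by.y = "name")
  expect_equal(m$start.x, m$start.y)
  expect_equal(m$end.x, m$end.y)
  expect_equal(m$strand.x, m$strand.y)
  expect_true(all(nchar(hits$cds) %% 3 == 0))
  expect_true(all(hits$pident > 99))
  # extracted CDS equal the annotated CDS
  for (g in c("COX1", "ND5", "ATP8"))
    expect_identical(hits$cds[hits$gene == g], gene_cds(ref_genome, g))
})

test_that("gene extraction is invariant to genome rotation", {
  L <- nchar(ref_genome$seq)
  rot <- mitogenome(paste0(substr(ref_genome$seq, 4001, L),
                           substr(ref_genome$seq, 1, 4000)), taxon = "rot")
  h0 <- extract_genes(ref_genome, prot_refs)
  h1 <- extract_genes(rot, prot_refs)
  expect_equal(nrow(h1), 13)
  m <- merge(h0, h1, by = "gene")
  expect_true(all((m$start.x - 4000) %% L == m$start.y %% L))
  expect_identical(sort(m$cds.x), sort(m$cds.y))
})

test_that("a deleted gene is reported missing, not silently dropped", {
  set.seed(72)
  mut <- ref_genome$seq
  i <- match("ND3", tmpl$name)
  substr(mut, tmpl$start[i] + 1, tmpl$end[i]) <- random_dna(tmpl$length[i])
  h <- extract_genes(mitogenome(mut, taxon = "del"), prot_refs)
  expect_equal(nrow(h), 12)
  expect_identical(attr(h, "missing"), "ND3")
})

test_that("codon alignment: identity, frame-preserving insertions, round-trip", {
  cds0 <- gene_cds(ref_genome, "ND3")
  idn <- setNames(rep(cds0, 3), c("a", "b", "c"))
  ca <- codon_align(idn)
  expect_equal(unname(nchar(ca)), rep(nchar(cds0), 3))
  expect_false(any(grepl("-", ca)))
  # one taxon with one extra codon: everyone else gains one triplet gap
  ins <- idn
  ins["b"] <- paste0(substr(cds0, 1, 150), "GCA", substr(cds0, 151, nchar(cds0)))
  ca2 <- codon_align(ins)
  expect_equal(unname(nchar(ca2)), rep(nchar(cds0) + 3, 3))
  expect_equal(lengths(regmatches(ca2["a"], gregexpr("-+", ca2["a"]))), c(a = 1))
  expect_equal(nchar(regmatches(ca2["a"], gregexpr("-+", ca2["a"]))[[1]]), 3)
  # ungapping recovers every input CDS
  for (tx in names(ins))
    expect_identical(gsub("-", "", ca2[[tx]]), unname(ins[tx]))
  expect_true(all(nchar(ca2) %% 3 == 0))
  expect_error(codon_align(ins[1]), ">= 2")
  bad <- idn
  bad["b"] <- paste0("ATGTAA", substr(cds0, 7, nchar(cds0)))
  expect_error(codon_align(bad), "internal stop.*'b'")
})

test_that("alignments of diverged orthologs stay in frame and round-trip", {
  tr <- simulate_time_tree(4, 0.2, 3, seed = 73)
  gs <- evolve_genomes(tr, simulation_truth(seed = 74), tmpl,
                       root_genome = ref_genome, avoid_stops = TRUE)
  for (g in c("ND2", "CYTB")) {
    cds <- vapply(gs, gene_cds, "", g)
    ca <- codon_align(cds, g)
    expect_true(all(nchar(ca) %% 3 == 0))
    gaps <- regmatches(ca, gregexpr("-+", ca))
    expect_true(all(unlist(lapply(gaps, nchar)) %% 3 == 0))
    for (tx in names(cds))
      expect_identical(gsub("-", "", ca[[tx]]), unname(cds[tx]))
  }
})

test_that("concatenation builds a partitioned supermatrix with codon classes", {
  a1 <- structure(setNames(c("ATGGCATAA", "ATGGCTTAA"), c("x", "y")),
                  class = "codon_alignment", gene = "g1")
  a2 <- structure(setNames(c(strrep("ATGGCA", 3), strrep("ATGGCC", 3)),
                           c("x", "y")), class = "codon_alignment", gene = "g2")
  sm <- concatenate(list(g1 = a1, g2 = a2))
  expect_equal(nchar(sm$seqs[["x"]]), 9 + 18)
  expect_equal(sm$partitions$start, c(1L, 10L))
  expect_equal(sm$partitions$end, c(9L, 27L))
  expect_identical(sm$classes[1:6], c("12", "12", "3", "12", "12", "3"))
  expect_error(concatenate(list(g1 = a1), taxa = c("x", "x")), "duplicate")
  # a taxon missing from one gene is gap-filled and flagged
  a3 <- structure(setNames("ATGGCATAA", "z"), class = "codon_alignment")
  sm2 <- concatenate(list(g1 = a1, g3 = a3))
  expect_equal(nchar(sm2$seqs[["z"]]), 18)
  expect_identical(substr(sm2$seqs[["z"]], 1, 9), strrep("-", 9))
  expect_true(all(c("x", "y", "z") %in% attr(sm2, "filled_taxa")))
})

test_that("supermatrix writers and the PHYLIP reader round-trip", {
  a1 <- setNames(c("ATGGCATAA", "ATGGCTTAA"), c("x", "y"))
  sm <- concatenate(list(ND2 = a1, COX1 = a1))
  d <- withr::local_tempdir()
  paths <- write_supermatrix(sm, file.path(d, "sm"))
  expect_true(all(file.exists(paths)))
  back <- read_supermatrix(paths[1], paths[3])
  expect_identical(back$seqs, sm$seqs)
  expect_equal(back$partitions$gene, sm$partitions$gene)
  expect_identical(back$classes, sm$classes)
  # the NEXUS copy parses
  nx <- ape::read.nexus.data(paths[2])
  expect_equal(toupper(paste(nx$x, collapse = "")), sm$seqs[["x"]])
})

test_that("the 13-gene concatenation over simulated genomes has the expected size", {
  tr <- simulate_time_tree(3, 0.2, 2, seed = 75)
  gs <- evolve_genomes(tr, simulation_truth(seed = 76), tmpl,
                       root_genome = ref_genome, avoid_stops = TRUE)
  alns <- lapply(setNames(nm = c("ND1", "ND2", "ND3", "ND4", "ND4L", "ND5",
                                 "ND6", "COX1", "COX2", "COX3", "CYTB",
                                 "ATP6", "ATP8")), function(g)
    codon_align(vapply(gs, gene_cds, "", g), g))
  sm <- concatenate(alns)
  cds_total <- sum(tmpl$length[tmpl$type == "CDS"])
  # no indels are simulated, but the aligner may open a few compensating
  # triplet gaps in divergent stretches; allow at most a few codons of slack
  width <- nchar(sm$seqs[[1]])
  expect_gte(width, cds_total)
  expect_lt(width - cds_total, 40)
  expect_equal(width %% 3, 0)
  expect_equal(nrow(sm$partitions), 13)
})
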