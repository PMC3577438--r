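test_that("k-mer graph counts and canonicalization behave", {
  r <- "ACGTACGTACGTACGTACGTA"           # length 21
  g <- build_graph(r, 15)
  expect_equal(sum(g$counts), 21 - 15 + 1)
  expect_error(build_graph(r, 16), "odd")
  # a k-mer and its reverse complement collapse to one node
  g2 <- build_graph(c("ACGTACGTACGTACG", revcomp("ACGTACGTACGTACG")), 15)
  expect_length(g2$counts, 1)
  expect_equal(unname(g2$counts[1]), 2L)
})

test_that("graph of deep error-free circular reads equals the genome k-mer set", {
  g <- toy_genome(2000, seed = 41)
  rm <- shotgun_reads(g, NULL, mean_coverage = 200, read_len = 100,
                      error_rate = 0, seed = 42)
  gr <- build_graph(read_sequences(rm), 29)
  circ <- paste0(g$seq, substr(g$seq, 1, 28))
  truth <- sort(unique(mitochron:::canonical_kmers(
    substring(circ, 1:2000, 29:2028))))
  expect_identical(sort(names(gr$counts)), truth)
})

test_that("two reads sharing a (k-1)-overlap assemble into one merged contig", {
  set.seed(43)
  s <- random_dna(60, c(A = .3, C = .2, G = .2, T = .3))
  r1 <- substr(s, 1, 40); r2 <- substr(s, 21, 60)
  ct <- assemble_contigs(build_graph(c(r1, r2), 21), 1)
  expect_equal(nrow(ct), 1)
  expect_true(ct$seq == s || ct$seq == revcomp(s))
})

test_that("coverage cutoff removes rare k-mers; clean circles give one contig", {
  g <- toy_genome(1500, seed = 44)
  rm <- shotgun_reads(g, NULL, mean_coverage = 300, read_len = 100,
                      error_rate = 0, seed = 45)
  reads <- read_sequences(rm)
  spike <- paste(rep("ACGGT", 10), collapse = "")   # one stray read
  gr <- build_graph(c(reads, spike), 29)
  ct <- assemble_contigs(gr, 70)
  expect_equal(nrow(ct), 1)
  expect_true(ct$circular[1])
  expect_equal(ct$length[1], 1500)
  dbl <- paste0(g$seq, g$seq)
  expect_true(grepl(ct$seq[1], dbl, fixed = TRUE) ||
              grepl(revcomp(ct$seq[1]), dbl, fixed = TRUE))
  # the spiked k-mers fell below the cutoff
  expect_false(grepl("ACGGTACGGT", paste(ct$seq, collapse = "|"), fixed = TRUE))
})

test_that("an exact repeat longer than k splits the assembly at the branch", {
  set.seed(46)
  u1 <- random_dna(300); u2 <- random_dna(300); rep_seq <- random_dna(60)
  genome <- paste0(u1, rep_seq, u2, rep_seq)       # circular with 60 bp repeat
  g <- mitogenome(genome)
  rm <- shotgun_reads(g, NULL, mean_coverage = 150, read_len = 90,
                      error_rate = 0, seed = 47)
  ct <- assemble_contigs(build_graph(read_sequences(rm), 29), 1)
  expect_gte(nrow(ct), 3)
})

test_that("anchoring places exact and reverse-complement contigs correctly", {
  g <- toy_genome(4000, seed = 48)
  c1 <- substr(g$seq, 1001, 3000)                  # ref[1000:3000), 0-based
  lay <- anchor_layout(c(c1), g)
  expect_equal(lay$start[1], 1000)
  expect_equal(lay$end[1], 3000)
  expect_equal(lay$strand[1], "+")
  lay2 <- anchor_layout(c(revcomp(c1)), g)
  expect_equal(lay2$start[1], 1000)
  expect_equal(lay2$strand[1], "-")
  # recorded overlaps equal those computed from coordinates
  c2 <- substr(g$seq, 2851, 4000)                  # overlaps c1 by 150
  lay3 <- anchor_layout(c(c1, c2), g)
  expect_equal(attr(lay3, "overlaps")[1], 150)
  # unanchorable contig is reported unplaced
  set.seed(49)
  lay4 <- anchor_layout(c(c1, random_dna(500)), g)
  expect_equal(sum(lay4$placed), 1)
})

test_that("overlap collapse applies minimal IUPAC codes and reports gaps", {
  g <- toy_genome(1200, seed = 50)
  c1 <- substr(g$seq, 1, 700)
  c2 <- substr(g$seq, 601, 1100)                   # overlap 100: agreement -> pass-through
  lay <- anchor_layout(c(c1, c2), g)
  draft <- collapse_layout(lay)
  expect_equal(substr(as.character(draft), 1, 1100), substr(g$seq, 1, 1100))
  expect_equal(attr(draft, "gaps"), data.frame(start = 1100L, end = 1200L))
  expect_equal(substr(as.character(draft), 1101, 1200), strrep("N", 100))
  # disagreement A vs G -> R (etc. via the minimal-code table)
  c2m <- c2
  pos <- 50                                        # position 650 of the genome
  base <- substr(c2m, pos, pos)
  alt <- c(A = "G", G = "A", C = "T", T = "C")[[base]]
  substr(c2m, pos, pos) <- alt
  dr2 <- collapse_layout(anchor_layout(c(c1, c2m), g))
  expect_equal(substr(as.character(dr2), 650, 650), iupac_code(c(base, alt)))
  expect_true(iupac_code(c("A", "G")) == "R" &&
              iupac_code(c("A", "C", "T")) == "H" &&
              iupac_code(c("A", "A")) == "A")
})

test_that("polish replaces strict-majority disagreements and keeps ties", {
  set.seed(51)
  truth <- random_dna(400, c(A = .3, C = .2, G = .2, T = .3))
  draft <- truth
  substr(draft, 200, 200) <- if (substr(truth, 200, 200) == "C") "A" else "C"
  reads <- vapply(seq(1, 301, by = 4), function(s)
    substr(paste0(truth, truth), s, s + 99), "")
  pol <- polish(draft, reads, k_map = 31)
  expect_identical(pol$seq, truth)
  expect_true(pol$corrected[200])
  expect_equal(pol$n_corrected, 1)
  # tie: equal support for two bases keeps the draft base
  half1 <- truth
  substr(half1, 200, 200) <- "A"
  half2 <- truth
  substr(half2, 200, 200) <- "C"
  reads_tie <- c(substr(half1, 150, 280), substr(half2, 150, 280))
  pol2 <- polish(draft, reads_tie, k_map = 31)
  expect_equal(substr(pol2$seq, 200, 200), substr(draft, 200, 200))
  # IUPAC draft positions resolve to the covering majority base
  amb <- truth
  substr(amb, 120, 120) <- "R"
  pol3 <- polish(amb, reads, k_map = 31)
  expect_identical(pol3$seq, truth)
  # error-free reads on a correct draft: zero corrections, and a second
  # pass stays at zero (convergence)
  pol4 <- polish(truth, reads, k_map = 31, max_iter = 2)
  expect_equal(pol4$n_corrected, 0)
})

test_that("genome -> reads -> enrich -> assemble -> anchor -> collapse -> polish round-trips", {
  g <- toy_genome(3000, seed = 52)
  set.seed(52)
  nuc <- random_dna(30000)
  rm <- shotgun_reads(g, nuc, copy_ratio = 55, mean_coverage = 300,
                      read_len = 100, error_rate = 0, seed = 53)
  enriched <- select_duplicated_reads(rm, 2)
  gr <- build_graph(read_sequences(enriched), 29)
  ct <- assemble_contigs(gr, 2)
  lay <- anchor_layout(ct, g)
  draft <- collapse_layout(lay)
  pol <- polish(as.character(draft), rm, 31)
  expect_identical(pol$seq, g$seq)
})
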