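MT_GENES <- c("ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6",
              "COX1", "COX2", "COX3", "CYTB", "ATP6", "ATP8")

# invertebrate mitochondrial genetic code (translation table 5)
MT_CODE <- Biostrings::getGeneticCode("5")

#' Translate DNA under the invertebrate mitochondrial code
#'
#' Translation table 5: TGA = Trp, ATA = Met, AGA/AGG = Ser.  Codons
#' containing IUPAC ambiguity translate as X; a trailing complete stop codon
#' is dropped.
#'
#' @param nt character vector of in-frame nucleotide sequences
#' @param keep_stop keep a terminal `*`
#' @return character vector of amino-acid sequences
#' @export
translate_mt <- function(nt, keep_stop = FALSE) {
  aa <- as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAStringSet(nt),
                          genetic.code = MT_CODE, if.fuzzy.codon = "X")))
  if (!keep_stop) aa <- sub("\\*$", "", aa)
  aa
}

#' Build a 13-protein reference set from an annotated mitogenome
#'
#' @param genome a `mitogenome` with a template annotation
#' @return named character vector of 13 amino-acid sequences, class
#'   `protein_reference`
#' @export
protein_reference <- function(genome) {
  aa <- vapply(MT_GENES, function(g) translate_mt(gene_cds(genome, g)), "")
  structure(aa, class = "protein_reference")
}

#' Locate the 13 protein-coding genes by translated search
#'
#' Six-frame translation of the (circular) genome under the invertebrate
#' mitochondrial code, followed by local protein alignment (BLOSUM62, affine
#' gaps) of each reference protein against every frame; the best-scoring
#' locus per gene is reported with its CDS coordinates (extended over a
#' trailing stop codon when present).  Genes scoring below `min_score` are
#' reported as missing.
#'
#' @param genome a `mitogenome` (or sequence string)
#' @param refs a [protein_reference()] or named character vector of proteins
#' @param min_score minimum local alignment score to accept a hit
#' @return data.frame of class `gene_hits`: gene, start, end (0-based
#'   half-open on the circle; end may exceed the genome length for wrapping
#'   genes), strand, frame, score, pident, cds; attribute `missing` lists
#'   genes without an acceptable hit
#' @export
extract_genes <- function(genome, refs, min_score = 100) {
  seq <- if (inherits(genome, "mitogenome")) genome$seq else toupper(genome)
  L <- nchar(seq)
  if (L < 10000) stop("genome shorter than 10 kb; not a mitogenome?")
  dbl <- paste0(seq, seq)
  frames <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dbl else revcomp(dbl)
    for (off in 0:2) {
      nt <- substr(s, off + 1L, off + ((2L * L - off) %/% 3L) * 3L)
      frames[[paste0(strand, off)]] <-
        list(aa = translate_mt(nt, keep_stop = TRUE), strand = strand, off = off)
    }
  }
  sm <- "BLOSUM62"
  rows <- list(); missing <- character()
  for (g in names(refs)) {
    best <- NULL
    pat <- Biostrings::AAString(gsub("\\*", "X", refs[[g]]))
    for (fr in frames) {
      subj <- Biostrings::AAString(gsub("\\*", "X", fr$aa))
      al <- Biostrings::pairwiseAlignment(pat, subj, type = "local",
                                          substitutionMatrix = sm,
                                          gapOpening = 10, gapExtension = 0.5)
      sc <- Biostrings::score(al)
      if (is.null(best) || sc > best$score) {
        rng <- Biostrings::subject(al)
        best <- list(score = sc, strand = fr$strand, off = fr$off,
                     aa_start = Biostrings::start(rng),
                     aa_end = Biostrings::end(rng),
                     pident = Biostrings::pid(al))
      }
    }
    if (is.null(best) || best$score < min_score) {
      missing <- c(missing, g); next
    }
    # nucleotide coords on the doubled strand
    nt_s <- best$off + (best$aa_start - 1L) * 3L          # 0-based
    nt_e <- best$off + best$aa_end * 3L
    strand_seq <- if (best$strand == "+") dbl else revcomp(dbl)
    if (nt_e + 3L <= 2L * L &&
        substr(strand_seq, nt_e + 1L, nt_e + 3L) %in% MT_STOPS) {
      nt_e <- nt_e + 3L                                   # include the stop
    }
    if (best$strand == "+") {
      start0 <- nt_s %% L; end0 <- start0 + (nt_e - nt_s)
    } else {
      # map from the reverse strand of the doubled sequence back to forward
      start0 <- (2L * L - nt_e) %% L; end0 <- start0 + (nt_e - nt_s)
    }
    cds <- substr_circ(seq, start0, nt_e - nt_s)
    if (best$strand == "-") cds <- revcomp(cds)
    rows[[g]] <- data.frame(gene = g, start = start0, end = end0,
                            strand = best$strand, frame = best$off,
                            score = best$score, pident = best$pident,
                            cds = cds, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), start = integer(), end = integer(),
               strand = character(), frame = integer(), score = numeric(),
               pident = numeric(), cds = character())
  rownames(out) <- NULL
  structure(out, class = c("gene_hits", "data.frame"), missing = missing)
}

# 4-mer amino-acid similarity used for guide ordering
.aa_kmer_sim <- function(a, b, k = 4L) {
  ka <- unique(seq_kmers(a, k)); kb <- unique(seq_kmers(b, k))
  if (!length(ka) || !length(kb)) return(0)
  length(intersect(ka, kb)) / min(length(ka), length(kb))
}

#' Codon-aware multiple alignment of one gene
#'
#' CDSs are translated under the invertebrate mitochondrial code, aligned
#' progressively at the amino-acid level (pairwise global alignments against
#' the running consensus, BLOSUM62, gap open 10 / extend 0.5, guide order by
#' descending k-mer similarity to the most central sequence), and the
#' alignment is back-translated so every gap is a frame-preserving triplet.
#'
#' @param cds_per_taxon named character vector of in-frame CDS (lengths
#'   divisible by 3), >= 2 taxa; terminal stop codons are tolerated
#' @param gene gene name carried in the result
#' @return object of class `codon_alignment`: named character vector of
#'   aligned nucleotide sequences with attributes `gene`, `aa_alignment`
#' @export
codon_align <- function(cds_per_taxon, gene = "gene") {
  if (length(cds_per_taxon) < 2L) stop("need >= 2 taxa")
  if (any(nchar(cds_per_taxon) %% 3L != 0L))
    stop("CDS length not divisible by 3 for: ",
         paste(names(cds_per_taxon)[nchar(cds_per_taxon) %% 3L != 0L],
               collapse = ", "))
  taxa <- names(cds_per_taxon) %||% paste0("t", seq_along(cds_per_taxon))
  aa <- translate_mt(cds_per_taxon)
  stops <- regexpr("\\*", aa)
  if (any(stops > 0)) {
    i <- which(stops > 0)[1]
    stop("internal stop codon in taxon '", taxa[i], "' at codon ", stops[i])
  }
  n <- length(aa)
  sim <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    sim[i, j] <- .aa_kmer_sim(aa[i], aa[j])
  center <- which.max(rowSums(sim))
  ord <- c(center, setdiff(order(sim[center, ], decreasing = TRUE), center))
  msa <- matrix(strsplit(aa[ord[1]], "")[[1]], nrow = 1)
  added <- ord[1]
  for (i in ord[-1]) {
    cons <- apply(msa, 2, function(col) {
      col <- col[col != "-"]
      if (!length(col)) "A" else names(sort(table(col), decreasing = TRUE))[1]
    })
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(aa[i]),
      Biostrings::AAString(paste(cons, collapse = "")),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5)
    pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    # columns where the consensus gained a gap -> insert gap columns into msa
    new_msa <- matrix("-", nrow(msa) + 1L, length(pat))
    msa_col <- 0L
    for (c2 in seq_along(pat)) {
      if (sub[c2] != "-") {
        msa_col <- msa_col + 1L
        new_msa[seq_len(nrow(msa)), c2] <- msa[, msa_col]
      }
      new_msa[nrow(msa) + 1L, c2] <- pat[c2]
    }
    msa <- new_msa
    added <- c(added, i)
  }
  aa_aln <- setNames(apply(msa, 1, paste, collapse = ""), taxa[added])
  aa_aln <- aa_aln[taxa]                       # restore input order
  nt_aln <- vapply(taxa, function(tx) {
    cod <- substring(cds_per_taxon[[tx]],
                     seq(1, nchar(cds_per_taxon[[tx]]) - 2, 3),
                     seq(3, nchar(cds_per_taxon[[tx]]), 3))
    has_stop <- length(cod) && cod[length(cod)] %in% MT_STOPS
    aach <- strsplit(aa_aln[[tx]], "")[[1]]
    out <- character(length(aach))
    ci <- 0L
    for (p in seq_along(aach)) {
      if (aach[p] == "-") out[p] <- "---"
      else { ci <- ci + 1L; out[p] <- cod[ci] }
    }
    if (has_stop) out <- c(out, cod[length(cod)])   # re-append terminal stop
    paste(out, collapse = "")
  }, "")
  # pad to equal length if some taxa carried terminal stops and others not
  w <- nchar(nt_aln)
  if (length(unique(w)) > 1L)
    nt_aln <- paste0(nt_aln, strrep("-", max(w) - w))
  structure(setNames(nt_aln, taxa), class = "codon_alignment",
            gene = gene, aa_alignment = aa_aln)
}

#' Concatenate per-gene codon alignments into a partitioned supermatrix
#'
#' @param alignments named list of [codon_align()] results (or named character
#'   vectors of equal-length aligned sequences)
#' @param taxa taxon order for the output (default: union in input order);
#'   taxa missing from a gene are filled with gaps and flagged
#' @return object of class `supermatrix`: list(seqs, partitions, classes)
#'   where `partitions` maps gene -> 1-based column interval and `classes`
#'   labels every column "12" or "3" by codon position
#' @export
concatenate <- function(alignments, taxa = NULL) {
  if (is.null(names(alignments)))
    names(alignments) <- paste0("gene", seq_along(alignments))
  all_taxa <- taxa %||% unique(unlist(lapply(alignments, names)))
  if (anyDuplicated(all_taxa)) stop("duplicate taxon labels")
  pieces <- matrix("", length(all_taxa), length(alignments),
                   dimnames = list(all_taxa, names(alignments)))
  lens <- integer(length(alignments))
  filled <- character()
  for (j in seq_along(alignments)) {
    a <- alignments[[j]]
    lens[j] <- nchar(a[[1]])
    for (tx in all_taxa) {
      if (tx %in% names(a)) pieces[tx, j] <- a[[tx]]
      else { pieces[tx, j] <- strrep("-", lens[j]); filled <- c(filled, tx) }
    }
  }
  seqs <- setNames(apply(pieces, 1, paste, collapse = ""), all_taxa)
  ends <- cumsum(lens)
  partitions <- data.frame(gene = names(alignments),
                           start = ends - lens + 1L, end = ends)
  classes <- unlist(lapply(lens, function(l)
    rep(c("12", "12", "3"), length.out = l)), use.names = FALSE)
  structure(list(seqs = seqs, partitions = partitions, classes = classes),
            class = "supermatrix", filled_taxa = unique(filled))
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("supermatrix:", length(x$seqs), "taxa x", nchar(x$seqs[[1]]),
      "columns,", nrow(x$partitions), "gene partitions\n")
  invisible(x)
}

#' Supermatrix as a character matrix (taxa x columns)
#' @param sm a `supermatrix`
#' @return character matrix
#' @export
sm_matrix <- function(sm) {
  do.call(rbind, strsplit(sm$seqs, ""))
}

#' Write a supermatrix (relaxed PHYLIP, NEXUS and partition TSV)
#'
#' @param sm a `supermatrix`
#' @param prefix output path prefix; writes `<prefix>.phy`, `<prefix>.nex`
#'   and `<prefix>.partitions.tsv`
#' @return invisibly, the three paths
#' @export
write_supermatrix <- function(sm, prefix) {
  phy <- paste0(prefix, ".phy"); nex <- paste0(prefix, ".nex")
  tsv <- paste0(prefix, ".partitions.tsv")
  n <- length(sm$seqs); L <- nchar(sm$seqs[[1]])
  writeLines(c(paste(n, L),
               paste(names(sm$seqs), sm$seqs)), phy)
  m <- lapply(strsplit(sm$seqs, ""), tolower)
  ape::write.nexus.data(m, nex, interleaved = FALSE)
  part <- sm$partitions
  part3 <- do.call(rbind, lapply(seq_len(nrow(part)), function(i)
    data.frame(gene = part$gene[i],
               start = part$start[i], end = part$end[i],
               class = c("12", "3"))))
  write.table(part3, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(phy, nex, tsv))
}

#' Read a relaxed-PHYLIP supermatrix and its partition TSV
#' @param phy path to the `.phy` file
#' @param partitions optional path to the partition TSV
#' @return a `supermatrix`
#' @export
read_supermatrix <- function(phy, partitions = NULL) {
  ln <- readLines(phy)
  hdr <- scan(text = ln[1], quiet = TRUE)
  parts <- strsplit(trimws(ln[-1]), "\\s+")
  parts <- parts[lengths(parts) == 2L]
  seqs <- setNames(toupper(vapply(parts, `[[`, "", 2L)),
                   vapply(parts, `[[`, "", 1L))
  part <- NULL
  L <- nchar(seqs[[1]])
  classes <- rep("12", L)
  if (!is.null(partitions)) {
    tab <- read.table(partitions, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    part <- unique(tab[, c("gene", "start", "end")])
    classes <- unlist(lapply(part$end - part$start + 1L, function(l)
      rep(c("12", "12", "3"), length.out = l)))
  } else {
    part <- data.frame(gene = "all", start = 1L, end = L)
    classes <- rep(c("12", "12", "3"), length.out = L)
  }
  structure(list(seqs = seqs, partitions = part, classes = classes),
            class = "supermatrix")
}
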