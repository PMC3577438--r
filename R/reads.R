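#' Construct a paired-end read multiset
#'
#' One row per read pair; `origin` records the simulated source (mt/nuclear)
#' when known.  Single-end (mate-flattened) multisets have `seq2 = NA`.
#'
#' @param seq1,seq2 mate sequences (seq2 may be NA for unpaired sets)
#' @param origin per-pair origin label ("mt", "nuclear" or NA)
#' @param id read ids
#' @return data.frame of class `read_multiset`
#' @export
read_multiset <- function(seq1, seq2 = NA_character_, origin = NA_character_,
                          id = NULL) {
  n <- length(seq1)
  seq2 <- rep_len(if (all(is.na(seq2))) NA_character_ else toupper(seq2), n)
  df <- data.frame(id = id %||% sprintf("read%d", seq_len(n)),
                   seq1 = toupper(seq1), seq2 = seq2,
                   origin = rep_len(origin, n), stringsAsFactors = FALSE)
  structure(df, class = c("read_multiset", "data.frame"))
}

#' @export
print.read_multiset <- function(x, ...) {
  paired <- !all(is.na(x$seq2))
  cat("read_multiset:", nrow(x), if (paired) "pairs" else "reads",
      sprintf("(read length %d)", nchar(x$seq1[1])), "\n")
  invisible(x)
}

#' All mate sequences of a read multiset as a flat character vector
#' @param reads a `read_multiset`
#' @return character vector (2N for paired sets)
#' @export
read_sequences <- function(reads) {
  if (all(is.na(reads$seq2))) reads$seq1 else c(reads$seq1, reads$seq2)
}

# uniform substitution errors
.add_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  len <- nchar(seqs[1])
  nerr <- rbinom(length(seqs), len, rate)
  hit <- which(nerr > 0)
  for (i in hit) {
    pos <- sample.int(len, nerr[i])
    ch <- strsplit(seqs[i], "")[[1]]
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(DNA, b), 1L), "")
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate whole-genome shotgun read pairs
#'
#' Fragments of length `insert_size` are drawn uniformly from the circular
#' mitogenome(s) and the linear nuclear background in proportion to
#' `copy_ratio`; each fragment yields a forward read and a reverse-complement
#' mate.  `mean_coverage` is the target per-bp coverage of the mitogenome;
#' nuclear coverage is `mean_coverage / copy_ratio`.
#'
#' @param genomes a `mitogenome` or list of them
#' @param nuclear_background nuclear surrogate sequence (string); NULL for
#'   mt-only read sets
#' @param copy_ratio mt genome copies per nuclear copy (>= 1)
#' @param mean_coverage target mt per-bp coverage
#' @param read_len read length in bp
#' @param insert_size fragment length (default 300 bp)
#' @param error_rate per-base substitution error probability
#' @param seed optional seed
#' @return a paired `read_multiset` with per-pair origin labels
#' @export
shotgun_reads <- function(genomes, nuclear_background = NULL, copy_ratio = 55,
                          mean_coverage = 500, read_len = 100L,
                          insert_size = 300L, error_rate = 0.002,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (copy_ratio < 1) stop("copy_ratio must be >= 1")
  if (mean_coverage <= 0) stop("coverage must be positive")
  if (inherits(genomes, "mitogenome")) genomes <- list(genomes)
  insert_size <- max(insert_size, 2L * read_len)
  s1 <- character(); s2 <- character(); org <- character()
  for (g in genomes) {
    L <- nchar(g$seq)
    if (read_len > L) stop("read_len exceeds genome length")
    npair <- round(mean_coverage * L / (2 * read_len))
    starts <- sample.int(L, npair, replace = TRUE) - 1L
    frags <- substr_circ_vec(g$seq, starts, insert_size)
    s1 <- c(s1, substr(frags, 1L, read_len))
    s2 <- c(s2, revcomp(substr(frags, insert_size - read_len + 1L, insert_size)))
    org <- c(org, rep("mt", npair))
  }
  if (!is.null(nuclear_background)) {
    Ln <- nchar(nuclear_background)
    if (Ln <= insert_size) stop("nuclear background shorter than insert size")
    ncov <- mean_coverage / copy_ratio
    npair <- round(ncov * Ln / (2 * read_len))
    starts <- sample.int(Ln - insert_size + 1L, npair, replace = TRUE)
    frags <- substring(nuclear_background, starts, starts + insert_size - 1L)
    s1 <- c(s1, substr(frags, 1L, read_len))
    s2 <- c(s2, revcomp(substr(frags, insert_size - read_len + 1L, insert_size)))
    org <- c(org, rep("nuclear", npair))
  }
  s1 <- .add_errors(s1, error_rate)
  s2 <- .add_errors(s2, error_rate)
  read_multiset(s1, s2, org)
}

# vectorized circular substring
substr_circ_vec <- function(seq, starts0, len) {
  dbl <- paste0(seq, seq)
  substring(dbl, starts0 + 1L, starts0 + len)
}

#' Write a paired read multiset as two FASTQ files
#'
#' Mates carry `/1` and `/2` suffixes; qualities are constant Q30.
#'
#' @param reads a paired `read_multiset`
#' @param prefix output prefix; writes `<prefix>_R1.fastq`, `<prefix>_R2.fastq`
#' @return invisibly, the two file paths
#' @export
write_fastq_pair <- function(reads, prefix) {
  q <- function(s) strrep("?", nchar(s))   # '?' = Phred+33 Q30
  f1 <- paste0(prefix, "_R1.fastq"); f2 <- paste0(prefix, "_R2.fastq")
  writeLines(rbind(paste0("@", reads$id, "/1"), reads$seq1, "+", q(reads$seq1)), f1)
  writeLines(rbind(paste0("@", reads$id, "/2"), reads$seq2, "+", q(reads$seq2)), f2)
  invisible(c(f1, f2))
}

#' Read a pair of FASTQ files into a read multiset
#' @param file1,file2 FASTQ paths (mate 1 and mate 2); file2 may be NULL
#' @return a `read_multiset`
#' @export
read_fastq_pair <- function(file1, file2 = NULL) {
  r1 <- Biostrings::readDNAStringSet(file1, format = "fastq")
  s2 <- NA_character_
  if (!is.null(file2)) s2 <- as.character(Biostrings::readDNAStringSet(file2, format = "fastq"))
  read_multiset(as.character(r1), s2, id = sub("/[12]$", "", names(r1)))
}

#' Write sequences to FASTA
#' @param seqs named character vector, `mitogenome`, or list of mitogenomes
#' @param file output path
#' @return invisibly, the path
#' @export
write_fasta <- function(seqs, file) {
  if (inherits(seqs, "mitogenome")) seqs <- list(seqs)
  if (is.list(seqs)) {
    seqs <- setNames(vapply(seqs, `[[`, "", "seq"),
                     vapply(seqs, `[[`, "", "taxon"))
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), file)
  invisible(file)
}

#' Write the simulation truth table (read id, origin) as TSV
#' @param reads a `read_multiset`
#' @param file output path
#' @return invisibly, the path
#' @export
write_truth_table <- function(reads, file) {
  write.table(data.frame(id = reads$id, origin = reads$origin),
              file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
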