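#' @useDynLib mitochron, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim qgamma pgamma quantile rexp runif rbinom acf setNames dnorm sd
#' @importFrom utils head tail write.table read.table
NULL

DNA <- c("A", "C", "G", "T")

# IUPAC code <-> base-set tables (sorted base sets, names are the codes)
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)
IUPAC_OF_SET <- setNames(names(IUPAC_SETS),
                         vapply(IUPAC_SETS, paste, "", collapse = ""))

#' Minimal IUPAC code covering a set of bases
#' @param bases character vector of bases/IUPAC codes observed at a position
#' @return single IUPAC letter
#' @export
iupac_code <- function(bases) {
  expanded <- sort(unique(unlist(IUPAC_SETS[toupper(bases)], use.names = FALSE)))
  code <- IUPAC_OF_SET[paste(expanded, collapse = "")]
  if (is.na(code)) stop("cannot encode base set: ", paste(bases, collapse = ","))
  unname(code)
}

#' Reverse complement of DNA strings (IUPAC-aware)
#' @param x character vector of sequences
#' @return character vector
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Draw a random DNA sequence
#' @param n length in bp
#' @param freqs base frequencies (A, C, G, T)
#' @return a single string
#' @export
random_dna <- function(n, freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(DNA, n, replace = TRUE, prob = freqs), collapse = "")
}

# circular substring: 0-based start, length len, sequence treated as a circle
substr_circ <- function(seq, start0, len) {
  L <- nchar(seq)
  stopifnot(len <= 2L * L)
  dbl <- paste0(seq, seq)
  substr(dbl, start0 + 1L, start0 + len)
}

# all k-mers of a set of sequences (forward strand), as one character vector
seq_kmers <- function(seqs, k) {
  seqs <- seqs[nchar(seqs) >= k]
  if (!length(seqs)) return(character())
  unlist(lapply(seqs, function(s) {
    n <- nchar(s) - k + 1L
    substring(s, 1:n, k:(n + k - 1L))
  }), use.names = FALSE)
}

# canonical form: lexicographic min of a k-mer and its reverse complement
canonical_kmers <- function(kmers) {
  rc <- revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
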