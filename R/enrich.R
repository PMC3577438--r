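#' Select reads occurring at least `min_multiplicity` times
#'
#' The duplicate-read enrichment heuristic: at very high mitochondrial copy
#' number, reads whose exact sequence occurs twice or more in a shotgun
#' dataset are overwhelmingly mitochondrial.  Each mate is counted
#' independently by default; with `require_pair = TRUE` a pair is kept only if
#' both mates pass.
#'
#' @param reads a `read_multiset`
#' @param min_multiplicity minimum exact-sequence count (default 2)
#' @param require_pair keep pairs only when both mates pass
#' @param collapse_rc count a read and its reverse complement together
#' @return a `read_multiset` of retained reads (mate-flattened unless
#'   `require_pair`), multiplicities preserved; see [enrichment_report()]
#' @export
select_duplicated_reads <- function(reads, min_multiplicity = 2L,
                                    require_pair = FALSE,
                                    collapse_rc = FALSE) {
  if (min_multiplicity < 1) stop("min_multiplicity must be >= 1")
  if (!nrow(reads)) stop("empty read multiset")
  key <- function(s) if (collapse_rc) canonical_kmers(s) else s
  paired <- !all(is.na(reads$seq2))
  allseq <- key(read_sequences(reads))
  cnt <- table(allseq)
  pass <- function(s) cnt[key(s)] >= min_multiplicity
  if (paired && require_pair) {
    keep <- pass(reads$seq1) & pass(reads$seq2)
    out <- reads[keep, , drop = FALSE]
    class(out) <- class(reads)
    return(out)
  }
  if (paired) {
    k1 <- pass(reads$seq1); k2 <- pass(reads$seq2)
    read_multiset(c(reads$seq1[k1], reads$seq2[k2]),
                  origin = c(reads$origin[k1], reads$origin[k2]),
                  id = c(paste0(reads$id[k1], "/1"), paste0(reads$id[k2], "/2")))
  } else {
    out <- reads[pass(reads$seq1), , drop = FALSE]
    class(out) <- class(reads)
    out
  }
}

#' Abundance filter with deduplication
#'
#' Retains one instance of every distinct sequence represented by strictly
#' more than `min_count` reads (the coverage-normalization step used before
#' de novo assembly of amplicon data: rare sequences are treated as
#' error-bearing, and multiplicity is collapsed to 1).
#'
#' @param reads a `read_multiset` (mates are pooled)
#' @param min_count strict lower bound on multiplicity (default 20: a
#'   sequence needs > 20 supporting reads)
#' @return character vector of distinct retained sequences
#' @export
abundance_filter_dedup <- function(reads, min_count = 20L) {
  if (min_count < 0) stop("min_count must be non-negative")
  if (!nrow(reads)) return(character())
  cnt <- table(read_sequences(reads))
  names(cnt)[cnt > min_count]
}

#' Enrichment report: purity and recall against simulation truth
#'
#' @param input the unfiltered `read_multiset` (with origin labels)
#' @param retained the filtered `read_multiset`
#' @return object of class `enrichment_report` (a one-row data.frame with
#'   input/retained counts, distinct sequences, purity and recall)
#' @export
enrichment_report <- function(input, retained) {
  n_in <- sum(!is.na(c(input$seq1, input$seq2)))
  n_out <- sum(!is.na(c(retained$seq1, retained$seq2)))
  purity <- recall <- NA_real_
  if (!all(is.na(input$origin)) && !all(is.na(retained$origin))) {
    mates_in <- if (all(is.na(input$seq2))) 1L else 2L
    mates_out <- if (all(is.na(retained$seq2))) 1L else 2L
    mt_in <- sum(input$origin == "mt") * mates_in
    mt_out <- sum(retained$origin == "mt") * mates_out
    purity <- mt_out / n_out
    recall <- mt_out / mt_in
  }
  structure(data.frame(input = n_in, retained = n_out,
                       distinct = length(unique(read_sequences(retained))),
                       purity = purity, recall = recall),
            class = c("enrichment_report", "data.frame"))
}

#' Estimate the mitochondrial:nuclear copy ratio from marker coverage
#'
#' Reads are assigned to markers by exact k-mer matching; the ratio of per-bp
#' coverage on the mitochondrial markers to per-bp coverage on the nuclear
#' marker estimates the copy-number excess of the mitogenome.
#'
#' @param reads a `read_multiset`
#' @param mt_marker_seqs character vector of mitochondrial marker sequences
#'   (e.g. COI, COII), each >= 200 bp
#' @param nuclear_marker_seq nuclear single-copy marker (e.g. VGSC), >= 200 bp
#' @param k k-mer size for read assignment (<= read length)
#' @return fold ratio (mt/nuclear per-bp coverage); `Inf` with a warning and
#'   attribute `zero_nuclear = TRUE` when no reads match the nuclear marker
#' @export
estimate_copy_ratio <- function(reads, mt_marker_seqs, nuclear_marker_seq,
                                k = 31L) {
  if (any(nchar(c(mt_marker_seqs, nuclear_marker_seq)) < 200))
    stop("markers must be >= 200 bp")
  if (k > nchar(reads$seq1[1])) stop("k exceeds read length")
  mt_set <- unique(canonical_kmers(seq_kmers(mt_marker_seqs, k)))
  nuc_set <- unique(canonical_kmers(seq_kmers(nuclear_marker_seq, k)))
  nuc_set <- setdiff(nuc_set, mt_set)
  seqs <- read_sequences(reads)
  assign_bp <- function(markers) {
    hit <- vapply(seqs, function(s) {
      any(canonical_kmers(seq_kmers(s, k)) %in% markers)
    }, TRUE, USE.NAMES = FALSE)
    sum(nchar(seqs[hit]))
  }
  mt_cov <- assign_bp(mt_set) / sum(nchar(mt_marker_seqs))
  nuc_cov <- assign_bp(nuc_set) / nchar(nuclear_marker_seq)
  if (mt_cov == 0) return(0)
  if (nuc_cov == 0) {
    warning("no reads assigned to the nuclear marker; ratio is infinite")
    return(structure(Inf, zero_nuclear = TRUE))
  }
  mt_cov / nuc_cov
}
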