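#' Build a de Bruijn k-mer graph from reads
#'
#' k-mers are canonicalized to the lexicographic minimum of the strand pair;
#' odd k is enforced so no k-mer is its own reverse complement.  Edges are
#' implicit ((k-1)-base overlap between oriented k-mers).
#'
#' @param sequences character vector of reads or distinct sequences
#' @param k odd k-mer size
#' @return object of class `kmer_graph`: list(k, counts) where `counts` is a
#'   named integer vector of canonical k-mer multiplicities
#' @export
build_graph <- function(sequences, k) {
  if (k %% 2L == 0L) stop("k must be odd (prevents self-reverse-complement k-mers)")
  km <- seq_kmers(sequences, k)
  if (!length(km)) stop("k exceeds every sequence length")
  counts <- table(canonical_kmers(km))
  structure(list(k = as.integer(k),
                 counts = setNames(as.integer(counts), names(counts))),
            class = "kmer_graph")
}

#' @export
print.kmer_graph <- function(x, ...) {
  cat("kmer_graph: k =", x$k, ",", length(x$counts), "canonical k-mers\n")
  invisible(x)
}

#' Assemble contigs as maximal non-branching paths
#'
#' Nodes with coverage below `min_kmer_coverage` are removed (the coverage
#' cutoff used to strip sequencing-error k-mers from very deep data; use 1
#' for deduplicated read sets), then maximal unambiguous paths of the
#' bidirected graph are spelled out.  An isolated cycle (a clean circular
#' genome) is emitted once, as one rotation of the circle.
#'
#' @param graph a [build_graph()] result
#' @param min_kmer_coverage minimum k-mer count to keep a node (default 70)
#' @return data.frame of class `contig_set`: id, seq, length, mean_coverage,
#'   circular
#' @export
assemble_contigs <- function(graph, min_kmer_coverage = 70L) {
  k <- graph$k
  counts <- graph$counts[graph$counts >= min_kmer_coverage]
  if (!length(counts)) {
    warning("no k-mers left after coverage filtering")
    return(structure(data.frame(id = character(), seq = character(),
                                length = integer(), mean_coverage = numeric(),
                                circular = logical()),
                     class = c("contig_set", "data.frame")))
  }
  canon <- names(counts)
  orient <- c(canon, revcomp(canon))            # oriented node universe
  n2 <- length(orient)
  canon_of <- rep(seq_along(canon), 2L)         # oriented -> canonical index
  pref <- substr(orient, 1L, k - 1L)
  suff <- substr(orient, 2L, k)
  u <- unique(c(pref, suff))
  pm <- match(pref, u); sm <- match(suff, u)
  out_deg <- tabulate(pm, length(u))[sm]        # successors of each oriented node
  in_deg  <- tabulate(sm, length(u))[pm]        # predecessors of each oriented node
  first_pref <- match(seq_along(u), pm)         # oriented index with given prefix
  first_suff <- match(seq_along(u), sm)
  succ <- ifelse(out_deg == 1L, first_pref[sm], NA_integer_)
  pred <- ifelse(in_deg == 1L, first_suff[pm], NA_integer_)

  visited <- logical(length(canon))
  contigs <- list()
  spell <- function(path) {
    paste0(orient[path[1L]],
           paste(substr(orient[path[-1L]], k, k), collapse = ""))
  }
  walk <- function(s) {
    path <- s
    visited[canon_of[s]] <<- TRUE
    circular <- FALSE
    repeat {
      cur <- path[length(path)]
      nxt <- succ[cur]
      if (is.na(nxt) || is.na(pred[nxt])) break  # branch ahead or merge at next
      if (nxt == s) { circular <- TRUE; break }
      if (visited[canon_of[nxt]]) break
      path <- c(path, nxt)
      visited[canon_of[nxt]] <<- TRUE
    }
    list(path = path, circular = circular)
  }
  # linear unitigs start where extension backwards is ambiguous or absent
  is_start <- is.na(pred) | (!is.na(pred) & is.na(succ[ifelse(is.na(pred), 1L, pred)]))
  for (s in which(is_start)) {
    if (visited[canon_of[s]]) next
    w <- walk(s)
    contigs[[length(contigs) + 1L]] <- w
  }
  for (s in seq_len(n2)) {                       # remaining pure cycles
    if (visited[canon_of[s]]) next
    w <- walk(s)
    w$circular <- TRUE
    contigs[[length(contigs) + 1L]] <- w
  }
  seqs <- vapply(contigs, function(w) {
    s <- spell(w$path)
    if (w$circular) substr(s, 1L, length(w$path)) else s
  }, "")
  cov <- vapply(contigs, function(w) mean(counts[canon_of[w$path]]), 0)
  circ <- vapply(contigs, `[[`, TRUE, "circular")
  structure(data.frame(id = paste0("contig", seq_along(seqs)), seq = seqs,
                       length = nchar(seqs), mean_coverage = cov,
                       circular = circ, stringsAsFactors = FALSE),
            class = c("contig_set", "data.frame"))
}

#' Anchor contigs to a circular reference by exact-match voting
#'
#' Each contig is placed (both strands, circular coordinates) at the diagonal
#' supported by the largest number of exact `anchor_min`-mer matches against
#' the reference; contigs without any sufficiently long exact match are
#' reported unplaced.
#'
#' @param contigs a `contig_set` (or character vector of contig sequences)
#' @param reference a `mitogenome` or reference string (treated as circular)
#' @param anchor_min seed length for exact matching (default 20 bp)
#' @return object of class `contig_layout`: data.frame (id, seq, start, end, strand,
#'   votes, placed) sorted by reference start, 0-based half-open coordinates
#'   (`end` may exceed the reference length for wrapping contigs); attributes
#'   `reference_length`, `overlaps` (overlap with the next placed contig)
#' @export
anchor_layout <- function(contigs, reference, anchor_min = 20L) {
  if (inherits(reference, "mitogenome")) reference <- reference$seq
  if (is.character(contigs)) {
    contigs <- data.frame(id = paste0("contig", seq_along(contigs)),
                          seq = contigs, stringsAsFactors = FALSE)
  }
  L <- nchar(reference)
  refk <- seq_kmers(substr_circ(reference, 0L, L + anchor_min - 1L), anchor_min)
  place_one <- function(cseq) {
    best <- list(votes = 0L)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") cseq else revcomp(cseq)
      ck <- seq_kmers(s, anchor_min)
      if (!length(ck)) next
      hit <- match(ck, refk)                       # first ref position per seed
      ok <- which(!is.na(hit))
      if (!length(ok)) next
      diag0 <- (hit[ok] - ok) %% L                 # implied contig start (0-based)
      tab <- table(diag0)
      v <- max(tab)
      if (v > best$votes) {
        best <- list(votes = as.integer(v),
                     start = as.integer(names(tab)[which.max(tab)]),
                     strand = strand, seq = s)
      }
    }
    best
  }
  res <- lapply(contigs$seq, place_one)
  placed <- vapply(res, function(r) r$votes > 0L, TRUE)
  df <- data.frame(id = contigs$id,
                   seq = ifelse(placed, vapply(res, function(r) r$seq %||% NA_character_, ""), contigs$seq),
                   start = vapply(res, function(r) r$start %||% NA_integer_, 1L),
                   strand = vapply(res, function(r) r$strand %||% NA_character_, ""),
                   votes = vapply(res, `[[`, 1L, "votes"),
                   placed = placed, stringsAsFactors = FALSE)
  df$end <- df$start + nchar(df$seq)
  df <- df[order(!df$placed, df$start), ]
  pl <- df[df$placed, , drop = FALSE]
  overlaps <- NULL
  if (nrow(pl) > 1L) {
    overlaps <- c(pl$end[-nrow(pl)] - pl$start[-1L],
                  pl$end[nrow(pl)] - (pl$start[1L] + L))
  } else if (nrow(pl) == 1L) {
    overlaps <- max(0L, pl$end[1L] - (pl$start[1L] + L))
  }
  structure(df[, c("id", "seq", "start", "end", "strand", "votes", "placed")],
            class = c("contig_layout", "data.frame"),
            reference_length = L, overlaps = overlaps)
}

.BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)
.BIT_CODE <- c("N", "A", "C", "M", "G", "R", "S", "V",
               "T", "W", "Y", "H", "K", "D", "B", "N")  # index = bits + 1

#' Collapse an anchored layout into a draft consensus
#'
#' Overlapping contig bases that agree pass through; disagreements become the
#' minimal IUPAC code covering the observed bases; reference positions covered
#' by no contig are emitted as N and reported as gaps.
#'
#' @param layout a `contig_layout` from [anchor_layout()]
#' @return draft consensus string of reference length, with attributes
#'   `depth` (contigs covering each position) and `gaps` (data.frame of
#'   0-based half-open uncovered intervals)
#' @export
collapse_layout <- function(layout) {
  L <- attr(layout, "reference_length")
  bits <- integer(L)
  depth <- integer(L)
  pl <- layout[layout$placed, , drop = FALSE]
  for (i in seq_len(nrow(pl))) {
    len <- min(nchar(pl$seq[i]), L)
    pos <- ((pl$start[i] + seq_len(len) - 1L) %% L) + 1L
    bb <- unname(.BITS[strsplit(substr(pl$seq[i], 1L, len), "")[[1]]])
    bb[is.na(bb)] <- 15L                          # IUPAC in contig -> N-ish
    bits[pos] <- bitwOr(bits[pos], bb)
    depth[pos] <- depth[pos] + 1L
  }
  cons <- .BIT_CODE[bits + 1L]
  uncov <- depth == 0L
  gaps <- NULL
  if (any(uncov)) {
    r <- rle(uncov)
    e <- cumsum(r$lengths); s <- e - r$lengths
    gaps <- data.frame(start = s[r$values], end = e[r$values])
  }
  structure(paste(cons, collapse = ""), depth = depth,
            gaps = gaps %||% data.frame(start = integer(), end = integer()))
}

#' Polish a draft genome by majority vote of mapped reads
#'
#' Reads are placed on the (circular) draft by exact seed match (`k_map`-mer)
#' and ungapped extension; at every position, if a strict majority (> 50%) of
#' covering reads carries a base different from the draft, the draft base is
#' replaced.  IUPAC ambiguity codes in the draft are resolved to the most
#' common covering base.  Ties keep the draft base; zero-coverage positions
#' are left unchanged and flagged.
#'
#' @param draft draft sequence (string, may contain IUPAC codes)
#' @param reads a `read_multiset` or character vector of reads
#' @param k_map seed length for exact-match placement (default 31)
#' @param max_iter number of polishing passes (default 1)
#' @return object of class `polished_genome`: list(seq, depth, corrected,
#'   zero_coverage, n_corrected)
#' @export
polish <- function(draft, reads, k_map = 31L, max_iter = 1L) {
  seqs <- if (inherits(reads, "read_multiset")) read_sequences(reads) else reads
  total_corr <- 0L
  corrected_all <- rep(FALSE, nchar(draft))
  for (iter in seq_len(max_iter)) {
    res <- .polish_once(draft, seqs, k_map)
    draft <- res$seq
    corrected_all <- corrected_all | res$corrected
    total_corr <- total_corr + sum(res$corrected)
    if (!sum(res$corrected)) break
  }
  structure(list(seq = draft, depth = res$depth, corrected = corrected_all,
                 zero_coverage = res$depth == 0L, n_corrected = total_corr),
            class = "polished_genome")
}

.polish_once <- function(draft, seqs, k_map) {
  L <- nchar(draft)
  rl <- nchar(seqs[1])
  dbl <- substr_circ(draft, 0L, L + rl - 1L)      # wrap margin for circular reads
  dk <- seq_kmers(dbl, k_map)
  offs <- unique(pmin(c(0L, k_map, 2L * k_map), max(rl - k_map, 0L)))
  start <- rep(NA_integer_, length(seqs))
  strand <- rep(NA_integer_, length(seqs))
  rc <- revcomp(seqs)
  for (off in offs) {
    for (st in 1:2) {
      s <- if (st == 1L) seqs else rc
      need <- is.na(start)
      if (!any(need)) break
      key <- substr(s[need], off + 1L, off + k_map)
      hit <- match(key, dk)
      got <- !is.na(hit)
      idx <- which(need)[got]
      start[idx] <- hit[got] - off                # 1-based on dbl
      strand[idx] <- st
    }
  }
  mapped <- which(!is.na(start) & start >= 1L)
  cnt <- matrix(0L, 4L, L, dimnames = list(DNA, NULL))
  if (length(mapped)) {
    oriented <- ifelse(strand[mapped] == 1L, seqs[mapped], rc[mapped])
    pos <- unlist(lapply(mapped, function(i) start[i] + 0:(rl - 1L)),
                  use.names = FALSE)
    pos <- ((pos - 1L) %% L) + 1L
    bas <- unlist(strsplit(oriented, ""), use.names = FALSE)
    keep <- bas %in% DNA
    pos <- pos[keep]; bas <- bas[keep]
    for (b in DNA) cnt[b, ] <- tabulate(pos[bas == b], L)
  }
  depth <- colSums(cnt)
  maj_i <- max.col(t(cnt), ties.method = "first")
  maj <- DNA[maj_i]
  maj_n <- cnt[cbind(maj_i, seq_len(L))]
  dch <- strsplit(draft, "")[[1]]
  is_ambig <- !(dch %in% DNA)
  repl <- (depth > 0L) &
    ((maj_n > depth / 2 & maj != dch) | (is_ambig & maj_n > 0L))
  # strict-majority ties: when the top two counts are equal, keep the draft
  if (any(repl & !is_ambig)) {
    for (p in which(repl & !is_ambig)) {
      if (sum(cnt[, p] == maj_n[p]) > 1L) repl[p] <- FALSE
    }
  }
  out <- dch
  out[repl] <- maj[repl]
  list(seq = paste(out, collapse = ""), depth = depth, corrected = repl)
}
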