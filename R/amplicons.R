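#' Build a variant-masked consensus from aligned genomes
#'
#' Per alignment column: the majority base, a variant flag (two or more
#' distinct unambiguous bases observed), and a gap flag.  Variant and gap
#' columns are excluded from primer footprints, as flagged by the scanner.
#'
#' @param alignment named character vector of >= 2 aligned sequences of equal
#'   length (gaps as `-`), or a character matrix (taxa x columns)
#' @return object of class `masked_consensus`: list(seq, variant, gapcol)
#' @export
build_masked_consensus <- function(alignment) {
  if (is.character(alignment) && is.null(dim(alignment))) {
    if (length(alignment) < 2L) stop("need at least two aligned sequences")
    if (length(unique(nchar(alignment))) != 1L)
      stop("aligned sequences must have equal length")
    m <- do.call(rbind, strsplit(toupper(alignment), ""))
  } else {
    m <- toupper(alignment)
    if (nrow(m) < 2L) stop("need at least two aligned sequences")
  }
  ncolumns <- ncol(m)
  variant <- logical(ncolumns); gapcol <- logical(ncolumns)
  cons <- character(ncolumns)
  for (j in seq_len(ncolumns)) {
    col <- m[, j]
    gapcol[j] <- any(col == "-")
    bases <- col[col %in% DNA]
    if (!length(bases)) { cons[j] <- "N"; variant[j] <- TRUE; next }
    tab <- sort(table(bases), decreasing = TRUE)
    cons[j] <- names(tab)[1L]
    variant[j] <- length(tab) >= 2L
  }
  variant <- variant | gapcol
  structure(list(seq = paste(cons, collapse = ""), variant = variant,
                 gapcol = gapcol, n_col = ncolumns),
            class = "masked_consensus")
}

#' @export
print.masked_consensus <- function(x, ...) {
  cat("masked_consensus:", x$n_col, "columns,", sum(x$variant),
      "variant/gap columns masked\n")
  invisible(x)
}

# SantaLucia (1998) unified nearest-neighbor parameters
.NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
            GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
            TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0)
.NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
            TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
            CC = -19.9)

#' Oligo melting temperature
#'
#' Nearest-neighbor Tm (SantaLucia 1998 unified parameters, 1 M -> `na_mM`
#' entropic salt correction, non-self-complementary duplex), or the Wallace
#' rule for a quick estimate.
#'
#' @param seq primer sequence(s)
#' @param method "nn" (nearest neighbor) or "wallace"
#' @param primer_conc molar primer concentration (default 250 nM)
#' @param na_mM monovalent cation concentration in mM (default 50)
#' @return Tm in degrees C (vectorized)
#' @export
primer_tm <- function(seq, method = c("nn", "wallace"),
                      primer_conc = 2.5e-7, na_mM = 50) {
  method <- match.arg(method)
  seq <- toupper(seq)
  if (method == "wallace") {
    ch <- strsplit(seq, "")
    return(vapply(ch, function(x) 2 * sum(x %in% c("A", "T")) +
                    4 * sum(x %in% c("G", "C")), 0))
  }
  vapply(seq, function(s) {
    n <- nchar(s)
    steps <- substring(s, 1:(n - 1L), 2:n)
    dh <- sum(.NN_DH[steps]) * 1000           # cal/mol
    ds <- sum(.NN_DS[steps])
    ends <- substring(s, c(1L, n), c(1L, n))
    for (e in ends) {
      if (e %in% c("G", "C")) { dh <- dh + 100;  ds <- ds - 2.8 }
      else                    { dh <- dh + 2300; ds <- ds + 4.1 }
    }
    ds <- ds + 0.368 * (n - 1L) * log(na_mM / 1000)
    dh / (ds + 1.987 * log(primer_conc / 4)) - 273.15
  }, 0, USE.NAMES = FALSE)
}

#' Scan a masked consensus for admissible primer sites
#'
#' Enumerates all circular windows in the length range on both strands and
#' keeps those satisfying the variant constraints (at most `max_variants`
#' masked columns in the footprint, none within the 3'-terminal
#' `three_prime_clean` bases, no gap columns), plus melting-temperature and
#' GC-content ranges.  Masked columns are excluded from the GC fraction;
#' Tm is computed on the majority-base sequence of the footprint.
#'
#' @param consensus a [build_masked_consensus()] result
#' @param tm_range admissible Tm range in degrees C
#' @param gc_range admissible GC fraction range
#' @param len_range primer length range in bp
#' @param max_variants maximum masked columns per footprint (default 2)
#' @param three_prime_clean number of 3'-terminal bases that must be
#'   variant-free (default 3)
#' @return data.frame of class `primer_sites`: start (0-based), length,
#'   strand, end, seq, tm, gc, n_variants
#' @export
scan_primer_sites <- function(consensus, tm_range = c(50, 66),
                              gc_range = c(0.20, 0.65),
                              len_range = c(18L, 27L),
                              max_variants = 2L, three_prime_clean = 3L) {
  L <- consensus$n_col
  ch <- strsplit(consensus$seq, "")[[1]]
  var <- as.numeric(consensus$variant)
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") ch else rev(c(A = "T", C = "G", G = "C", T = "A", N = "N")[ch])
    v <- if (strand == "+") var else rev(var)
    sd <- c(s, s); vd <- c(v, v)                   # circular doubling
    gc <- as.numeric(sd %in% c("G", "C")) * (1 - vd)
    cv <- cumsum(c(0, vd)); cg <- cumsum(c(0, gc))
    for (len in len_range[1]:len_range[2]) {
      starts <- seq_len(L)                         # 1-based on doubled strand
      nv <- cv[starts + len] - cv[starts]
      nt3 <- cv[starts + len] - cv[starts + len - three_prime_clean]
      ngc <- cg[starts + len] - cg[starts]
      gcf <- ifelse(len - nv > 0, ngc / (len - nv), 0)
      ok <- nv <= max_variants & nt3 == 0 & gcf >= gc_range[1] & gcf <= gc_range[2]
      if (!any(ok)) next
      w <- which(ok)
      seqs <- substring(paste(sd, collapse = ""), w, w + len - 1L)
      tm <- primer_tm(seqs)
      keep <- tm >= tm_range[1] & tm <= tm_range[2]
      if (!any(keep)) next
      w <- w[keep]
      # map back to forward-strand 0-based coordinates
      if (strand == "+") {
        start0 <- w - 1L
      } else {
        start0 <- (L - (w - 1L) - len) %% L        # 5' end position of the site on + strand
      }
      res[[length(res) + 1L]] <-
        data.frame(start = start0, length = len, strand = strand,
                   seq = seqs[keep], tm = tm[keep], gc = gcf[ok][keep],
                   n_variants = nv[ok][keep], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(start = integer(), length = integer(), strand = character(),
               seq = character(), tm = numeric(), gc = numeric(),
               n_variants = integer(), stringsAsFactors = FALSE)
  out$end <- (out$start + out$length) %% max(L, 1L)
  out <- out[order(out$start, out$strand, out$length), ]
  rownames(out) <- NULL
  structure(out, class = c("primer_sites", "data.frame"), genome_length = L)
}

#' Design a circular tiling of overlapping long-range amplicons
#'
#' Depth-first search with backtracking over admissible primer sites, aiming
#' for `n_target` amplicons whose products lie in `product_range` and whose
#' consecutive products overlap by at least `min_overlap`, closing the circle.
#' If no `n_target`-amplicon scheme exists, the feasible scheme with count
#' closest to `n_target` is returned with a warning.
#'
#' @param sites a [scan_primer_sites()] result
#' @param genome_length circle length in bp
#' @param product_range amplicon length range in bp (default 2.0-3.5 kb)
#' @param min_overlap minimum overlap between consecutive amplicons (bp)
#' @param n_target target number of amplicons (default 7)
#' @param max_nodes DFS node budget per candidate count
#' @return object of class `amplicon_scheme`: data.frame (amplicon, fwd/rev
#'   primer start, length and sequence, product_start, product_end,
#'   product_length, overlap_with_next) with attribute `n_amplicons`;
#'   coordinates 0-based on the circle
#' @export
design_tiling <- function(sites, genome_length, product_range = c(2000L, 3500L),
                          min_overlap = 100L, n_target = 7L,
                          max_nodes = 100000L) {
  if (genome_length < product_range[1])
    stop("infeasible: genome (", genome_length,
         " bp) shorter than the minimum product size")
  fwd <- sites[sites$strand == "+", , drop = FALSE]
  rev <- sites[sites$strand == "-", , drop = FALSE]
  if (!nrow(fwd) || !nrow(rev))
    stop("infeasible: no admissible primer sites on both strands")
  L <- genome_length
  pmin <- product_range[1]; pmax <- product_range[2]
  fst <- fwd$start                               # product left edges
  ren <- (rev$start + rev$length)                # product right edges (exclusive)

  # unwrapped candidates >= lo for a circular coordinate set
  unwrap <- function(x, lo) x + L * ceiling((lo - x) / L)

  nodes <- 0L
  dfs <- function(x_cur, depth, m, s0) {
    nodes <<- nodes + 1L
    if (nodes > max_nodes) return(NULL)
    y_cand <- unwrap(ren, x_cur + pmin)
    keep <- which(y_cand <= x_cur + pmax)
    if (depth == m) {
      need <- s0 + L + min_overlap               # close the circle
      keep <- keep[y_cand[keep] >= need]
      if (!length(keep)) return(NULL)
      r <- keep[which.min(y_cand[keep])]
      return(list(rid = r, y = y_cand[r]))
    }
    ideal_y <- x_cur + (s0 + L + min_overlap - x_cur) / (m - depth + 1L) + min_overlap
    keep <- keep[order(abs(y_cand[keep] - ideal_y))]
    for (r in keep) {
      y <- y_cand[r]
      x_cand <- unwrap(fst, x_cur + 1L)
      fkeep <- which(x_cand <= y - min_overlap & x_cand < s0 + L)
      if (!length(fkeep)) next
      # prune: remaining amplicons must be able to reach the closure point
      reach <- x_cand[fkeep] + pmax + (m - depth - 1L) * (pmax - min_overlap)
      fkeep <- fkeep[reach >= s0 + L + min_overlap]
      if (!length(fkeep)) next
      ideal_x <- y - min_overlap
      fkeep <- fkeep[order(abs(x_cand[fkeep] - ideal_x))]
      for (f in fkeep) {
        sub <- dfs(x_cand[f], depth + 1L, m, s0)
        if (!is.null(sub))
          return(list(rid = r, y = y, fid = f, x = x_cand[f], nxt = sub))
        if (nodes > max_nodes) return(NULL)
      }
    }
    NULL
  }

  try_count <- function(m) {
    if (pmax + (m - 1L) * (pmax - min_overlap) < L + min_overlap)
      return(NULL)                                 # cannot span the circle
    if ((m - 1L) * 1L + pmin > 2L * L + pmax) return(NULL)
    for (a1 in order(fst)) {
      nodes <<- 0L
      sol <- dfs(fst[a1], 1L, m, fst[a1])
      if (!is.null(sol)) return(list(first = a1, chain = sol))
    }
    NULL
  }

  m_max <- max(3L, ceiling(L / max(1L, pmin - min_overlap)) + 2L)
  m_try <- n_target + c(0L, as.vector(rbind(seq_len(m_max), -seq_len(m_max))))
  m_try <- unique(m_try[m_try >= 2L & m_try <= m_max + n_target])
  found <- NULL; m_used <- NA_integer_
  for (m in m_try) {
    found <- try_count(m)
    if (!is.null(found)) { m_used <- m; break }
  }
  if (is.null(found))
    stop("infeasible: no circular tiling satisfies the product/overlap ",
         "constraints with the available primer sites")
  if (m_used != n_target)
    warning("no ", n_target, "-amplicon scheme found; returning ", m_used,
            " amplicons")

  fids <- found$first
  rids <- integer(0); xs <- fst[found$first]; ys <- numeric(0)
  node <- found$chain
  while (!is.null(node)) {
    rids <- c(rids, node$rid); ys <- c(ys, node$y)
    if (!is.null(node$fid)) { fids <- c(fids, node$fid); xs <- c(xs, node$x) }
    node <- node$nxt
  }
  nm <- length(fids)
  s0 <- xs[1]
  ov <- c(ys[-nm] - xs[-1], ys[nm] - (s0 + L))
  df <- data.frame(amplicon = seq_len(nm),
                   fwd_start = xs %% L, fwd_len = fwd$length[fids],
                   fwd_seq = fwd$seq[fids],
                   rev_start = rev$start[rids], rev_len = rev$length[rids],
                   rev_seq = rev$seq[rids],
                   product_start = xs %% L, product_end = ys %% L,
                   product_length = as.integer(ys - xs),
                   overlap_with_next = as.integer(ov),
                   stringsAsFactors = FALSE)
  structure(df, class = c("amplicon_scheme", "data.frame"),
            n_amplicons = nm, genome_length = L, circular = TRUE)
}

#' @export
print.amplicon_scheme <- function(x, ...) {
  cat("amplicon_scheme:", attr(x, "n_amplicons"), "amplicons tiling a",
      attr(x, "genome_length"), "bp circle\n")
  print.data.frame(x[, c("amplicon", "product_start", "product_end",
                         "product_length", "overlap_with_next")])
  invisible(x)
}

#' Verify an amplicon scheme against its constraint system
#'
#' Re-checks product sizes, minimum overlaps and full circular coverage.
#'
#' @param scheme an [design_tiling()] result
#' @param product_range,min_overlap the constraints to verify against
#' @return TRUE invisibly, or an error describing the violated constraint
#' @export
verify_scheme <- function(scheme, product_range = c(2000L, 3500L),
                          min_overlap = 100L) {
  L <- attr(scheme, "genome_length")
  if (any(scheme$product_length < product_range[1] |
          scheme$product_length > product_range[2]))
    stop("product length outside range")
  cov <- logical(L)
  for (i in seq_len(nrow(scheme))) {
    pos <- (scheme$product_start[i] + seq_len(scheme$product_length[i]) - 1L) %% L + 1L
    cov[pos] <- TRUE
  }
  if (!all(cov)) stop("scheme does not cover the full circle")
  if (any(scheme$overlap_with_next < min_overlap))
    stop("overlap below minimum")
  invisible(TRUE)
}
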