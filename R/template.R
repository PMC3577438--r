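#' @include utils.R
NULL

#' Canonical mosquito mitogenome template
#'
#' Builds the annotation template used by the simulator: the ancestral insect
#' mitochondrial gene order (as in *Anopheles gambiae*) with 13 protein-coding
#' genes, 2 rRNAs, 22 tRNAs and a control region laid out contiguously on a
#' circle of ~15.3 kb.  Coordinates are 0-based half-open; protein-coding gene
#' lengths are divisible by 3 (a complete stop codon is included in each CDS).
#'
#' @param control_region_length length of the AT-rich control region in bp
#' @return an object of class `genome_template`: a data.frame of features
#'   (name, type, start, end, strand, length) with attribute `genome_length`
#' @export
genome_template <- function(control_region_length = 500L) {
  f <- function(name, type, len, strand = "+") {
    data.frame(name = name, type = type, length = as.integer(len),
               strand = strand, stringsAsFactors = FALSE)
  }
  feats <- rbind(
    f("trnI", "tRNA", 69), f("trnQ", "tRNA", 69, "-"), f("trnM", "tRNA", 69),
    f("ND2", "CDS", 1026), f("trnW", "tRNA", 68), f("trnC", "tRNA", 66, "-"),
    f("trnY", "tRNA", 67, "-"), f("COX1", "CDS", 1536), f("trnL2", "tRNA", 71),
    f("COX2", "CDS", 687), f("trnK", "tRNA", 71), f("trnD", "tRNA", 68),
    f("ATP8", "CDS", 159), f("ATP6", "CDS", 678), f("COX3", "CDS", 786),
    f("trnG", "tRNA", 65), f("ND3", "CDS", 354), f("trnA", "tRNA", 67),
    f("trnR", "tRNA", 65), f("trnN", "tRNA", 66), f("trnS1", "tRNA", 67),
    f("trnE", "tRNA", 66), f("trnF", "tRNA", 66, "-"), f("ND5", "CDS", 1719, "-"),
    f("trnH", "tRNA", 65, "-"), f("ND4", "CDS", 1341, "-"),
    f("ND4L", "CDS", 297, "-"), f("trnT", "tRNA", 65), f("trnP", "tRNA", 66, "-"),
    f("ND6", "CDS", 522), f("CYTB", "CDS", 1137), f("trnS2", "tRNA", 68),
    f("ND1", "CDS", 942, "-"), f("trnL1", "tRNA", 65, "-"),
    f("rrnL", "rRNA", 1320, "-"), f("trnV", "tRNA", 72, "-"),
    f("rrnS", "rRNA", 789, "-"),
    f("CR", "control", as.integer(control_region_length))
  )
  feats$end <- cumsum(feats$length)
  feats$start <- feats$end - feats$length
  feats <- feats[, c("name", "type", "start", "end", "strand", "length")]
  total <- sum(feats$length)
  stopifnot(all(feats$length[feats$type == "CDS"] %% 3L == 0L),
            sum(feats$type == "CDS") == 13L,
            sum(feats$type == "tRNA") == 22L,
            sum(feats$type == "rRNA") == 2L)
  structure(feats, class = c("genome_template", "data.frame"),
            genome_length = total)
}

#' @export
print.genome_template <- function(x, ...) {
  cat("genome_template:", attr(x, "genome_length"), "bp,",
      sum(x$type == "CDS"), "CDS /", sum(x$type == "tRNA"), "tRNA /",
      sum(x$type == "rRNA"), "rRNA features\n")
  invisible(x)
}

# stop codons of the invertebrate mitochondrial code (TGA is Trp, AGA/AGG Ser)
MT_STOPS <- c("TAA", "TAG")

ALL_CODONS <- as.vector(outer(outer(DNA, DNA, paste0), DNA, paste0))
SENSE_CODONS <- setdiff(ALL_CODONS, MT_STOPS)

#' Simulate a root mitogenome from a template
#'
#' Protein-coding genes are built from random sense codons (invertebrate
#' mitochondrial code), opened with ATG and closed with TAA, so translation of
#' any simulated CDS never hits an internal stop.  Non-coding features are
#' drawn from the supplied base frequencies (AT-rich by default, as in insect
#' mitochondria).
#'
#' @param template a [genome_template()]
#' @param freqs base frequencies for non-coding sequence
#' @param taxon taxon label
#' @return an object of class `mitogenome`: list(seq, template, taxon)
#' @export
simulate_root_genome <- function(template,
                                 freqs = c(A = 0.40, C = 0.11, G = 0.09, T = 0.40),
                                 taxon = "root") {
  L <- attr(template, "genome_length")
  chars <- sample(DNA, L, replace = TRUE, prob = freqs)
  for (i in which(template$type == "CDS")) {
    len <- template$length[i]
    ncod <- len %/% 3L
    cds <- c("ATG",
             sample(SENSE_CODONS, ncod - 2L, replace = TRUE),
             "TAA")
    cds <- paste(cds, collapse = "")
    if (template$strand[i] == "-") cds <- revcomp(cds)
    chars[(template$start[i] + 1L):template$end[i]] <- strsplit(cds, "")[[1]]
  }
  mitogenome(paste(chars, collapse = ""), template, taxon)
}

#' Construct a mitogenome object
#' @param seq circular nucleotide sequence (string)
#' @param template optional [genome_template()] annotation
#' @param taxon taxon label
#' @return object of class `mitogenome`
#' @export
mitogenome <- function(seq, template = NULL, taxon = "genome") {
  stopifnot(is.character(seq), length(seq) == 1L)
  structure(list(seq = toupper(seq), template = template, taxon = taxon),
            class = "mitogenome")
}

#' @export
print.mitogenome <- function(x, ...) {
  cat("mitogenome '", x$taxon, "': ", nchar(x$seq), " bp (circular)\n", sep = "")
  invisible(x)
}

#' Extract the coding sequence of one gene from a mitogenome
#'
#' Minus-strand genes are returned reverse-complemented (coding orientation).
#'
#' @param genome a `mitogenome` with a template
#' @param gene gene name as in the template
#' @return CDS string in coding orientation
#' @export
gene_cds <- function(genome, gene) {
  tm <- genome$template
  stopifnot(!is.null(tm))
  i <- match(gene, tm$name)
  if (is.na(i)) stop("gene not in template: ", gene)
  s <- substr(genome$seq, tm$start[i] + 1L, tm$end[i])
  if (tm$strand[i] == "-") s <- revcomp(s)
  s
}
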