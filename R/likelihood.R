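# --- site patterns and tip partial likelihoods -------------------------------

# seqs: named character vector of equal-length sequences (taxa order = tips)
# returns list(tipp = 4 x npat x ntip array, w = pattern weights)
.site_patterns <- function(seqs, taxa) {
  m <- do.call(rbind, strsplit(toupper(unname(seqs[taxa])), ""))
  key <- apply(m, 2, paste0, collapse = "")
  tab <- table(key)
  upat <- names(tab)
  ntip <- length(taxa); npat <- length(upat)
  pm <- do.call(rbind, strsplit(upat, ""))
  tipp <- array(1, dim = c(4, npat, ntip))
  for (t in seq_len(ntip)) {
    for (b in unique(pm[, t])) {
      sel <- which(pm[, t] == b)
      v <- rep(0, 4)
      set <- IUPAC_SETS[[b]]
      if (is.null(set)) v <- rep(1, 4) else v[match(set, DNA)] <- 1
      tipp[, sel, t] <- v
    }
  }
  list(tipp = tipp, w = as.numeric(tab))
}

.part_payload <- function(tipp, w, model, relrate = 1) {
  list(tipp = as.numeric(tipp), w = w,
       U = as.numeric(model$eigen$U), Uinv = as.numeric(model$eigen$Uinv),
       lam = as.numeric(model$eigen$values), pi = as.numeric(model$freqs),
       rates = as.numeric(model$rates),
       rwts = as.numeric(model$rate_weights), relrate = relrate)
}

# postorder edge matrix of a rooted phylo
.postorder_edges <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  list(edge = tr$edge, edge.length = tr$edge.length)
}

#' Phylogenetic log-likelihood by Felsenstein pruning
#'
#' Likelihood of an alignment on a rooted tree with branch lengths in
#' substitutions/site, under a reversible model with discrete-gamma rate
#' variation, computed over unique site patterns.  With a `supermatrix` and
#' `partition = "srd06"` the codon-position classes 1+2 and 3 get independent
#' models and a relative rate for class 3, and the partition log-likelihoods
#' are summed.
#'
#' @param x named character vector of aligned sequences, or a `supermatrix`
#' @param tree rooted binary `phylo`; tip labels must match sequence names
#' @param model a [subst_model()], or for `partition = "srd06"` a list of two
#'   models (classes 1+2 and 3)
#' @param partition "none" or "srd06"
#' @param rate3 relative rate of codon-position class 3 (srd06 only)
#' @return log-likelihood (numeric scalar)
#' @export
log_likelihood <- function(x, tree, model, partition = c("none", "srd06"),
                           rate3 = 1) {
  partition <- match.arg(partition)
  if (any(.postorder_edges(tree)$edge.length < 0))
    stop("negative branch length")
  if (inherits(x, "supermatrix")) seqs <- x$seqs else seqs <- x
  if (!all(tree$tip.label %in% names(seqs)))
    stop("tree tips not found in alignment")
  po <- .postorder_edges(tree)
  ntip <- length(tree$tip.label)
  if (partition == "none") {
    sp <- .site_patterns(seqs, tree$tip.label)
    return(C_pruning_loglik(po$edge, ntip, po$edge.length,
                            .part_payload(sp$tipp, sp$w, model)))
  }
  if (!inherits(x, "supermatrix")) stop("srd06 partitioning needs a supermatrix")
  models <- if (inherits(model, "subst_model")) list(model, model) else model
  cls <- x$classes
  ll <- 0
  for (i in 1:2) {
    keep <- which(cls == c("12", "3")[i])
    sub <- vapply(seqs, function(s)
      paste(strsplit(s, "")[[1]][keep], collapse = ""), "")
    sp <- .site_patterns(sub, tree$tip.label)
    ll <- ll + C_pruning_loglik(po$edge, ntip, po$edge.length,
                                .part_payload(sp$tipp, sp$w, models[[i]],
                                              if (i == 2) rate3 else 1))
  }
  ll
}
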