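#' Model-corrected pairwise distances from an alignment
#'
#' Closed-form corrected distances (TN93 by default, optionally with a gamma
#' rate-variation correction), with pairwise deletion of gap/ambiguity sites.
#' Saturated pairs (undefined correction) are capped with a warning.
#'
#' Alternatively, `model = "ML"` computes each pairwise distance by numerical
#' maximum likelihood under a full [subst_model()] (including discrete-gamma
#' rate variation), which avoids the over-correction of the continuous-gamma
#' closed form on data whose rate variation is itself discrete.
#'
#' @param x a `supermatrix` or named character vector of aligned sequences
#' @param model distance model: "TN93", "JC69", "K80", "raw", or "ML"
#' @param alpha gamma shape for rate-variation correction (NULL = none;
#'   closed-form models only)
#' @param cap distance assigned to saturated pairs
#' @param subst a [subst_model()] used when `model = "ML"`
#' @return symmetric matrix of distances (substitutions/site), class
#'   `distance_matrix`
#' @export
pairwise_distances <- function(x, model = "TN93", alpha = NULL, cap = 5,
                               subst = NULL) {
  seqs <- if (inherits(x, "supermatrix")) x$seqs else x
  if (length(seqs) < 2) stop("need >= 2 taxa")
  if (model == "ML") {
    if (is.null(subst)) stop("model = 'ML' needs a subst_model")
    n <- length(seqs)
    m <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- .ml_distance(seqs[c(i, j)], subst, cap)
    }
    return(structure(m, class = c("distance_matrix", class(m))))
  }
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(seqs), "")))
  d <- ape::dist.dna(bin, model = model,
                     gamma = if (is.null(alpha)) FALSE else alpha,
                     pairwise.deletion = TRUE)
  m <- as.matrix(d)
  # identical pairs are distance 0 even when base-frequency terms degenerate
  p <- as.matrix(ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE))
  m[p == 0] <- 0
  bad <- !is.finite(m)
  if (any(bad)) {
    warning(sum(bad & upper.tri(m)), " saturated pair(s) capped at ", cap)
    m[bad] <- cap
  }
  diag(m) <- 0
  structure(m, class = c("distance_matrix", class(m)))
}

# two-sequence ML distance under a subst_model (pruning kernel on a cherry)
.ml_distance <- function(pair, model, cap = 5) {
  tr <- structure(list(edge = matrix(c(3L, 3L, 1L, 2L), 2L),
                       edge.length = c(0.5, 0.5),
                       tip.label = names(pair), Nnode = 1L),
                  class = "phylo", order = "cladewise")
  f <- function(t) {
    tr$edge.length <- c(t / 2, t / 2)
    log_likelihood(pair, tr, model)
  }
  opt <- optimize(f, c(0, cap), maximum = TRUE, tol = 1e-7)
  if (opt$maximum > cap * 0.99) {
    warning("saturated pair capped at ", cap)
    return(cap)
  }
  opt$maximum
}

#' Neighbor-joining tree with outgroup rooting
#'
#' Standard NJ on a distance matrix, rooted on the branch leading to the
#' outgroup's most recent common ancestor.  A non-monophyletic outgroup
#' triggers a warning and the tree is rooted at the outgroup attachment.
#'
#' @param D a `distance_matrix` (or any symmetric matrix / `dist`)
#' @param outgroup character vector of outgroup taxa (NULL = unrooted)
#' @return a `phylo` (rooted when an outgroup is given)
#' @export
nj_tree <- function(D, outgroup = NULL) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (nrow(D) < 3) stop("need >= 3 taxa for neighbor joining")
  phy <- ape::nj(stats::as.dist(D))
  if (is.null(outgroup)) return(phy)
  if (!all(outgroup %in% phy$tip.label)) stop("outgroup taxa not in matrix")
  if (!ape::is.monophyletic(phy, outgroup)) {
    warning("outgroup is not monophyletic; rooting at its attachment point")
    return(ape::root(phy, outgroup = outgroup[1], resolve.root = TRUE))
  }
  ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
}

#' Divergence time from a corrected distance under a fixed clock rate
#'
#' TMRCA = d / (2 mu): the two lineages each accumulate mu substitutions per
#' site per my, so a corrected pairwise distance d corresponds to a divergence
#' d / (2 mu) million years ago.  The default rate is the insect mitochondrial
#' rate of 0.0115 substitutions/site/my.
#'
#' @param d corrected pairwise distance(s), substitutions/site
#' @param mu clock rate in substitutions/site/my
#' @return TMRCA in mya (vectorized)
#' @export
rate_date <- function(d, mu = 0.0115) {
  if (mu <= 0) stop("mu must be positive")
  if (any(d < 0)) stop("distances must be non-negative")
  d / (2 * mu)
}
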