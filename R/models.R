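#' Nucleotide substitution model
#'
#' Reversible substitution models (JC69, HKY, GTR) with optional discrete
#' gamma rate variation.  The rate matrix is scaled to one expected
#' substitution per site per unit branch length, so branch lengths are in
#' substitutions/site.
#'
#' @param family one of "JC69", "HKY", "GTR"
#' @param freqs equilibrium base frequencies (A, C, G, T); must sum to 1
#' @param kappa transition/transversion rate ratio (HKY)
#' @param rates six GTR exchangeabilities in order AC, AG, AT, CG, CT, GT
#' @param alpha gamma shape for among-site rate variation (NULL = no gamma)
#' @param ncat number of discrete gamma categories
#' @return object of class `subst_model` with elements `Q`, `eigen`
#'   (decomposition for computing transition probabilities), `rates`/`rate_weights`
#' @export
subst_model <- function(family = c("HKY", "JC69", "GTR"),
                        freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                        kappa = 2, rates = rep(1, 6),
                        alpha = NULL, ncat = 4L) {
  family <- match.arg(family)
  freqs <- freqs / sum(freqs)
  if (any(freqs <= 0)) stop("frequencies must be positive")
  if (family == "JC69") freqs <- rep(0.25, 4)
  ex <- switch(family,
    JC69 = rep(1, 6),
    HKY  = { if (kappa <= 0) stop("kappa must be positive")
             c(1, kappa, 1, 1, kappa, 1) },
    GTR  = { if (length(rates) != 6 || any(rates <= 0)) stop("need 6 positive rates")
             rates })
  Q <- matrix(0, 4, 4, dimnames = list(DNA, DNA))
  idx <- rbind(c(1,2), c(1,3), c(1,4), c(2,3), c(2,4), c(3,4))
  for (m in 1:6) {
    i <- idx[m,1]; j <- idx[m,2]
    Q[i,j] <- ex[m] * freqs[j]
    Q[j,i] <- ex[m] * freqs[i]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q <- Q / mu
  # symmetrized eigendecomposition (reversible): B = D^1/2 Q D^-1/2 symmetric
  d <- sqrt(freqs)
  B <- diag(d) %*% Q %*% diag(1 / d)
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  U <- diag(1 / d) %*% eg$vectors
  Uinv <- t(eg$vectors) %*% diag(d)
  if (!is.null(alpha)) {
    if (alpha <= 0) stop("alpha must be positive")
    r <- discrete_gamma(alpha, ncat)
  } else r <- 1
  structure(list(family = family, freqs = freqs, kappa = kappa,
                 exchangeability = ex, Q = Q, alpha = alpha, ncat = ncat,
                 eigen = list(values = eg$values, U = U, Uinv = Uinv),
                 rates = r, rate_weights = rep(1 / length(r), length(r))),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat("subst_model:", x$family,
      if (!is.null(x$alpha)) sprintf("+G (alpha=%.3g, %d cats)", x$alpha, x$ncat),
      "\n")
  invisible(x)
}

#' Mean rates of equal-probability discrete gamma categories
#'
#' Standard mean-per-category discretization of a Gamma(alpha, alpha)
#' distribution (mean 1).
#'
#' @param alpha shape parameter
#' @param ncat number of categories
#' @return numeric vector of `ncat` relative rates with mean 1
#' @export
discrete_gamma <- function(alpha, ncat = 4L) {
  if (ncat == 1L) return(1)
  b <- qgamma(seq(0, 1, length.out = ncat + 1L), shape = alpha, rate = alpha)
  # E[X | b_i < X < b_{i+1}] via the incomplete-moment identity
  p <- pgamma(b, shape = alpha + 1, rate = alpha)
  r <- (p[-1] - p[-length(p)]) * ncat
  r / mean(r)
}

#' Transition probability matrix P(t) for a model
#' @param model a [subst_model()]
#' @param t branch length in substitutions/site
#' @return 4x4 matrix of transition probabilities
#' @export
transition_prob <- function(model, t) {
  eg <- model$eigen
  P <- eg$U %*% diag(exp(eg$values * t)) %*% eg$Uinv
  P[P < 0] <- 0
  P / rowSums(P)
}
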