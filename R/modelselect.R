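#' Fit one substitution model on a fixed topology by maximum likelihood
#'
#' Branch lengths and model parameters are optimized numerically (L-BFGS-B on
#' log-transformed parameters) with base frequencies fixed at their empirical
#' values (counted from the alignment).
#'
#' @param x alignment (named character vector or `supermatrix`)
#' @param tree rooted binary `phylo` with starting branch lengths
#' @param family "JC69", "HKY" or "GTR"
#' @param gamma fit discrete-gamma rate variation (4 categories)
#' @return list(family, gamma, logLik, k, AIC, model, tree, convergence)
#' @export
fit_model <- function(x, tree, family = "HKY", gamma = FALSE) {
  seqs <- if (inherits(x, "supermatrix")) x$seqs else x
  ch <- unlist(strsplit(seqs, ""), use.names = FALSE)
  emp <- table(factor(ch, levels = DNA))
  freqs <- setNames(as.numeric(emp) / sum(emp), DNA)
  nb <- nrow(tree$edge)
  b0 <- pmax(tree$edge.length, 1e-6)
  np_model <- switch(family, JC69 = 0L, HKY = 1L, GTR = 5L)
  np <- nb + np_model + gamma
  par0 <- c(log(b0),
            if (family == "HKY") log(2),
            if (family == "GTR") rep(0, 5),
            if (gamma) log(0.5))
  mk <- function(par) {
    kappa <- 2; rates <- rep(1, 6); alpha <- NULL
    i <- nb
    if (family == "HKY") { kappa <- exp(par[i + 1]); i <- i + 1 }
    if (family == "GTR") { rates <- c(exp(par[i + 1:5]), 1); i <- i + 5 }
    if (gamma) alpha <- exp(par[i + 1])
    subst_model(family, freqs = freqs, kappa = kappa, rates = rates,
                alpha = alpha)
  }
  tr <- tree
  nll <- function(par) {
    tr$edge.length <- exp(par[seq_len(nb)])
    ll <- try(log_likelihood(seqs, tr, mk(par)), silent = TRUE)
    if (inherits(ll, "try-error") || !is.finite(ll)) return(1e10)
    -ll
  }
  opt <- optim(par0, nll, method = "L-BFGS-B",
               lower = c(rep(log(1e-8), nb), rep(-6, np - nb)),
               upper = c(rep(log(10), nb), rep(6, np - nb)),
               control = list(maxit = 300))
  ntaxa <- length(tree$tip.label)
  k <- as.integer((2 * ntaxa - 3) + np_model + gamma +
    (if (family == "JC69") 0L else 3L))       # empirical frequencies
  ll <- -opt$value
  tr$edge.length <- exp(opt$par[seq_len(nb)])
  list(family = family, gamma = gamma, logLik = ll, k = k,
       AIC = 2 * k - 2 * ll, model = mk(opt$par), tree = tr,
       convergence = opt$convergence)
}

#' Select a substitution model by AIC
#'
#' Fits JC69, HKY, HKY+G, GTR and GTR+G on the fixed topology by maximum
#' likelihood and returns the minimum-AIC model.  AIC = 2k - 2 lnL with k the
#' free parameter count (branch lengths, exchangeabilities, empirical
#' frequencies, gamma shape).  Non-converged fits are flagged and excluded.
#'
#' @param x alignment (named character vector or `supermatrix`)
#' @param tree rooted binary `phylo` with starting branch lengths
#' @return list(best = name of the winning model, alpha = its gamma shape (or
#'   NULL), fits = data.frame of per-model logLik/k/AIC/converged, model = the
#'   winning [subst_model()])
#' @export
select_model <- function(x, tree) {
  cand <- list(JC69 = c("JC69", FALSE), HKY = c("HKY", FALSE),
               `HKY+G` = c("HKY", TRUE), GTR = c("GTR", FALSE),
               `GTR+G` = c("GTR", TRUE))
  fits <- lapply(cand, function(cf)
    fit_model(x, tree, family = cf[1], gamma = as.logical(cf[2])))
  df <- data.frame(model = names(cand),
                   logLik = vapply(fits, `[[`, 0, "logLik"),
                   k = vapply(fits, `[[`, 0L, "k"),
                   AIC = vapply(fits, `[[`, 0, "AIC"),
                   converged = vapply(fits, function(f) f$convergence == 0, TRUE))
  usable <- which(df$converged)
  if (!length(usable)) stop("no model fit converged")
  best <- usable[which.min(df$AIC[usable])]
  if (any(!df$converged))
    warning("excluded non-converged fits: ",
            paste(df$model[!df$converged], collapse = ", "))
  list(best = df$model[best], alpha = fits[[best]]$model$alpha,
       fits = df, model = fits[[best]]$model)
}
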