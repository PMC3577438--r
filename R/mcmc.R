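#' Strict-clock model specification
#' @param rate substitution rate in substitutions/site/my (default the insect
#'   mitochondrial rate 0.0115)
#' @param fixed if TRUE the rate is held constant; if FALSE it is sampled
#'   (requires a calibration prior for identifiability)
#' @param bounds admissible rate range when sampled
#' @return object of class `clock_model`
#' @export
clock_model <- function(rate = 0.0115, fixed = TRUE, bounds = c(1e-6, 1)) {
  if (rate <= 0) stop("rate must be positive")
  structure(list(mode = "strict", rate = rate, fixed = fixed, bounds = bounds),
            class = "clock_model")
}

#' Root-age calibration prior
#'
#' Normal prior on the root age.  The default matches a Drosophila-Anopheles
#' style calibration: mean 260 mya with sd 8.42 my, chosen so the central 95%
#' mass spans roughly 243-276 mya; `truncated = TRUE` additionally imposes
#' the bounds as hard truncation.
#'
#' @param mean prior mean (mya)
#' @param sd prior standard deviation (my)
#' @param bounds optional truncation bounds
#' @param truncated hard-truncate at `bounds`
#' @return object of class `calibration_prior`
#' @export
calibration_prior <- function(mean = 260, sd = 8.42, bounds = c(243, 276),
                              truncated = FALSE) {
  if (sd <= 0) stop("sd must be positive")
  if (!is.null(bounds) && (bounds[1] > mean || bounds[2] < mean))
    stop("bounds must bracket the mean")
  structure(list(node = "root", mean = mean, sd = sd, bounds = bounds,
                 truncated = truncated),
            class = "calibration_prior")
}

# initial internal-node ages: proportional to node height in edge steps
.init_ages <- function(tree, root_age0) {
  n <- length(tree$tip.label)
  nnode <- n + tree$Nnode
  h <- numeric(nnode)
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    h[p] <- max(h[p], h[ch] + 1)
  }
  ages <- root_age0 * h / h[n + 1L]
  ages[seq_len(n)] <- 0
  ages
}

#' Bayesian strict-clock divergence dating on a fixed topology
#'
#' Metropolis-Hastings sampling of internal node ages (and optionally the
#' clock rate) on a fixed rooted topology.  Node ages get a root-
#' scale-invariant order-constrained uniform prior, with an optional Normal
#' calibration prior on the root; the likelihood is the pruning likelihood
#' with branch length = rate x duration.  Proposals: uniform slides of
#' internal ages within their parent/child bounds, a log-scale root move and
#' (for a free rate) a log-scale rate move.  Multiple independent runs are
#' concatenated after burn-in.
#'
#' @param x alignment: named character vector or `supermatrix`
#' @param topology rooted binary `phylo` (branch lengths, if any, only seed
#'   the initial ages)
#' @param clock a [clock_model()]
#' @param calibration a [calibration_prior()] or NULL (diffuse uniform root)
#' @param model a [subst_model()] (or list of two for `partition = "srd06"`)
#' @param partition "none" or "srd06" (codon-position classes of a supermatrix)
#' @param rate3 relative rate of codon class 3 under srd06
#' @param iterations MCMC iterations per run
#' @param thin sampling interval
#' @param burnin burn-in fraction discarded from each run
#' @param runs number of independent runs (different seeds, combined)
#' @param seed integer seed
#' @param root_max upper bound of the uniform root prior (mya) when no
#'   calibration is given
#' @param likelihood_off sample from the prior only (prior-recovery checks)
#' @param root_delta,mu_delta proposal scales of the log-scale moves
#' @return object of class `posterior_trace`
#' @export
mcmc_date <- function(x, topology, clock = clock_model(),
                      calibration = NULL, model = subst_model("HKY"),
                      partition = c("none", "srd06"), rate3 = 1,
                      iterations = 200000L, thin = 100L, burnin = 0.10,
                      runs = 1L, seed = 1L, root_max = 1000,
                      likelihood_off = FALSE,
                      root_delta = 0.1, mu_delta = 0.1) {
  partition <- match.arg(partition)
  seqs <- if (inherits(x, "supermatrix")) x$seqs else x
  if (!all(topology$tip.label %in% names(seqs)))
    stop("topology tips not found in alignment")
  if (!clock$fixed && is.null(calibration))
    warning("free clock rate without a calibration prior is unidentifiable")
  ntip <- length(topology$tip.label)
  po <- .postorder_edges(topology)

  parts <- list()
  if (!likelihood_off) {
    if (partition == "srd06") {
      if (!inherits(x, "supermatrix")) stop("srd06 needs a supermatrix")
      models <- if (inherits(model, "subst_model")) list(model, model) else model
      for (i in 1:2) {
        keep <- which(x$classes == c("12", "3")[i])
        sub <- vapply(seqs, function(s)
          paste(strsplit(s, "")[[1]][keep], collapse = ""), "")
        sp <- .site_patterns(sub, topology$tip.label)
        parts[[i]] <- .part_payload(sp$tipp, sp$w, models[[i]],
                                    if (i == 2) rate3 else 1)
      }
    } else {
      sp <- .site_patterns(seqs, topology$tip.label)
      parts[[1]] <- .part_payload(sp$tipp, sp$w, model)
    }
  } else {
    # placeholder single-pattern partition; likelihood is switched off
    sp <- .site_patterns(setNames(rep("A", ntip), topology$tip.label),
                         topology$tip.label)
    parts[[1]] <- .part_payload(sp$tipp, sp$w, subst_model("JC69"))
  }

  if (!is.null(calibration)) {
    rp <- 1L; rmean <- calibration$mean; rsd <- calibration$sd
    rlb <- if (calibration$truncated) calibration$bounds[1] else 0
    rub <- if (calibration$truncated) calibration$bounds[2] else Inf
    root0 <- calibration$mean
  } else {
    rp <- 0L; rmean <- 0; rsd <- 1; rlb <- 0; rub <- Inf
    root0 <- if (!is.null(topology$edge.length) &&
                 all(topology$edge.length > 0)) {
      max(node_ages(topology))
    } else root_max / 10
    root0 <- min(max(root0, 1e-3), root_max * 0.9)
  }
  ages0 <- .init_ages(topology, root0)

  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, runs)
  traces <- vector("list", runs)
  for (r in seq_len(runs)) {
    set.seed(run_seeds[r])
    res <- C_mcmc_clock(po$edge, ntip, ages0, parts,
                        clock$rate, !clock$fixed,
                        clock$bounds[1], clock$bounds[2],
                        rp, rmean, rsd, rlb, rub, root_max,
                        !likelihood_off, as.integer(iterations),
                        as.integer(thin), root_delta, mu_delta)
    if (res$accepted == 0)
      stop("no proposal accepted; decrease root_delta/mu_delta or check data")
    s <- res$samples
    colnames(s) <- c(paste0("age_", ntip + seq_len(ntip - 1L)),
                     "mu", "loglik", "logprior")
    traces[[r]] <- list(samples = s,
                        acceptance = res$accepted / res$proposed)
  }
  structure(list(runs = traces, ntip = ntip, topology = topology,
                 iterations = iterations, thin = thin, burnin = burnin,
                 seed = seed, clock = clock, calibration = calibration),
            class = "posterior_trace")
}

#' @export
print.posterior_trace <- function(x, ...) {
  cat("posterior_trace:", length(x$runs), "run(s) x",
      nrow(x$runs[[1]]$samples), "samples (thin", x$thin, ", burn-in",
      x$burnin, ")\n")
  cat("acceptance:",
      paste(sprintf("%.2f", vapply(x$runs, `[[`, 0, "acceptance")),
            collapse = ", "), "\n")
  invisible(x)
}

#' Pooled post-burn-in samples of a posterior trace
#' @param trace a `posterior_trace`
#' @return matrix of samples (rows) by parameters (columns)
#' @export
trace_samples <- function(trace) {
  do.call(rbind, lapply(trace$runs, function(r) {
    n <- nrow(r$samples)
    drop_n <- floor(trace$burnin * n)
    r$samples[(drop_n + 1):n, , drop = FALSE]
  }))
}

#' Effective sample size by autocorrelation time
#'
#' ESS = n / (1 + 2 sum rho_k), summing autocorrelations by Geyer's initial
#' positive sequence criterion.
#'
#' @param x numeric vector of MCMC samples
#' @return effective sample size
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 4 || sd(x) == 0) return(if (sd(x) == 0) 0 else n)
  rho <- acf(x, lag.max = min(n - 2, 2000), plot = FALSE)$acf[-1]
  s <- 0
  k <- 1
  while (k < length(rho)) {
    g <- rho[k] + rho[k + 1]
    if (is.na(g) || g <= 0) break
    s <- s + g
    k <- k + 2
  }
  max(1, n / (1 + 2 * s))
}

#' Posterior node-age summaries
#'
#' Per-node posterior mean, central 95% credible interval (2.5% and 97.5%
#' quantiles, not HPD) and effective sample size over pooled post-burn-in
#' samples; warns when any ESS is at or below 200.
#'
#' @param trace a `posterior_trace`
#' @param min_samples minimum pooled sample count required
#' @return data.frame of class `node_summary`: node, mean, lower, upper, ess
#' @export
summarize_trace <- function(trace, min_samples = 100L) {
  s <- trace_samples(trace)
  if (!nrow(s)) stop("empty trace")
  if (nrow(s) < min_samples)
    stop("fewer than ", min_samples, " post-burn-in samples")
  cols <- grep("^age_|^mu$", colnames(s), value = TRUE)
  if (trace$clock$fixed) cols <- setdiff(cols, "mu")
  out <- data.frame(
    node = cols,
    mean = colMeans(s[, cols, drop = FALSE]),
    lower = apply(s[, cols, drop = FALSE], 2, quantile, 0.025),
    upper = apply(s[, cols, drop = FALSE], 2, quantile, 0.975),
    ess = apply(s[, cols, drop = FALSE], 2, ess),
    row.names = NULL)
  if (any(out$ess <= 200))
    warning("ESS <= 200 for: ", paste(out$node[out$ess <= 200], collapse = ", "))
  structure(out, class = c("node_summary", "data.frame"))
}

#' Posterior summary of the root age
#' @param trace a `posterior_trace`
#' @return one-row data.frame (mean, lower, upper, ess)
#' @export
root_age_summary <- function(trace) {
  su <- suppressWarnings(summarize_trace(trace))
  root_col <- paste0("age_", trace$ntip + 1L)
  su[su$node == root_col, c("mean", "lower", "upper", "ess")]
}
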