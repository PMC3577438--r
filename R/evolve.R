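#' Default simulation truth parameters
#'
#' Bundles the parameters governing strict-clock sequence simulation: the
#' per-lineage substitution rate (default the insect mitochondrial rate of
#' 0.0115 substitutions/site/my), the mitochondrial:nuclear copy ratio
#' (default 55-fold, the midpoint of the 50-60-fold coverage excess typical
#' of mosquito shotgun data), sequencing error rate and seed.
#'
#' @param mu substitution rate, substitutions/site/my
#' @param copy_ratio mitochondrial genome copies per nuclear copy (>= 1)
#' @param error_rate per-base sequencing error probability
#' @param seed integer seed
#' @param model a [subst_model()]; default HKY+G with AT-rich frequencies
#' @param third_position_rate rate of codon position 3 relative to positions
#'   1+2 inside protein-coding genes (class rates are normalized to mean 1
#'   over a codon)
#' @return object of class `simulation_truth`
#' @export
simulation_truth <- function(mu = 0.0115, copy_ratio = 55, error_rate = 0.002,
                             seed = 1L,
                             model = subst_model("HKY",
                                                 freqs = c(A = 0.40, C = 0.11,
                                                           G = 0.09, T = 0.40),
                                                 kappa = 8, alpha = 0.3),
                             third_position_rate = 2) {
  if (mu <= 0) stop("mu must be positive")
  if (copy_ratio < 1) stop("copy_ratio must be >= 1")
  structure(list(mu = mu, copy_ratio = copy_ratio, error_rate = error_rate,
                 seed = seed, model = model,
                 third_position_rate = third_position_rate),
            class = "simulation_truth")
}

# evolve integer states (1..4) one branch; states matrix n_sites, site_rates
# vector of per-site relative rates, t branch length in subs/site
.evolve_branch <- function(states, site_rates, t, model) {
  out <- states
  for (r in unique(site_rates)) {
    P <- transition_prob(model, t * r)
    sel <- site_rates == r
    for (s in 1:4) {
      idx <- which(sel & states == s)
      if (length(idx)) out[idx] <- sample.int(4L, length(idx), replace = TRUE,
                                              prob = P[s, ])
    }
  }
  out
}

#' Simulate a strict-clock nucleotide alignment on a dated tree
#'
#' Evolves `n_sites` independent sites down `tree` under `model`, with branch
#' lengths equal to `mu` times branch durations (strict molecular clock).
#' Gamma rate variation (if the model has it) assigns each site a fixed
#' category across the whole tree.
#'
#' @param tree an ultrametric `phylo` with branch lengths in my
#' @param n_sites alignment length
#' @param mu substitution rate in substitutions/site/my
#' @param model a [subst_model()]
#' @param seed optional seed
#' @return character matrix (taxa x 1) of sequences: named character vector of
#'   equal-length strings, one per tip
#' @export
simulate_alignment <- function(tree, n_sites, mu = 0.0115,
                               model = subst_model("HKY",
                                                   freqs = c(A = 0.40, C = 0.11,
                                                             G = 0.09, T = 0.40),
                                                   kappa = 8, alpha = 0.3),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (mu < 0) stop("mu must be non-negative")
  n <- length(tree$tip.label)
  nnode <- n + tree$Nnode
  site_rates <- sample(model$rates, n_sites, replace = TRUE)
  states <- vector("list", nnode)
  root <- n + 1L
  states[[root]] <- sample.int(4L, n_sites, replace = TRUE, prob = model$freqs)
  for (e in seq_len(nrow(tree$edge))) {   # cladewise: parents first
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    states[[ch]] <- .evolve_branch(states[[p]], site_rates,
                                   mu * tree$edge.length[e], model)
  }
  out <- vapply(seq_len(n),
                function(i) paste(DNA[states[[i]]], collapse = ""), "")
  names(out) <- tree$tip.label
  out
}

# per-position relative rate classes for a template: codon position 3 of CDS
# evolves at third_position_rate relative to class 1+2; non-coding at 1
.site_rate_classes <- function(template, third_rate) {
  L <- attr(template, "genome_length")
  r3 <- 3 * third_rate / (2 + third_rate)   # normalize codon mean rate to 1
  r12 <- 3 / (2 + third_rate)
  cls <- rep(1, L)
  for (i in which(template$type == "CDS")) {
    pos <- (template$start[i] + 1L):template$end[i]
    within <- seq_along(pos) %% 3L          # 1,2,0 in coding orientation
    if (template$strand[i] == "-") within <- rev(within)
    cls[pos] <- ifelse(within == 0L, r3, r12)
  }
  cls
}

# positions (1-based, genome coords) of in-frame stop codons within CDS
.find_cds_stops <- function(chars, template) {
  bad <- integer()
  for (i in which(template$type == "CDS")) {
    pos <- (template$start[i] + 1L):template$end[i]
    cds <- chars[pos]
    if (template$strand[i] == "-") cds <- rev(c(A = "T", C = "G", G = "C", T = "A")[cds])
    cod <- paste0(cds[c(TRUE, FALSE, FALSE)], cds[c(FALSE, TRUE, FALSE)],
                  cds[c(FALSE, FALSE, TRUE)])
    ncod <- length(cod)
    hit <- which(cod %in% MT_STOPS & seq_len(ncod) < ncod)  # internal only
    for (h in hit) {
      cpos <- pos[((h - 1L) * 3L + 1L):(h * 3L)]
      if (template$strand[i] == "-") cpos <- pos[(length(pos) - h * 3L + 1L):(length(pos) - (h - 1L) * 3L)]
      bad <- c(bad, cpos)
    }
  }
  unique(bad)
}

#' Evolve mitogenomes down a dated tree
#'
#' Forward-simulates whole mitogenomes by substitution only (no indels) under
#' a strict clock, with codon position 3 of protein-coding genes evolving at
#' its own relative rate.  With `avoid_stops = TRUE`, substitutions that would
#' create an internal in-frame stop codon in a CDS are rejected (a crude model
#' of purifying selection that keeps all simulated CDS translatable).
#'
#' @param tree ultrametric `phylo`, branch lengths in my
#' @param truth a [simulation_truth()]
#' @param template a [genome_template()]
#' @param root_genome optional `mitogenome` to use at the root (default
#'   simulated from the template)
#' @param avoid_stops reject substitutions creating internal stops in CDS
#' @return named list of `mitogenome` objects, one per tip
#' @export
evolve_genomes <- function(tree, truth, template,
                           root_genome = NULL, avoid_stops = FALSE) {
  set.seed(truth$seed)
  root_genome <- root_genome %||% simulate_root_genome(template)
  if (nchar(root_genome$seq) != attr(template, "genome_length"))
    stop("root genome length does not match template")
  model <- truth$model
  L <- attr(template, "genome_length")
  cls <- .site_rate_classes(template, truth$third_position_rate)
  gam <- sample(model$rates, L, replace = TRUE)
  site_rates <- cls * gam
  n <- length(tree$tip.label)
  base_idx <- setNames(1:4, DNA)
  states <- vector("list", n + tree$Nnode)
  states[[n + 1L]] <- unname(base_idx[strsplit(root_genome$seq, "")[[1]]])
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    st <- .evolve_branch(states[[p]], site_rates,
                         truth$mu * tree$edge.length[e], model)
    if (avoid_stops) {
      repeat {
        bad <- .find_cds_stops(DNA[st], template)
        if (!length(bad)) break
        st[bad] <- states[[p]][bad]        # revert the offending codons
      }
    }
    states[[ch]] <- st
  }
  out <- lapply(seq_len(n), function(i)
    mitogenome(paste(DNA[states[[i]]], collapse = ""), template,
               tree$tip.label[i]))
  names(out) <- tree$tip.label
  out
}
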