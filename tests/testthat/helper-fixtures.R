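# shared fixtures: built in code, deterministic under fixed seeds

BASES <- c("A", "C", "G", "T")
at_rich <- c(A = 0.40, C = 0.11, G = 0.09, T = 0.40)

toy_genome <- function(n = 3000, seed = 3, taxon = "toy") {
  set.seed(seed)
  mitogenome(random_dna(n, c(A = .3, C = .2, G = .2, T = .3)), taxon = taxon)
}

default_model <- function() {
  subst_model("HKY", freqs = at_rich, kappa = 8, alpha = 0.3)
}

# naive hash-and-count reference for the enrichment filters
naive_dup_filter <- function(seqs, m) {
  cnt <- table(seqs)
  seqs[cnt[seqs] >= m]
}
naive_abundance <- function(seqs, mc) {
  cnt <- table(seqs)
  sort(names(cnt)[cnt > mc])
}

# brute-force pruning oracle: enumerate every internal-state assignment
brute_loglik <- function(seqs, tree, model) {
  n <- length(tree$tip.label)
  nint <- tree$Nnode
  m <- do.call(rbind, strsplit(toupper(seqs[tree$tip.label]), ""))
  idx <- matrix(match(m, BASES), nrow(m))
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    transition_prob(model, tree$edge.length[e]))
  grid <- as.matrix(expand.grid(rep(list(1:4), nint)))
  parent <- tree$edge[, 1]; child <- tree$edge[, 2]
  ll <- 0
  for (s in seq_len(ncol(idx))) {
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      st <- c(idx[, s], grid[g, ])
      pr <- model$freqs[[st[n + 1]]]
      for (e in seq_along(P)) pr <- pr * P[[e]][st[parent[e]], st[child[e]]]
      tot <- tot + pr
    }
    ll <- ll + log(tot)
  }
  ll
}
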