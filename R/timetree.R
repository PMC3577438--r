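#' Simulate a dated Yule species tree
#'
#' Pure-birth (Yule) simulation conditioned on the number of tips and the root
#' age.  Lineages split after exponential waiting times with per-lineage rate
#' `birth_rate`; the realized depth is rescaled so that the root divergence
#' sits exactly at `root_age` and all tips at 0 (ultrametric).
#'
#' @param n_taxa number of tips (>= 2)
#' @param birth_rate per-lineage speciation rate (events per lineage per my)
#' @param root_age age of the root divergence, in mya
#' @param seed optional integer seed
#' @param labels optional tip labels (default t1..tn)
#' @return an ultrametric `phylo` object (class `c("timetree","phylo")`) with
#'   branch lengths in my; see [node_ages()]
#' @export
simulate_time_tree <- function(n_taxa, birth_rate = 0.1, root_age,
                               seed = NULL, labels = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  if (root_age <= 0) stop("root_age must be positive")
  if (birth_rate <= 0) stop("birth_rate must be positive")
  n_taxa <- as.integer(n_taxa)

  # forward simulation: root splits at time 0, grow to n_taxa lineages
  n_int <- n_taxa - 1L                      # internal nodes incl. root
  split_time <- numeric(n_int)              # time of each split (node i)
  parent_of <- integer(n_int)               # internal node -> parent internal node (0 = none)
  # active lineages are identified by the internal node they descend from and
  # a slot (1 or 2); when a lineage splits it becomes a new internal node
  act_node <- c(1L, 1L); act_slot <- c(1L, 2L)
  child_node <- matrix(0L, n_int, 2L)       # 0 = still a tip
  t_now <- 0; n_next <- 2L
  while (n_next <= n_int) {
    k <- length(act_node)
    t_now <- t_now + rexp(1L, rate = birth_rate * k)
    j <- sample.int(k, 1L)
    split_time[n_next] <- t_now
    parent_of[n_next] <- act_node[j]
    child_node[act_node[j], act_slot[j]] <- n_next
    act_node <- c(act_node[-j], n_next, n_next)
    act_slot <- c(act_slot[-j], 1L, 2L)
    n_next <- n_next + 1L
  }
  depth <- t_now + rexp(1L, rate = birth_rate * n_taxa)  # time tips are observed
  scale <- root_age / depth
  split_time <- split_time * scale

  # build ape edge matrix: tips 1..n, internal nodes n+1..2n-1 (root = n+1)
  tip_id <- 0L
  edge <- matrix(0L, 2L * n_taxa - 2L, 2L)
  elen <- numeric(nrow(edge))
  e <- 0L
  emit <- function(parent_int, slot) {
    child <- child_node[parent_int, slot]
    e <<- e + 1L
    if (child == 0L) {              # tip
      tip_id <<- tip_id + 1L
      edge[e, ] <<- c(n_taxa + parent_int, tip_id)
      elen[e] <<- root_age - split_time[parent_int]
    } else {
      edge[e, ] <<- c(n_taxa + parent_int, n_taxa + child)
      elen[e] <<- split_time[child] - split_time[parent_int]
      emit(child, 1L); emit(child, 2L)
    }
  }
  emit(1L, 1L); emit(1L, 2L)
  storage.mode(edge) <- "integer"     # ape's C routines require integer edges
  labels <- labels %||% paste0("t", seq_len(n_taxa))
  phy <- structure(list(edge = edge, edge.length = elen,
                        tip.label = labels, Nnode = n_int),
                   class = c("timetree", "phylo"), order = "cladewise")
  phy
}

#' Node ages of an ultrametric tree
#'
#' @param phy an ultrametric `phylo`
#' @return numeric vector of ages (mya, tips at 0) indexed by ape node number
#' @export
node_ages <- function(phy) {
  n <- length(phy$tip.label)
  depth <- numeric(n + phy$Nnode)
  # edges in cladewise order: parents before children
  for (e in seq_len(nrow(phy$edge))) {
    depth[phy$edge[e, 2L]] <- depth[phy$edge[e, 1L]] + phy$edge.length[e]
  }
  max(depth[seq_len(n)]) - depth
}

#' Check ultrametricity of a tree
#' @param phy a `phylo`
#' @param tol relative tolerance on root-to-tip path variation
#' @return logical
#' @export
is_ultrametric <- function(phy, tol = 1e-9) {
  n <- length(phy$tip.label)
  a <- node_ages(phy)[seq_len(n)]
  diff(range(a)) <= tol * max(node_ages(phy))
}

#' Root age of an ultrametric tree
#' @param phy a `phylo`
#' @return age of the root in my
#' @export
root_age <- function(phy) {
  max(node_ages(phy))
}
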