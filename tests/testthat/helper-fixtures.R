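# shared helpers: tiny alignments and trees built in code

tiny_aln <- function(seqs) protein_msa(seqs)

# additive distance matrix of a tree, labels sorted for stability
additive_matrix <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[sort(rownames(d)), sort(rownames(d))]
}

# brute-force patristic distance by enumerating the leaf-to-leaf path
brute_patristic <- function(tree, a, b) {
  if (a == b) return(0)
  n <- length(tree$tip.label)
  parent <- integer(max(tree$edge))
  plen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  plen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(node) {
    out <- node
    while (parent[node] != 0) {
      node <- parent[node]
      out <- c(out, node)
    }
    out
  }
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  pa <- path_to_root(ia)
  pb <- path_to_root(ib)
  mrca <- pa[pa %in% pb][1]
  up <- function(node, stop_at) {
    tot <- 0
    while (node != stop_at) {
      tot <- tot + plen[node]
      node <- parent[node]
    }
    tot
  }
  up(ia, mrca) + up(ib, mrca)
}

# deterministic random binary tree with branch lengths in [0.1, 2]
random_additive_tree <- function(n_leaves, seed) {
  set.seed(seed)
  t <- ape::rtree(n_leaves, rooted = FALSE,
                  tip.label = sprintf("T%02d", seq_len(n_leaves)))
  t$edge.length <- runif(nrow(t$edge), 0.1, 2)
  t
}

scenario_small <- function(label, seed = 1L, ...) {
  scenario(label, seq_length = 200L, seed = seed, ...)
}
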