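#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomerative neighbor joining: at each step the pair
#' minimising the Q-criterion `(n-2) d(i,j) - r_i - r_j` is joined, pendant
#' branch lengths come from the three-point formulas, and the matrix is
#' reduced with `d(u,k) = (d(i,k) + d(j,k) - d(i,j)) / 2`. The method is
#' exact on additive matrices. Two deterministic conventions are applied:
#' ties in Q are broken by the lexicographically smallest label pair
#' (clusters are keyed by their smallest leaf label), and negative branch
#' length estimates are clamped to zero with the deficit moved to the
#' sibling branch so the joined pair keeps its estimated total length.
#'
#' @param d A symmetric numeric matrix with zero diagonal, finite entries
#'   and unique dimnames (at least 2 labels).
#' @return An unrooted `ape::phylo` tree containing every input label.
#' @export
#' @examples
#' d <- matrix(c(0, .4, .4, 0), 2, 2,
#'             dimnames = list(c("A", "B"), c("A", "B")))
#' neighbor_joining(d)
neighbor_joining <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    abort("distance matrix must be square", class = "mosaic_invalid_matrix")
  }
  labels <- rownames(d)
  if (is.null(labels) || anyDuplicated(labels) ||
      !identical(labels, colnames(d))) {
    abort("distance matrix needs matching, unique dimnames",
          class = "mosaic_invalid_matrix")
  }
  if (any(!is.finite(d))) {
    abort("distance matrix contains NA/NaN/Inf", class = "mosaic_invalid_matrix")
  }
  if (max(abs(d - t(d))) > 1e-8) {
    abort("distance matrix is not symmetric", class = "mosaic_invalid_matrix")
  }
  n <- nrow(d)
  if (n < 2) abort("need at least 2 labels", class = "mosaic_invalid_matrix")

  fmt <- function(x) sprintf("%.17g", max(x, 0))
  # cluster state: newick fragment + smallest contained leaf (tie-break key)
  frag <- labels
  key <- labels

  clamp_pair <- function(li, lj) {
    if (li < 0) { lj <- lj - li; li <- 0 }
    if (lj < 0) { li <- li - lj; lj <- 0 }
    c(li, lj)
  }

  if (n == 2) {
    l <- d[1, 2] / 2
    txt <- paste0("(", frag[1], ":", fmt(l), ",", frag[2], ":", fmt(l), ");")
    return(ape::read.tree(text = txt))
  }

  while (n > 3) {
    r <- rowSums(d)
    Q <- (n - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 & upper.tri(Q), arr.ind = TRUE)
    # lexicographic tie-break on the (sorted) smallest-leaf key pair
    pk <- apply(cand, 1, function(ij) {
      p <- sort(c(key[ij[1]], key[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(pk)[1], ]
    i <- min(pick); j <- max(pick)
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    l2 <- clamp_pair(li, lj)
    new_frag <- paste0("(", frag[i], ":", fmt(l2[1]), ",",
                       frag[j], ":", fmt(l2[2]), ")")
    new_key <- min(key[i], key[j])
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    frag <- c(frag[keep], new_frag)
    key <- c(key[keep], new_key)
    n <- n - 1
    dimnames(d) <- list(key, key)
  }

  # final trifurcation by the three-point formulas
  a <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  c3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  txt <- paste0("(", frag[1], ":", fmt(a), ",", frag[2], ":", fmt(b), ",",
                frag[3], ":", fmt(c3), ");")
  ape::read.tree(text = txt)
}

#' Leaf bipartitions of a tree
#'
#' Every internal edge of an unrooted tree splits the leaves in two. Each
#' split is keyed canonically by the side *not* containing the reference
#' leaf (the lexicographically smallest label), so keys are comparable
#' across trees on the same leaf set regardless of representation.
#'
#' @param tree An `ape::phylo`.
#' @return A tibble with columns `node` (the child node of the edge),
#'   `key` (canonical string), `tips` (list of the clade-side labels).
#' @keywords internal
tree_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  ref <- min(tree$tip.label)
  internal <- setdiff(unique(tree$edge[, 2]), seq_len(ntip))
  if (length(internal) == 0) {
    return(tibble::tibble(node = integer(), key = character(), tips = list()))
  }
  desc <- phangorn::Descendants(tree, internal, type = "tips")
  tips <- purrr::map(desc, ~ tree$tip.label[.x])
  side <- purrr::map(tips, function(tp) {
    if (ref %in% tp) setdiff(tree$tip.label, tp) else tp
  })
  tibble::tibble(
    node = internal,
    key = purrr::map_chr(side, ~ paste(sort(.x), collapse = "|")),
    tips = tips
  )
}

# internal-node supports as numbers (NA where absent/blank)
node_supports <- function(tree) {
  ntip <- length(tree$tip.label)
  nl <- tree$node.label
  if (is.null(nl)) nl <- rep(NA_character_, tree$Nnode)
  suppressWarnings(as.numeric(nl))
}

support_scale <- function(tree) {
  sc <- attr(tree, "support_scale")
  if (is.null(sc)) "bootstrap_pct" else sc
}

#' Set the support scale tag of a tree
#'
#' Trees carry support values on internal node labels; the scale tag says
#' whether they are bootstrap percentages (`"bootstrap_pct"`, range 0-100)
#' or Bayesian posterior probabilities (`"posterior"`, range 0-1).
#'
#' @param tree An `ape::phylo`.
#' @param scale `"bootstrap_pct"` or `"posterior"`.
#' @return The tree with the `support_scale` attribute set.
#' @export
set_support_scale <- function(tree, scale = c("bootstrap_pct", "posterior")) {
  scale <- match.arg(scale)
  sup <- node_supports(tree)
  rng <- if (scale == "bootstrap_pct") c(0, 100) else c(0, 1)
  if (any(!is.na(sup) & (sup < rng[1] | sup > rng[2]))) {
    abort(paste0("support values outside the ", scale, " range [",
                 rng[1], ", ", rng[2], "]"), class = "mosaic_config_error")
  }
  attr(tree, "support_scale") <- scale
  tree
}

#' Read / write a gene tree in newick format
#'
#' Internal node labels hold clade support values; the scale (bootstrap
#' percentage vs posterior probability) is declared out of band via
#' `support_scale` because both conventions occur in the wild.
#'
#' @param path Newick file path.
#' @param support_scale `"bootstrap_pct"` (default) or `"posterior"`.
#' @return `read_gene_tree()` returns an `ape::phylo` with the scale
#'   attribute set; `write_gene_tree()` returns `path` invisibly.
#' @export
read_gene_tree <- function(path, support_scale = c("bootstrap_pct", "posterior")) {
  set_support_scale(ape::read.tree(path), match.arg(support_scale))
}

#' @rdname read_gene_tree
#' @param tree An `ape::phylo`.
#' @export
write_gene_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Bootstrapped neighbor-joining tree from an alignment
#'
#' Builds the point-estimate NJ tree from the full alignment, then
#' `n_reps` NJ trees from column-resampled alignments (columns drawn with
#' replacement, same length). Each internal edge's support is the
#' percentage of replicate trees containing the same leaf bipartition,
#' written onto the corresponding internal node label. Deterministic for a
#' fixed `seed`.
#'
#' @param aln A [protein_msa()].
#' @param n_reps Number of bootstrap replicates (>= 1). Default 100.
#' @param model Distance model passed to [pairwise_distance()].
#' @param seed Integer seed.
#' @return An unrooted `ape::phylo` with bootstrap-percentage node labels
#'   and `support_scale = "bootstrap_pct"`.
#' @export
bootstrap_supports <- function(aln, n_reps = 100L, model = "poisson", seed = 1L) {
  if (n_reps < 1) abort("n_reps must be >= 1", class = "mosaic_config_error")
  point <- neighbor_joining(pairwise_distance(aln, model = model))
  bp <- tree_bipartitions(point)
  counts <- setNames(rep(0L, nrow(bp)), bp$key)
  L <- ncol(aln)
  m <- unclass(aln)
  set.seed(seed)
  for (rep_i in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_aln <- protein_msa(m[, cols, drop = FALSE])
    rep_tree <- try(neighbor_joining(pairwise_distance(rep_aln, model = model)),
                    silent = TRUE)
    if (inherits(rep_tree, "try-error")) next  # e.g. resample left a pair with no overlap
    keys <- tree_bipartitions(rep_tree)$key
    hit <- names(counts) %in% keys
    counts[hit] <- counts[hit] + 1L
  }
  sup <- round(100 * counts / n_reps, 6)
  ntip <- length(point$tip.label)
  labs <- rep("", point$Nnode)
  labs[bp$node - ntip] <- as.character(sup[bp$key])
  point$node.label <- labs
  set_support_scale(point, "bootstrap_pct")
}

#' Patristic distance between two leaves
#'
#' Sum of branch lengths on the unique path between two leaves.
#'
#' @param tree An `ape::phylo` with branch lengths.
#' @param a,b Leaf labels.
#' @return A non-negative number; zero when `a == b`.
#' @export
patristic_distance <- function(tree, a, b) {
  tips <- tree$tip.label
  if (!a %in% tips || !b %in% tips) {
    abort(paste0("unknown leaf: ",
                 paste(setdiff(c(a, b), tips), collapse = ", ")),
          class = "mosaic_unknown_taxon")
  }
  if (a == b) return(0)
  dm <- ape::cophenetic.phylo(tree)
  unname(dm[a, b])
}

#' Collapse monophyletic single-genus clades to one representative
#'
#' To diminish taxon-sampling bias, every maximal clade composed
#' exclusively of OTUs from one genus is reduced to a single
#' representative leaf (the lexicographically smallest label), repeatedly
#' until a fixpoint. Clades are read relative to the protected leaves
#' (normally the query): the bipartition side containing a protected leaf
#' is never a collapse candidate and protected leaves are never pruned.
#'
#' @param tree An `ape::phylo`.
#' @param taxonomy A [taxonomy_map()] registering every leaf.
#' @param protected Character vector of leaf labels never to prune
#'   (at least the query). May be empty, in which case the
#'   lexicographically smallest leaf anchors the orientation.
#' @return The pruned `ape::phylo` (support scale attribute preserved).
#' @export
collapse_single_genus_clades <- function(tree, taxonomy, protected = character()) {
  genus <- function(labels) genus_lookup(labels, taxonomy)
  invisible(genus(tree$tip.label))  # validate registration up front
  sc <- support_scale(tree)
  repeat {
    tips <- tree$tip.label
    ref <- if (length(protected) > 0) sort(protected)[1] else min(tips)
    bp <- tree_bipartitions(tree)
    sides <- purrr::map(bp$tips, function(tp) {
      if (ref %in% tp) setdiff(tips, tp) else tp
    })
    eligible <- purrr::map_lgl(sides, function(s) {
      length(s) >= 2 && !any(s %in% protected) &&
        length(unique(genus(s))) == 1
    })
    if (!any(eligible)) break
    sides <- sides[eligible]
    sizes <- lengths(sides)
    # keep only maximal pure clades (not nested in a larger pure clade)
    ord <- order(-sizes)
    chosen <- list()
    for (k in ord) {
      s <- sides[[k]]
      if (!any(purrr::map_lgl(chosen, ~ all(s %in% .x)))) {
        chosen <- c(chosen, list(s))
      }
    }
    drop <- unlist(purrr::map(chosen, ~ setdiff(.x, min(.x))))
    drop <- unique(drop)
    if (length(drop) == 0) break
    tree <- ape::drop.tip(tree, drop)
    if (is.null(tree)) abort("collapse removed the whole tree",
                             class = "mosaic_too_few_taxa")
  }
  attr(tree, "support_scale") <- sc
  tree
}

#' Test whether a leaf set is a supported bipartition of a tree
#'
#' In the unrooted sense, a leaf set is monophyletic when a single edge
#' separates it from all other leaves. The result distinguishes a split
#' present with adequate support (`"present"`), present but below the
#' threshold or carrying no recorded support (`"present_unsupported"`),
#' and not present at all (`"absent"`). Singleton sets are trivially
#' monophyletic with maximal support. The support threshold is compared
#' inclusively on the tree's own support scale.
#'
#' @param tree An `ape::phylo` with supports on internal node labels.
#' @param taxa Character vector; a proper non-empty subset of the leaves.
#' @param min_support Inclusive support threshold, on the tree's scale
#'   (default 70 bootstrap percent).
#' @return One of `"present"`, `"present_unsupported"`, `"absent"`.
#' @export
supported_bipartition <- function(tree, taxa, min_support = 70) {
  tips <- tree$tip.label
  if (length(taxa) == 0 || !all(taxa %in% tips) || length(taxa) >= length(tips)) {
    abort("taxa must be a proper non-empty subset of the leaves",
          class = "mosaic_invalid_taxa_set")
  }
  if (length(taxa) == 1) return("present")
  bp <- tree_bipartitions(tree)
  ref <- min(tips)
  target <- if (ref %in% taxa) setdiff(tips, taxa) else taxa
  key <- paste(sort(target), collapse = "|")
  hit <- which(bp$key == key)
  if (length(hit) == 0) return("absent")
  sup <- node_supports(tree)[bp$node[hit[1]] - length(tips)]
  if (is.na(sup) || sup < min_support) "present_unsupported" else "present"
}
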