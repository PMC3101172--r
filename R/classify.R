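#' Classifier configuration
#'
#' Thresholds and conventions for the topology classification. The
#' defining monophyly of a red-lineage gene must reach 70% bootstrap
#' support on bootstrap-scaled trees or 0.9 posterior probability on
#' posterior-scaled trees (both inclusive). Trees are oriented by the
#' first outgroup group present, in preference order cyanobacteria, other
#' eubacteria, unikonts. A sister clade counts as "red" or "green" when at
#' least `sister_majority` of its leaves belong to that group, tolerating
#' occasional stragglers in real sister clades.
#'
#' @param min_bootstrap Inclusive bootstrap-percent threshold (default 70).
#' @param min_posterior Inclusive posterior threshold (default 0.9).
#' @param outgroup_groups Ordered rooting preference list.
#' @param sister_majority Fraction of sister leaves required to call its
#'   group (default 0.8).
#' @return A list of class `classify_config`.
#' @export
classify_config <- function(min_bootstrap = 70,
                            min_posterior = 0.9,
                            outgroup_groups = c("CYANOBACTERIA",
                                                "OTHER_BACTERIA", "UNIKONT"),
                            sister_majority = 0.8) {
  if (min_bootstrap < 0 || min_bootstrap > 100 ||
      min_posterior < 0 || min_posterior > 1) {
    abort("thresholds outside their scales' ranges", class = "mosaic_config_error")
  }
  bad <- setdiff(outgroup_groups, lineage_groups())
  if (length(bad) > 0) {
    abort(paste0("unknown outgroup group(s): ", paste(bad, collapse = ", ")),
          class = "mosaic_config_error")
  }
  structure(list(min_bootstrap = min_bootstrap,
                 min_posterior = min_posterior,
                 outgroup_groups = outgroup_groups,
                 sister_majority = sister_majority),
            class = "classify_config")
}

support_threshold <- function(tree, config) {
  if (support_scale(tree) == "posterior") config$min_posterior else config$min_bootstrap
}

outgroup_group_used <- function(tree, taxonomy, config) {
  groups <- assign_group(tree$tip.label, taxonomy)
  present <- config$outgroup_groups[config$outgroup_groups %in% groups]
  if (length(present) == 0) {
    abort(paste0("no outgroup group (",
                 paste(config$outgroup_groups, collapse = ", "),
                 ") represented in the tree"),
          class = "mosaic_no_outgroup")
  }
  present[1]
}

# Clades containing `query`, oriented away from the reference outgroup
# leaf, ordered smallest to largest (the chain of query ancestors).
query_clade_chain <- function(tree, query, ref) {
  tips <- tree$tip.label
  bp <- tree_bipartitions(tree)
  sup <- node_supports(tree)
  ntip <- length(tips)
  sides <- purrr::map(bp$tips, function(tp) {
    if (ref %in% tp) setdiff(tips, tp) else tp
  })
  supports <- sup[bp$node - ntip]
  keep <- purrr::map_lgl(sides, ~ query %in% .x)
  sides <- sides[keep]
  supports <- supports[keep]
  # around a rooted basal bifurcation the same unrooted edge appears twice;
  # keep one entry per split, with the best recorded support
  key <- purrr::map_chr(sides, ~ paste(sort(.x), collapse = "|"))
  if (anyDuplicated(key)) {
    agg <- split(seq_along(key), key)
    idx <- purrr::map_int(agg, function(ii) {
      s <- supports[ii]
      if (all(is.na(s))) ii[1] else ii[which.max(s)]
    })
    sides <- sides[idx]
    supports <- supports[idx]
  }
  ord <- order(lengths(sides))
  tibble::tibble(side = sides[ord], support = supports[ord],
                 size = lengths(sides)[ord])
}

#' Overwrite every internal-edge support of a tree
#'
#' Utility for threshold sweeps and planted-truth checks: sets all
#' internal node labels to one support value on the given scale.
#'
#' @param tree An `ape::phylo`.
#' @param value Support value.
#' @param scale `"bootstrap_pct"` or `"posterior"`.
#' @return The modified tree.
#' @export
set_all_supports <- function(tree, value, scale = "bootstrap_pct") {
  tree$node.label <- rep(as.character(value), tree$Nnode)
  set_support_scale(tree, scale)
}

#' Root a gene tree on its outgroup
#'
#' Roots on the edge subtending the largest clade composed purely of the
#' first outgroup group present in the tree (preference order from the
#' config); when that group's leaves form no pure clade, the single
#' lexicographically smallest outgroup leaf is used. An error of class
#' `mosaic_no_outgroup` is raised when no outgroup group is represented.
#'
#' @param tree An `ape::phylo`.
#' @param taxonomy A [taxonomy_map()].
#' @param config A [classify_config()].
#' @return A rooted `ape::phylo` (support scale attribute preserved).
#' @export
root_tree <- function(tree, taxonomy, config = classify_config()) {
  og <- outgroup_group_used(tree, taxonomy, config)
  groups <- assign_group(tree$tip.label, taxonomy)
  og_leaves <- tree$tip.label[groups == og]
  sc <- support_scale(tree)
  bp <- tree_bipartitions(tree)
  pure <- purrr::map(bp$tips, function(tp) {
    for (s in list(tp, setdiff(tree$tip.label, tp))) {
      if (all(s %in% og_leaves)) return(s)
    }
    NULL
  })
  pure <- purrr::compact(pure)
  out <- if (length(pure) > 0) pure[[which.max(lengths(pure))]] else sort(og_leaves)[1]
  rooted <- ape::root(tree, outgroup = out, resolve.root = TRUE)
  attr(rooted, "support_scale") <- sc
  rooted
}

#' Is the query nested in, or associated with, the red lineage?
#'
#' Finds the smallest clade containing the query (oriented away from the
#' outgroup) whose other members all belong to `{CR, RED, EUGLENID}`, with
#' at least one CR or RED member, and whose subtending edge support meets
#' the threshold for the tree's support scale.
#'
#' @param tree An `ape::phylo` with supports, containing `query`.
#' @param query Query leaf label.
#' @param taxonomy A [taxonomy_map()].
#' @param config A [classify_config()].
#' @return A list: `found` (logical), `support` (the defining edge
#'   support, `NA` when not found), `clade` (character vector of leaves,
#'   `NULL` when not found).
#' @export
red_lineage_monophyly <- function(tree, query, taxonomy,
                                  config = classify_config()) {
  if (!query %in% tree$tip.label) {
    abort(paste0("query ", sQuote(query), " is not a leaf"),
          class = "mosaic_unknown_taxon")
  }
  og <- outgroup_group_used(tree, taxonomy, config)
  groups_all <- assign_group(tree$tip.label, taxonomy)
  ref <- sort(tree$tip.label[groups_all == og])[1]
  thr <- support_threshold(tree, config)
  ch <- query_clade_chain(tree, query, ref)
  for (k in seq_len(nrow(ch))) {
    others <- setdiff(ch$side[[k]], query)
    if (length(others) == 0) next
    g <- assign_group(others, taxonomy)
    if (all(g %in% c("CR", "RED", "EUGLENID")) && any(g %in% c("CR", "RED")) &&
        !is.na(ch$support[k]) && ch$support[k] >= thr) {
      return(list(found = TRUE, support = ch$support[k], clade = ch$side[[k]]))
    }
  }
  list(found = FALSE, support = NA_real_, clade = NULL)
}

#' Does a clade contain a Peranema sequence?
#'
#' Flags the presence of the aplastidic eukaryovorous euglenid
#' *Peranema* inside a defining clade — evidence that the transfer
#' predates the divergence of euglenophytes and eukaryovorous euglenids.
#'
#' @param clade Character vector of OTU labels (a defining clade).
#' @param taxonomy A [taxonomy_map()].
#' @return `TRUE` iff at least one clade member has genus `"Peranema"`.
#' @export
peranema_coclade <- function(clade, taxonomy) {
  if (length(clade) == 0) return(FALSE)
  any(genus_lookup(clade, taxonomy) == "Peranema")
}

#' Classify a gene tree into transfer topology categories
#'
#' Implements the topology semantics of the red-lineage screen. After
#' orienting the tree by its outgroup, the classifier looks for the
#' smallest supported clade uniting the query with CR and/or red-algal
#' sequences ([red_lineage_monophyly()]). If none exists the gene is
#' `GREEN` when the smallest supported mixed clade around the query is
#' purely green(+euglenid), otherwise `UNCLASSIFIED`. If it exists, the
#' classifier absorbs CR-dominated sister clades walking rootward (the
#' euglenid + CR assemblage) and reads the first non-CR sister: a
#' supported association with a red-algal sister is `CR_RED`, with a
#' green sister `CR_GREEN`, and an unsupported or mixed sister leaves the
#' affiliation unclear, `RED_OTHER`. A red-only association with no CR
#' member in the defining clade is reported `UNCLASSIFIED` with a note
#' (the triose-phosphate-isomerase convention).
#'
#' @param tree An `ape::phylo` (>= 4 leaves) with supports on internal
#'   node labels and a support scale attribute.
#' @param query Query leaf label.
#' @param taxonomy A [taxonomy_map()].
#' @param config A [classify_config()].
#' @param gene_id Optional gene identifier carried into the result.
#' @return An object of class `gene_classification`: gene id, `category`
#'   (`CR_RED`, `CR_GREEN`, `RED_OTHER`, `GREEN`, `UNCLASSIFIED`),
#'   `defining_support` and its scale, the rooting group, the defining
#'   clade, the Peranema flag, and an audit `notes` string naming the
#'   supporting edges.
#' @export
classify_gene_tree <- function(tree, query, taxonomy,
                               config = classify_config(),
                               gene_id = NA_character_) {
  if (length(tree$tip.label) < 4) {
    abort("tree needs at least 4 leaves", class = "mosaic_config_error")
  }
  og <- outgroup_group_used(tree, taxonomy, config)
  groups_all <- assign_group(tree$tip.label, taxonomy)
  ref <- sort(tree$tip.label[groups_all == og])[1]
  thr <- support_threshold(tree, config)
  scale <- support_scale(tree)
  grp <- function(labels) assign_group(labels, taxonomy)
  ok <- function(s) !is.na(s) && s >= thr

  result <- function(category, support, clade, notes) {
    structure(list(gene_id = gene_id, category = category,
                   defining_support = support, support_scale = scale,
                   root_group_used = og,
                   clade = clade,
                   peranema_in_clade = peranema_coclade(clade, taxonomy),
                   notes = notes),
              class = "gene_classification")
  }

  rm <- red_lineage_monophyly(tree, query, taxonomy, config)
  ch <- query_clade_chain(tree, query, ref)

  if (!rm$found) {
    for (k in seq_len(nrow(ch))) {
      others <- setdiff(ch$side[[k]], query)
      g <- if (length(others) > 0) grp(others) else character()
      if (any(g != "EUGLENID") && ok(ch$support[k])) {
        non_eug <- g[g != "EUGLENID"]
        if (all(non_eug == "GREEN")) {
          return(result("GREEN", ch$support[k], ch$side[[k]],
                        paste0("query nested in green clade (support ",
                               ch$support[k], ")")))
        }
        return(result("UNCLASSIFIED", NA_real_, character(),
                      "no red-lineage association; smallest supported mixed clade not green"))
      }
    }
    return(result("UNCLASSIFIED", NA_real_, character(),
                  "no supported clade associates the query with any group"))
  }

  # walk rootward from the defining clade, absorbing CR-dominated sisters
  i <- which(purrr::map_lgl(ch$side, ~ setequal(.x, rm$clade)))[1]
  C <- rm$clade
  supC <- rm$support
  category <- NULL
  defining <- supC
  note <- ""
  repeat {
    if (i >= nrow(ch)) {
      category <- "RED_OTHER"
      defining <- supC
      note <- "euglenid+CR clade reaches the tree base; sister group unclear"
      break
    }
    P <- ch$side[[i + 1]]
    S <- setdiff(P, C)
    g <- grp(S)
    frac <- function(set) mean(g %in% set)
    if (frac(c("CR", "EUGLENID")) >= config$sister_majority) {
      if (ok(ch$support[i + 1])) supC <- ch$support[i + 1]
      C <- P
      i <- i + 1
      next
    }
    if (frac("RED") >= config$sister_majority && ok(ch$support[i + 1])) {
      category <- "CR_RED"
      defining <- ch$support[i + 1]
      note <- paste0("euglenid+CR clade sister to red algae (support ",
                     defining, ")")
    } else if (frac("GREEN") >= config$sister_majority && ok(ch$support[i + 1])) {
      category <- "CR_GREEN"
      defining <- ch$support[i + 1]
      note <- paste0("euglenid+CR clade sister to green lineage (support ",
                     defining, ")")
    } else {
      category <- "RED_OTHER"
      defining <- supC
      note <- paste0("sister group of the euglenid+CR clade unclear ",
                     "(mixed or below threshold); clade support ", supC)
    }
    break
  }

  if (!any(grp(setdiff(C, query)) == "CR")) {
    return(result("UNCLASSIFIED", NA_real_, character(),
                  "red-only association (no CR members in the defining clade); not designated"))
  }
  result(category, defining, C, note)
}

#' @export
print.gene_classification <- function(x, ...) {
  cat("gene classification", if (!is.na(x$gene_id)) paste0("[", x$gene_id, "]"),
      "\n  category:         ", x$category,
      "\n  defining support: ", x$defining_support, "(", x$support_scale, ")",
      "\n  rooted on:        ", x$root_group_used,
      "\n  Peranema in clade:", x$peranema_in_clade,
      "\n  clade size:       ", length(x$clade),
      "\n  notes:            ", x$notes, "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gene_classification <- function(x, ...) {
  tibble::tibble(gene_id = x$gene_id,
                 category = x$category,
                 defining_support = x$defining_support,
                 support_scale = x$support_scale,
                 root_group_used = x$root_group_used,
                 peranema_in_clade = x$peranema_in_clade,
                 clade_size = length(x$clade),
                 notes = x$notes)
}

#' Classify many gene trees
#'
#' @param trees Named list of `ape::phylo` trees (names are gene ids).
#' @inheritParams classify_gene_tree
#' @return A tibble with one [tidy()] row per gene plus a `clade` list
#'   column.
#' @export
classify_gene_trees <- function(trees, query, taxonomy,
                                config = classify_config()) {
  stopifnot(is.list(trees), !is.null(names(trees)))
  purrr::imap(trees, function(tr, id) {
    cl <- classify_gene_tree(tr, query, taxonomy, config, gene_id = id)
    out <- tidy(cl)
    out$clade <- list(cl$clade)
    out
  }) |> dplyr::bind_rows()
}

#' Summarise gene classifications into a category table
#'
#' Produces the per-category counts and gene lists of the screen summary
#' (the worked red-lineage gene table), including the number of genes
#' whose defining clade carries a Peranema sequence.
#'
#' @param classifications A tibble from [classify_gene_trees()] (or bound
#'   [tidy()] rows).
#' @return An object of class `classification_summary` with elements
#'   `counts` (tibble `category`, `n_genes`, `genes`), `n_peranema`, and
#'   `n_total`.
#' @export
summarize_classifications <- function(classifications) {
  cats <- c("CR_RED", "CR_GREEN", "RED_OTHER", "GREEN", "UNCLASSIFIED")
  counts <- purrr::map(cats, function(cc) {
    genes <- classifications$gene_id[classifications$category == cc]
    tibble::tibble(category = cc, n_genes = length(genes),
                   genes = list(sort(genes)))
  }) |> dplyr::bind_rows()
  structure(list(counts = counts,
                 n_peranema = sum(classifications$peranema_in_clade),
                 n_total = nrow(classifications)),
            class = "classification_summary")
}

#' @export
print.classification_summary <- function(x, ...) {
  cat("classification summary over", x$n_total, "genes\n")
  for (k in seq_len(nrow(x$counts))) {
    cat(sprintf("  %-12s %3d  %s\n", x$counts$category[k], x$counts$n_genes[k],
                paste(x$counts$genes[[k]], collapse = ", ")))
  }
  cat("  Peranema co-clade:", x$n_peranema, "\n")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.classification_summary <- function(x, ...) {
  n <- setNames(x$counts$n_genes, x$counts$category)
  tibble::tibble(n_genes = x$n_total,
                 cr_red = n[["CR_RED"]],
                 cr_green = n[["CR_GREEN"]],
                 red_other = n[["RED_OTHER"]],
                 green = n[["GREEN"]],
                 unclassified = n[["UNCLASSIFIED"]],
                 red_lineage_total = n[["CR_RED"]] + n[["CR_GREEN"]] +
                   n[["RED_OTHER"]],
                 peranema_coclade = x$n_peranema)
}
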