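category_palette <- function() {
  c(CR_RED = "#b2182b", CR_GREEN = "#1b7837", RED_OTHER = "#d6604d",
    GREEN = "#a6dba0", UNCLASSIFIED = "grey70")
}

#' Bar chart of gene counts per topology category
#'
#' @param object A `classification_summary` from
#'   [summarize_classifications()].
#' @param ... Ignored.
#' @return A `ggplot` object.
#' @exportS3Method ggplot2::autoplot
autoplot.classification_summary <- function(object, ...) {
  df <- object$counts
  df$category <- factor(df$category, levels = df$category)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n_genes,
                                   fill = .data$category)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = category_palette()) +
    ggplot2::labs(x = NULL, y = "genes",
                  title = "Gene tree topology categories",
                  subtitle = paste0(object$n_total, " genes; ",
                                    object$n_peranema,
                                    " with Peranema in the defining clade")) +
    ggplot2::theme_minimal()
}

#' Bar chart of closest-lineage tallies from the screen
#'
#' @param tally A tibble from [tally_by_group()].
#' @return A `ggplot` object.
#' @export
plot_screen_tally <- function(tally) {
  df <- dplyr::left_join(tally, lineage_group_names(), by = "group")
  df$group <- factor(df$group, levels = lineage_groups())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$n_genes)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = NULL, y = "queries",
                  title = "Lineage group closest to the query, per gene") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}

#' Plot a gene tree with tips coloured by lineage group
#'
#' Thin wrapper around `ape::plot.phylo` that colours tip labels by their
#' lineage group and shows internal-edge supports.
#'
#' @param tree An `ape::phylo`.
#' @param taxonomy A [taxonomy_map()].
#' @param ... Passed to `ape::plot.phylo`.
#' @return The tree, invisibly.
#' @export
plot_gene_tree <- function(tree, taxonomy, ...) {
  groups <- assign_group(tree$tip.label, taxonomy)
  pal <- c(EUGLENID = "#542788", OTHER_EXCAVATA = "#998ec3", CR = "#b2182b",
           RED = "#d6604d", GREEN = "#1b7837", GLAUCOPHYTE = "#80cdc1",
           UNIKONT = "grey40", CYANOBACTERIA = "#2166ac",
           OTHER_BACTERIA = "grey20")
  ape::plot.phylo(tree, tip.color = pal[groups], ...)
  if (!is.null(tree$node.label)) {
    ape::nodelabels(tree$node.label, frame = "none", cex = 0.7, adj = c(1.1, -0.3))
  }
  invisible(tree)
}
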