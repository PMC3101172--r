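#' Screen configuration
#'
#' Collects the thresholds of the two-step homology screen and the tree
#' building parameters. Defaults follow the published pipeline: the
#' first-step gate keeps genes with a green-plant hit at E-value strictly
#' below `1e-5`; the second step fetches homologues at E-value strictly
#' below `1e-3`, capped at 500 hits; trees are bootstrapped NJ on
#' Poisson-corrected protein distances.
#'
#' @param stage1_evalue_max Strict E-value bound for the green-hit gate.
#' @param stage2_evalue_max Strict E-value bound for homologue selection.
#' @param max_hits Cap on selected homologues (>= 4).
#' @param n_bootstrap Bootstrap replicates for NJ supports.
#' @param max_gap_frac_col Column gap-fraction threshold (trimming).
#' @param max_gap_frac_taxon Row gap-fraction threshold (trimming).
#' @param model Distance model, `"poisson"` or `"p_distance"`.
#' @param seed Integer seed for the bootstrap resampler.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(stage1_evalue_max = 1e-5,
                          stage2_evalue_max = 1e-3,
                          max_hits = 500L,
                          n_bootstrap = 100L,
                          max_gap_frac_col = 0.5,
                          max_gap_frac_taxon = 0.75,
                          model = "poisson",
                          seed = 1L) {
  if (stage1_evalue_max <= 0 || stage2_evalue_max <= 0) {
    abort("E-value thresholds must be positive", class = "mosaic_config_error")
  }
  if (max_hits < 4) abort("max_hits must be >= 4", class = "mosaic_config_error")
  structure(list(stage1_evalue_max = stage1_evalue_max,
                 stage2_evalue_max = stage2_evalue_max,
                 max_hits = as.integer(max_hits),
                 n_bootstrap = as.integer(n_bootstrap),
                 max_gap_frac_col = max_gap_frac_col,
                 max_gap_frac_taxon = max_gap_frac_taxon,
                 model = model,
                 seed = as.integer(seed)),
            class = "screen_config")
}

validate_hits <- function(hits) {
  hits <- tibble::as_tibble(hits)
  need <- c("query_id", "subject_id", "evalue")
  if (!all(need %in% names(hits))) {
    abort("hit table needs columns query_id, subject_id, evalue",
          class = "mosaic_config_error")
  }
  if (nrow(hits) > 0) {
    if (any(hits$evalue < 0)) {
      abort("E-values must be non-negative", class = "mosaic_config_error")
    }
    if (length(unique(hits$query_id)) > 1) {
      abort("hit table mixes multiple query ids", class = "mosaic_config_error")
    }
  }
  hits
}

#' First-step screen gate: strong similarity to green plants
#'
#' A gene enters the screen when at least one of its hits is to a
#' `GREEN`-group subject with E-value strictly below the stage-1
#' threshold. An empty hit table never passes.
#'
#' @param hits A data frame with columns `query_id`, `subject_id`,
#'   `evalue`, and either a `subject_group` column or subjects resolvable
#'   through `taxonomy`.
#' @param config A [screen_config()].
#' @param taxonomy Optional [taxonomy_map()] used to derive
#'   `subject_group` when absent.
#' @return `TRUE` or `FALSE`.
#' @export
stage1_gate <- function(hits, config = screen_config(), taxonomy = NULL) {
  hits <- validate_hits(hits)
  if (nrow(hits) == 0) return(FALSE)
  if (!"subject_group" %in% names(hits)) {
    hits$subject_group <- assign_group(hits$subject_id, taxonomy)
  }
  any(hits$subject_group == "GREEN" & hits$evalue < config$stage1_evalue_max)
}

#' Second-step homologue selection
#'
#' Keeps hits with E-value strictly below the stage-2 threshold, sorted
#' ascending by `(evalue, subject_id)` and truncated to `max_hits`.
#'
#' @inheritParams stage1_gate
#' @return The selected hits, a tibble (possibly empty).
#' @export
stage2_select <- function(hits, config = screen_config()) {
  hits <- validate_hits(hits)
  hits |>
    dplyr::filter(.data$evalue < config$stage2_evalue_max) |>
    dplyr::arrange(.data$evalue, .data$subject_id) |>
    dplyr::slice_head(n = config$max_hits)
}

#' Read a homology hit table (TSV)
#'
#' Columns: `query_id`, `subject_id`, `evalue`; `#` comments allowed.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_hit_table <- function(path) {
  validate_hits(readr::read_tsv(
    path, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(query_id = readr::col_character(),
                            subject_id = readr::col_character(),
                            evalue = readr::col_double())))
}

#' Lineage group patristically closest to the query
#'
#' Finds the leaf minimising the patristic distance to the query among
#' leaves whose group is not excluded. The query's own group (`EUGLENID`)
#' is excluded by default so conspecific and congeneric sequences do not
#' mask the donor signal. Exact distance ties are broken by the
#' lexicographically smallest label; all tied leaves are recorded.
#'
#' @param tree An `ape::phylo` with branch lengths.
#' @param query Query leaf label.
#' @param taxonomy A [taxonomy_map()].
#' @param exclude_groups Groups ineligible as "closest" (default
#'   `"EUGLENID"`).
#' @return A one-row tibble: `query_id`, `closest_otu`, `closest_group`,
#'   `distance`, `tied_otus` (list column).
#' @export
closest_taxon <- function(tree, query, taxonomy,
                          exclude_groups = "EUGLENID") {
  if (!query %in% tree$tip.label) {
    abort(paste0("query ", sQuote(query), " is not a leaf of the tree"),
          class = "mosaic_unknown_taxon")
  }
  groups <- assign_group(tree$tip.label, taxonomy)
  eligible <- tree$tip.label != query & !(groups %in% exclude_groups)
  if (!any(eligible)) {
    abort("no eligible leaf outside the excluded groups",
          class = "mosaic_no_eligible_taxon")
  }
  dm <- ape::cophenetic.phylo(tree)
  dq <- dm[query, tree$tip.label[eligible]]
  dmin <- min(dq)
  tied <- sort(names(dq)[dq <= dmin + 1e-12])
  best <- tied[1]
  tibble::tibble(
    query_id = query,
    closest_otu = best,
    closest_group = assign_group(best, taxonomy),
    distance = unname(dmin),
    tied_otus = list(if (length(tied) > 1) tied else character())
  )
}

#' Tally closest-taxon reports by lineage group
#'
#' @param reports A tibble of [closest_taxon()] rows.
#' @return A tibble `group`, `n_genes` covering every lineage group
#'   (zeros included); counts sum to `nrow(reports)`.
#' @export
tally_by_group <- function(reports) {
  counts <- table(factor(reports$closest_group, levels = lineage_groups()))
  tibble::tibble(group = lineage_groups(),
                 n_genes = as.integer(counts[lineage_groups()]))
}

#' Run the stage-1 screen on one gene family alignment
#'
#' Trims indel-rich columns then taxa (protecting the query), builds a
#' bootstrapped NJ tree, collapses single-genus clades, and reports the
#' lineage group patristically closest to the query on the collapsed tree.
#'
#' @param aln A [protein_msa()] containing the query row.
#' @param query Query OTU label.
#' @param taxonomy A [taxonomy_map()].
#' @param config A [screen_config()].
#' @return A list with elements `tree` (the collapsed bootstrapped NJ
#'   tree) and `report` (a one-row tibble from [closest_taxon()]).
#' @export
screen_gene <- function(aln, query, taxonomy, config = screen_config()) {
  aln <- trim_gappy_columns(aln, config$max_gap_frac_col)
  aln <- drop_gappy_taxa(aln, config$max_gap_frac_taxon, query = query)
  tree <- bootstrap_supports(aln, n_reps = config$n_bootstrap,
                             model = config$model, seed = config$seed)
  tree <- collapse_single_genus_clades(tree, taxonomy, protected = query)
  list(tree = tree, report = closest_taxon(tree, query, taxonomy))
}

#' Screen a set of gene family alignments
#'
#' Maps [screen_gene()] over a named list of alignments and binds the
#' per-gene closest-taxon reports. Per-gene bootstrap seeds are derived
#' deterministically from `config$seed` so the screen is reproducible
#' end to end.
#'
#' @param alignments Named list of [protein_msa()] objects (names are gene
#'   ids), or a directory of `.fasta` files.
#' @param query Query OTU label present in every alignment.
#' @param taxonomy A [taxonomy_map()].
#' @param config A [screen_config()].
#' @return A tibble with one row per gene: `gene_id`, the
#'   [closest_taxon()] columns, and a `tree` list column.
#' @export
screen_genes <- function(alignments, query, taxonomy,
                         config = screen_config()) {
  if (is.character(alignments) && length(alignments) == 1 &&
      dir.exists(alignments)) {
    paths <- sort(list.files(alignments, pattern = "\\.fa(sta)?$",
                             full.names = TRUE))
    if (length(paths) == 0) {
      abort(paste0("no FASTA alignments found in ", sQuote(alignments)),
            class = "mosaic_config_error")
    }
    alignments <- setNames(lapply(paths, read_alignment),
                           sub("\\.fa(sta)?$", "", basename(paths)))
  }
  stopifnot(is.list(alignments), !is.null(names(alignments)))
  rows <- purrr::imap(alignments, function(aln, gene_id) {
    cfg_g <- config
    cfg_g$seed <- (config$seed + match(gene_id, names(alignments)) * 7919L) %%
      .Machine$integer.max
    res <- screen_gene(aln, query, taxonomy, cfg_g)
    out <- res$report
    out$query_id <- NULL
    tibble::tibble(gene_id = gene_id, out, tree = list(res$tree))
  })
  dplyr::bind_rows(rows)
}
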