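#' Lineage groups of the mosaicism screen
#'
#' The screen bins every OTU into one of nine fixed lineage groups. `CR`
#' (Chromalveolata plus Rhizaria) covers stramenopiles, alveolates,
#' cryptophytes (including nucleomorph-encoded entries), haptophytes and
#' Rhizaria; `GREEN` covers green algae (including prasinophytes) and land
#' plants; `RED` covers red algae only. Glaucophytes get their own code but
#' play no role in the classification rules. Cyanobacteria and other
#' eubacteria serve as rooting outgroups.
#'
#' @return A character vector of the nine group codes, in display order.
#' @export
#' @examples
#' lineage_groups()
lineage_groups <- function() {
  c("EUGLENID", "OTHER_EXCAVATA", "CR", "RED", "GREEN",
    "GLAUCOPHYTE", "UNIKONT", "CYANOBACTERIA", "OTHER_BACTERIA")
}

#' Human-readable names for the lineage group codes
#'
#' @return A tibble with columns `group` and `display_name`.
#' @export
lineage_group_names <- function() {
  tibble::tibble(
    group = lineage_groups(),
    display_name = c(
      "Euglenida", "other Excavata", "Chromalveolata + Rhizaria",
      "red algae", "green algae and land plants", "glaucophytes",
      "unikonts", "cyanobacteria", "other eubacteria"
    )
  )
}

#' Build a validated taxonomy map
#'
#' A taxonomy map relates OTU labels to a genus and one of the fixed lineage
#' groups (see [lineage_groups()]). Lookups of unregistered labels are errors,
#' never silent defaults, so a screen cannot quietly misbin a taxon.
#'
#' @param x A data frame with columns `otu_id`, `genus`, `group` and
#'   optionally `subgroup` (e.g. `"prasinophyte"`, `"nucleomorph"`; `NA` or
#'   `""` when not applicable).
#' @return A tibble of class `taxonomy_map` with columns `otu_id`, `genus`,
#'   `group`, `subgroup`.
#' @export
#' @examples
#' taxonomy_map(data.frame(
#'   otu_id = "Euglena_gracilis", genus = "Euglena", group = "EUGLENID"
#' ))
taxonomy_map <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("otu_id", "genus", "group")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("taxonomy is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "mosaic_config_error")
  }
  if (!"subgroup" %in% names(x)) x$subgroup <- NA_character_
  x <- x[, c("otu_id", "genus", "group", "subgroup")]
  x$subgroup <- dplyr::if_else(is.na(x$subgroup) | x$subgroup == "",
                               NA_character_, x$subgroup)
  if (anyDuplicated(x$otu_id)) {
    abort(paste0("duplicated OTU label(s): ",
                 paste(unique(x$otu_id[duplicated(x$otu_id)]), collapse = ", ")),
          class = "mosaic_config_error")
  }
  if (any(is.na(x$genus) | x$genus == "")) {
    abort("every OTU needs a non-empty genus", class = "mosaic_config_error")
  }
  bad <- setdiff(unique(x$group), lineage_groups())
  if (length(bad) > 0) {
    abort(paste0("unknown lineage group code(s): ", paste(bad, collapse = ", ")),
          class = "mosaic_config_error")
  }
  class(x) <- c("taxonomy_map", class(x))
  x
}

#' Look up the lineage group of an OTU
#'
#' @param otu_label One or more OTU labels.
#' @param taxonomy A [taxonomy_map()].
#' @return A character vector of group codes, same length as `otu_label`.
#'   Unregistered labels raise an error of class `mosaic_unknown_taxon`.
#' @export
#' @examples
#' tax <- default_taxonomy()
#' assign_group("Emiliania_huxleyi", tax)
assign_group <- function(otu_label, taxonomy) {
  idx <- match(otu_label, taxonomy$otu_id)
  if (anyNA(idx)) {
    abort(paste0("OTU label(s) not registered in the taxonomy: ",
                 paste(otu_label[is.na(idx)], collapse = ", ")),
          class = "mosaic_unknown_taxon")
  }
  taxonomy$group[idx]
}

#' Extract the genus token from an OTU label
#'
#' OTU labels follow the underscore-delimited `Genus_species[_suffix]`
#' convention, so the genus is the first underscore-delimited token. This is
#' what the single-genus clade collapsing rule keys on when no taxonomy row
#' is available.
#'
#' @param otu_label One or more OTU labels.
#' @return Character vector of genus tokens.
#' @export
#' @examples
#' genus_of("Ostreococcus_tauri_1")
genus_of <- function(otu_label) {
  bad <- is.na(otu_label) | otu_label == "" | !grepl("_", otu_label, fixed = TRUE)
  if (any(bad)) {
    abort(paste0("malformed OTU label(s) (need 'Genus_species'): ",
                 paste(sQuote(otu_label[bad]), collapse = ", ")),
          class = "mosaic_malformed_label")
  }
  sub("_.*$", "", otu_label)
}

genus_lookup <- function(otu_label, taxonomy) {
  idx <- match(otu_label, taxonomy$otu_id)
  if (anyNA(idx)) {
    abort(paste0("OTU label(s) not registered in the taxonomy: ",
                 paste(otu_label[is.na(idx)], collapse = ", ")),
          class = "mosaic_unknown_taxon")
  }
  taxonomy$genus[idx]
}

#' Read / write a taxonomy map as TSV
#'
#' The on-disk format is a UTF-8 TSV with columns `otu_id`, `genus`,
#' `group`, `subgroup` (empty allowed) and `#`-prefixed comment lines.
#'
#' @param path File path.
#' @return `read_taxonomy()` returns a [taxonomy_map()]; `write_taxonomy()`
#'   returns `path` invisibly.
#' @export
read_taxonomy <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  taxonomy_map(x)
}

#' @rdname read_taxonomy
#' @param taxonomy A [taxonomy_map()].
#' @export
write_taxonomy <- function(taxonomy, path) {
  out <- taxonomy
  out$subgroup[is.na(out$subgroup)] <- ""
  readr::write_tsv(tibble::as_tibble(unclass(out)), path)
  invisible(path)
}

#' Default taxonomy covering the taxa named in the euglenid screen
#'
#' Ships the OTU-to-group assignments for the organisms that recur in the
#' red-lineage gene trees: euglenids (including the aplastidic eukaryovore
#' *Peranema trichophorum*), other excavates, the CR assemblage
#' (stramenopiles, alveolates, cryptophytes and their nucleomorphs,
#' haptophytes, Rhizaria), red algae, green algae/land plants, glaucophytes,
#' unikonts and bacterial outgroups.
#'
#' @return A [taxonomy_map()].
#' @export
default_taxonomy <- function() {
  taxonomy_map(tibble::tribble(
    ~otu_id,                       ~genus,            ~group,           ~subgroup,
    "Euglena_gracilis",            "Euglena",         "EUGLENID",       NA,
    "Eutreptiella_gymnastica",     "Eutreptiella",    "EUGLENID",       NA,
    "Colacium_vesiculosum",        "Colacium",        "EUGLENID",       NA,
    "Peranema_trichophorum",       "Peranema",        "EUGLENID",       "eukaryovore",
    "Trypanosoma_brucei",          "Trypanosoma",     "OTHER_EXCAVATA", "kinetoplastid",
    "Leishmania_major",            "Leishmania",      "OTHER_EXCAVATA", "kinetoplastid",
    "Naegleria_gruberi",           "Naegleria",       "OTHER_EXCAVATA", "heterolobosean",
    "Giardia_intestinalis",        "Giardia",         "OTHER_EXCAVATA", NA,
    "Monocercomonoides_exilis",    "Monocercomonoides", "OTHER_EXCAVATA", NA,
    "Thalassiosira_pseudonana",    "Thalassiosira",   "CR",             "stramenopile",
    "Phaeodactylum_tricornutum",   "Phaeodactylum",   "CR",             "stramenopile",
    "Phytophthora_sojae",          "Phytophthora",    "CR",             "stramenopile",
    "Aureococcus_anophagefferens", "Aureococcus",     "CR",             "stramenopile",
    "Thraustochytrium_aureum",     "Thraustochytrium","CR",             "stramenopile",
    "Plasmodium_falciparum",       "Plasmodium",      "CR",             "alveolate",
    "Perkinsus_marinus",           "Perkinsus",       "CR",             "alveolate",
    "Lepidodinium_chlorophorum",   "Lepidodinium",    "CR",             "alveolate",
    "Guillardia_theta",            "Guillardia",      "CR",             "cryptophyte",
    "Guillardia_theta_nucleomorph","Guillardia",      "CR",             "nucleomorph",
    "Hemiselmis_andersenii_nucleomorph", "Hemiselmis", "CR",            "nucleomorph",
    "Emiliania_huxleyi",           "Emiliania",       "CR",             "haptophyte",
    "Bigelowiella_natans",         "Bigelowiella",    "CR",             "rhizarian",
    "Cyanidioschyzon_merolae",     "Cyanidioschyzon", "RED",            NA,
    "Galdieria_sulphuraria",       "Galdieria",       "RED",            NA,
    "Porphyra_yezoensis",          "Porphyra",        "RED",            NA,
    "Gracilaria_changii",          "Gracilaria",      "RED",            NA,
    "Chlamydomonas_reinhardtii",   "Chlamydomonas",   "GREEN",          NA,
    "Volvox_carteri",              "Volvox",          "GREEN",          NA,
    "Ostreococcus_tauri",          "Ostreococcus",    "GREEN",          "prasinophyte",
    "Ostreococcus_lucimarinus",    "Ostreococcus",    "GREEN",          "prasinophyte",
    "Micromonas_pusilla",          "Micromonas",      "GREEN",          "prasinophyte",
    "Pyramimonas_parkeae",         "Pyramimonas",     "GREEN",          "prasinophyte",
    "Arabidopsis_thaliana",        "Arabidopsis",     "GREEN",          "land plant",
    "Physcomitrella_patens",       "Physcomitrella",  "GREEN",          "land plant",
    "Cyanophora_paradoxa",         "Cyanophora",      "GLAUCOPHYTE",    NA,
    "Homo_sapiens",                "Homo",            "UNIKONT",        NA,
    "Monosiga_brevicollis",        "Monosiga",        "UNIKONT",        "choanoflagellate",
    "Saccharomyces_cerevisiae",    "Saccharomyces",   "UNIKONT",        NA,
    "Dictyostelium_discoideum",    "Dictyostelium",   "UNIKONT",        NA,
    "Synechocystis_sp",            "Synechocystis",   "CYANOBACTERIA",  NA,
    "Nostoc_punctiforme",          "Nostoc",          "CYANOBACTERIA",  NA,
    "Anabaena_variabilis",         "Anabaena",        "CYANOBACTERIA",  NA,
    "Prochlorococcus_marinus",     "Prochlorococcus", "CYANOBACTERIA",  NA,
    "Escherichia_coli",            "Escherichia",     "OTHER_BACTERIA", NA,
    "Bacillus_subtilis",           "Bacillus",        "OTHER_BACTERIA", NA
  ))
}
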