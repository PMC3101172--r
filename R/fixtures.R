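# The 14 red-lineage gene fixtures. Each newick encodes the verbally
# described topology of one gene tree from the euglenid screen's worked
# example: which taxa join the query in the defining euglenid+CR clade,
# what its sister group is, and which supports are strong versus
# unresolved. Basal splits are written as trifurcations so every
# bipartition appears exactly once. The ClpP topology is imputed from
# residue-level evidence (the underlying fragment is too short for a
# reliable tree) and flagged as such.

table1_fixture_specs <- function() {
  list(
    HPT = list(
      category = "CR_RED", peranema = FALSE,
      note = "homogentisate phytyltransferase; query within the CR sub-clade, CR+euglenid sister to red algae",
      newick = paste0(
        "(Synechocystis_sp:0.30,Nostoc_punctiforme:0.30,",
        "((Homo_sapiens:0.35,Saccharomyces_cerevisiae:0.35)98:0.25,",
        "(((Chlamydomonas_reinhardtii:0.20,Arabidopsis_thaliana:0.22)97:0.20,",
        "Ostreococcus_tauri:0.30)96:0.25,",
        "((Cyanidioschyzon_merolae:0.20,Porphyra_yezoensis:0.21)98:0.18,",
        "((Euglena_gracilis:0.16,(Thalassiosira_pseudonana:0.12,",
        "Emiliania_huxleyi:0.13)95:0.08)97:0.10,",
        "Bigelowiella_natans:0.22)96:0.15)98:0.20)95:0.18)97:0.40);")
    ),
    hypothetical_protein = list(
      category = "CR_RED", peranema = FALSE,
      note = "oxidoreductase-domain protein conserved in the red lineage incl. cryptophyte nucleomorphs; green plants on a separate branch",
      newick = paste0(
        "(Synechocystis_sp:0.32,Anabaena_variabilis:0.33,",
        "((Chlamydomonas_reinhardtii:0.24,Ostreococcus_tauri:0.26)95:0.30,",
        "((Porphyra_yezoensis:0.23,Gracilaria_changii:0.24)92:0.12,",
        "((Euglena_gracilis:0.20,(Guillardia_theta_nucleomorph:0.14,",
        "Hemiselmis_andersenii_nucleomorph:0.15)96:0.08)95:0.07,",
        "(Emiliania_huxleyi:0.15,Aureococcus_anophagefferens:0.16)93:0.09",
        ")96:0.11)97:0.16)94:0.28);")
    ),
    glucokinase = list(
      category = "CR_RED", peranema = FALSE,
      note = "prokaryote-type glucokinase conserved in primary and secondary algae; red-algal-like homologue also in Monosiga",
      newick = paste0(
        "(Escherichia_coli:0.45,Bacillus_subtilis:0.47,",
        "(Giardia_intestinalis:0.60,",
        "(Monosiga_brevicollis:0.42,",
        "((Cyanidioschyzon_merolae:0.25,Galdieria_sulphuraria:0.24)96:0.15,",
        "(Euglena_gracilis:0.21,(Thalassiosira_pseudonana:0.16,",
        "Phytophthora_sojae:0.17)94:0.10)97:0.12)98:0.14)88:0.10)93:0.30);")
    ),
    ClpP = list(
      category = "CR_RED", peranema = FALSE,
      note = "Clp protease proteolytic subunit; topology imputed from residue evidence shared with nucleomorph and pelagophyte sequences (fragment too short for a reliable tree)",
      newick = paste0(
        "(Synechocystis_sp:0.35,Prochlorococcus_marinus:0.36,",
        "((Chlamydomonas_reinhardtii:0.28,Micromonas_pusilla:0.27)94:0.22,",
        "((Cyanidioschyzon_merolae:0.26,Porphyra_yezoensis:0.27)95:0.13,",
        "(Euglena_gracilis:0.23,(Guillardia_theta_nucleomorph:0.17,",
        "Aureococcus_anophagefferens:0.18)92:0.08)96:0.10)97:0.15)93:0.30);")
    ),
    PRK = list(
      category = "CR_GREEN", peranema = FALSE,
      note = "phosphoribulokinase; query nests within the Chromalveolata clade, which branches with green algae rather than red algae",
      newick = paste0(
        "(Synechocystis_sp:0.30,Nostoc_punctiforme:0.31,",
        "((Cyanidioschyzon_merolae:0.28,Galdieria_sulphuraria:0.27)96:0.22,",
        "(((Ostreococcus_tauri:0.16,Micromonas_pusilla:0.17)95:0.12,",
        "Chlamydomonas_reinhardtii:0.25)96:0.14,",
        "(Euglena_gracilis:0.19,((Thalassiosira_pseudonana:0.13,",
        "Phaeodactylum_tricornutum:0.12)97:0.07,Emiliania_huxleyi:0.18",
        ")94:0.08)98:0.11)97:0.16)95:0.25);")
    ),
    FBT = list(
      category = "CR_GREEN", peranema = FALSE,
      note = "folate-biopterin transporter; query monophyletic with Perkinsus and Bigelowiella, the clade sister to prasinophyte sequences",
      newick = paste0(
        "(Escherichia_coli:0.50,Synechocystis_sp:0.45,",
        "((Arabidopsis_thaliana:0.30,Physcomitrella_patens:0.29)93:0.20,",
        "(((Ostreococcus_tauri:0.15,Ostreococcus_lucimarinus:0.14)98:0.10,",
        "Micromonas_pusilla:0.19)96:0.13,",
        "((Euglena_gracilis:0.18,(Perkinsus_marinus:0.14,",
        "Bigelowiella_natans:0.15)93:0.08)97:0.09,",
        "Thalassiosira_pseudonana:0.22)96:0.12)95:0.14)92:0.28);")
    ),
    ZEP = list(
      category = "RED_OTHER", peranema = FALSE,
      note = "zeaxanthin epoxidase; query nested among duplicated CR subclades, green affiliation unresolved (absent from red algae and cyanobacteria)",
      newick = paste0(
        "(Homo_sapiens:0.40,Monosiga_brevicollis:0.38,",
        "(((Ostreococcus_tauri:0.18,Micromonas_pusilla:0.17)97:0.22,",
        "Arabidopsis_thaliana:0.33)96:0.20,",
        "((Phytophthora_sojae:0.24,Aureococcus_anophagefferens:0.25)88:0.07,",
        "(Euglena_gracilis:0.19,(Thalassiosira_pseudonana:0.15,",
        "Phaeodactylum_tricornutum:0.14)96:0.09)97:0.08)55:0.06)50:0.25);")
    ),
    FBP_plastidic = list(
      category = "RED_OTHER", peranema = FALSE,
      note = "plastid-type fructose-1,6-bisphosphatase; query nested in the CR clade, basal resolution of the CR clade insufficient to verify the sister group",
      newick = paste0(
        "(Synechocystis_sp:0.36,Anabaena_variabilis:0.35,",
        "((Chlamydomonas_reinhardtii:0.27,Volvox_carteri:0.26)97:0.21,",
        "((Cyanidioschyzon_merolae:0.29,Gracilaria_changii:0.28)94:0.11,",
        "((Euglena_gracilis:0.20,(Thalassiosira_pseudonana:0.14,",
        "Phytophthora_sojae:0.15)93:0.08)96:0.09,",
        "(Emiliania_huxleyi:0.17,Aureococcus_anophagefferens:0.18)91:0.07",
        ")95:0.05)48:0.04)93:0.27);")
    ),
    FBP_cytosolic = list(
      category = "RED_OTHER", peranema = FALSE,
      note = "cytosolic fructose-1,6-bisphosphatase; query within the CR clade, sister group mixed/unresolved",
      newick = paste0(
        "(Escherichia_coli:0.48,Bacillus_subtilis:0.49,",
        "((Homo_sapiens:0.36,Saccharomyces_cerevisiae:0.37)96:0.18,",
        "(((Arabidopsis_thaliana:0.28,Chlamydomonas_reinhardtii:0.27)92:0.13,",
        "(Porphyra_yezoensis:0.29,Galdieria_sulphuraria:0.28)90:0.12)52:0.05,",
        "(Euglena_gracilis:0.21,((Phaeodactylum_tricornutum:0.13,",
        "Thalassiosira_pseudonana:0.14)96:0.07,Perkinsus_marinus:0.23",
        ")94:0.08)97:0.10)58:0.05)91:0.22);")
    ),
    GND = list(
      category = "RED_OTHER", peranema = TRUE,
      note = "6-phosphogluconate dehydrogenase; Peranema sequence monophyletic with the query inside the euglenid+CR clade, sister group unclear",
      newick = paste0(
        "(Synechocystis_sp:0.30,Nostoc_punctiforme:0.30,",
        "((Saccharomyces_cerevisiae:0.35,Homo_sapiens:0.36)98:0.25,",
        "(((Chlamydomonas_reinhardtii:0.22,Arabidopsis_thaliana:0.23)96:0.18,",
        "(Cyanidioschyzon_merolae:0.24,Porphyra_yezoensis:0.22)95:0.17)55:0.05,",
        "((Euglena_gracilis:0.10,Peranema_trichophorum:0.12)99:0.12,",
        "((Thalassiosira_pseudonana:0.14,Phaeodactylum_tricornutum:0.13)97:0.08,",
        "Emiliania_huxleyi:0.19)96:0.07)98:0.06)42:0.03)97:0.28);")
    ),
    ADP_ATP_transporter = list(
      category = "RED_OTHER", peranema = TRUE,
      note = "prokaryote-type ADP/ATP transporter found in euglenids and Chromalveolata; Peranema in the defining clade, deeper placement unsupported",
      newick = paste0(
        "(Escherichia_coli:0.40,Bacillus_subtilis:0.42,",
        "((Cyanidioschyzon_merolae:0.26,Galdieria_sulphuraria:0.25)96:0.12,",
        "((Euglena_gracilis:0.11,Peranema_trichophorum:0.13)99:0.14,",
        "((Thalassiosira_pseudonana:0.15,Phytophthora_sojae:0.16)95:0.07,",
        "Bigelowiella_natans:0.21)94:0.06)97:0.38)38:0.10);")
    ),
    LepA = list(
      category = "RED_OTHER", peranema = FALSE,
      note = "GTP-binding protein LepA/EF4, plastid clade; query nested in the CR subclade, sister group among photosynthetic lineages unresolved",
      newick = paste0(
        "(Escherichia_coli:0.52,Bacillus_subtilis:0.54,",
        "((Synechocystis_sp:0.30,Prochlorococcus_marinus:0.31)98:0.22,",
        "(((Arabidopsis_thaliana:0.26,Physcomitrella_patens:0.25)93:0.14,",
        "(Cyanidioschyzon_merolae:0.27,Porphyra_yezoensis:0.26)92:0.13)60:0.06,",
        "(Euglena_gracilis:0.18,(Thalassiosira_pseudonana:0.13,",
        "Emiliania_huxleyi:0.14)95:0.08)99:0.10)57:0.05)96:0.30);")
    ),
    MAT = list(
      category = "RED_OTHER", peranema = FALSE,
      note = "methionine adenosyltransferase (MATX form); query monophyletic with CR MATX with high support, family origin unclear",
      newick = paste0(
        "(Giardia_intestinalis:0.55,Trypanosoma_brucei:0.52,",
        "((Homo_sapiens:0.33,Saccharomyces_cerevisiae:0.34)97:0.20,",
        "(((Chlamydomonas_reinhardtii:0.27,Ostreococcus_tauri:0.28)91:0.12,",
        "(Porphyra_yezoensis:0.30,Cyanidioschyzon_merolae:0.29)90:0.11)49:0.05,",
        "(Euglena_gracilis:0.17,((Emiliania_huxleyi:0.14,",
        "Thalassiosira_pseudonana:0.15)96:0.07,Perkinsus_marinus:0.22",
        ")95:0.08)99:0.11)54:0.06)93:0.24);")
    ),
    fatty_acid_desaturase = list(
      category = "RED_OTHER", peranema = FALSE,
      note = "delta-4 fatty acid desaturase; query with Thalassiosira plus Thraustochytrium, indels not shared with other excavates, sister unresolved",
      newick = paste0(
        "(Trypanosoma_brucei:0.58,Leishmania_major:0.56,",
        "(Naegleria_gruberi:0.55,",
        "((Homo_sapiens:0.38,Monosiga_brevicollis:0.37)95:0.16,",
        "(((Ostreococcus_tauri:0.24,Micromonas_pusilla:0.23)94:0.15,",
        "(Porphyra_yezoensis:0.31,Galdieria_sulphuraria:0.30)89:0.12)51:0.06,",
        "(Euglena_gracilis:0.16,(Thalassiosira_pseudonana:0.12,",
        "Thraustochytrium_aureum:0.13)97:0.07)98:0.12)47:0.07)88:0.14)90:0.20);")
    )
  )
}

#' The 14 red-lineage gene tree fixtures of the worked example
#'
#' Builds the gene trees of the screen's worked example: four CR+Red
#' genes (HPT, a hypothetical oxidoreductase-domain protein, glucokinase,
#' ClpP), two CR+Green genes (PRK, FBT), and eight genes whose
#' euglenid+CR clade has an unclear sister group (ZEP, plastidic and
#' cytosolic FBP, GND, the ADP/ATP transporter, LepA, MAT, and a fatty
#' acid desaturase). The GND and ADP/ATP transporter trees carry a
#' *Peranema* sequence inside the defining clade. Supports are bootstrap
#' percentages; defining edges are >= 92 except where the described
#' topology requires an unresolved sister.
#'
#' @return A tibble: `gene_id`, `tree` (list of `ape::phylo`),
#'   `expected_category`, `expected_peranema`, `note`.
#' @export
#' @examples
#' fx <- make_table1_fixtures()
#' nrow(fx)
make_table1_fixtures <- function() {
  specs <- table1_fixture_specs()
  tibble::tibble(
    gene_id = names(specs),
    tree = purrr::map(specs, ~ set_support_scale(
      ape::read.tree(text = .x$newick), "bootstrap_pct")),
    expected_category = unname(purrr::map_chr(specs, "category")),
    expected_peranema = unname(purrr::map_lgl(specs, "peranema")),
    note = unname(purrr::map_chr(specs, "note"))
  )
}
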