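tax <- default_taxonomy()
QUERY <- "Euglena_gracilis"

test_that("rooting follows the outgroup preference order", {
  fx <- make_table1_fixtures()
  hpt <- fx$tree[[match("HPT", fx$gene_id)]]
  rooted <- root_tree(hpt, tax)
  expect_true(ape::is.rooted(rooted))
  # cyanobacteria split off first
  first_split <- rooted$tip.label[phangorn::Descendants(
    rooted, rooted$edge[1, 2], "tips")[[1]]]
  expect_true(all(assign_group(first_split, tax) == "CYANOBACTERIA") ||
                all(assign_group(setdiff(rooted$tip.label, first_split),
                                 tax) == "CYANOBACTERIA"))

  # no cyanobacteria or bacteria: unikonts root the ZEP tree
  zep <- fx$tree[[match("ZEP", fx$gene_id)]]
  cl <- classify_gene_tree(zep, QUERY, tax)
  expect_equal(cl$root_group_used, "UNIKONT")

  euk_only <- set_support_scale(ape::read.tree(text = paste0(
    "((Euglena_gracilis:1,Porphyra_yezoensis:1)90:1,",
    "(Ostreococcus_tauri:1,Micromonas_pusilla:1)90:1);")), "bootstrap_pct")
  expect_error(root_tree(euk_only, tax), class = "mosaic_no_outgroup")
  expect_error(classify_gene_tree(euk_only, QUERY, tax),
               class = "mosaic_no_outgroup")
})

test_that("red-lineage monophyly finds the smallest supported qualifying clade", {
  fx <- make_table1_fixtures()
  hpt <- fx$tree[[match("HPT", fx$gene_id)]]
  rm <- red_lineage_monophyly(hpt, QUERY, tax)
  expect_true(rm$found)
  expect_gte(rm$support, 70)
  expect_true(all(assign_group(setdiff(rm$clade, QUERY), tax) %in%
                    c("CR", "RED", "EUGLENID")))

  # query sister to green plants only: no CR/RED member anywhere
  green_tree <- set_support_scale(ape::read.tree(text = paste0(
    "(Synechocystis_sp:1,Nostoc_punctiforme:1,",
    "((Euglena_gracilis:1,Ostreococcus_tauri:1)95:1,",
    "(Micromonas_pusilla:1,Arabidopsis_thaliana:1)95:1)90:1);")),
    "bootstrap_pct")
  expect_false(red_lineage_monophyly(green_tree, QUERY, tax)$found)

  # a qualifying clade below threshold does not count
  weak <- set_all_supports(hpt, 65)
  expect_false(red_lineage_monophyly(weak, QUERY, tax)$found)
})

test_that("fixture trees classify into their described categories", {
  fx <- make_table1_fixtures()
  res <- classify_gene_trees(setNames(fx$tree, fx$gene_id), QUERY, tax)
  expect_equal(res$category, fx$expected_category)
  expect_equal(res$peranema_in_clade, fx$expected_peranema)
  # defining support meets the threshold for every red-lineage category
  red <- res$category %in% c("CR_RED", "CR_GREEN", "RED_OTHER")
  expect_true(all(res$defining_support[red] >= 70))
})

test_that("a query nested among green algae only is GREEN", {
  green_tree <- set_support_scale(ape::read.tree(text = paste0(
    "(Synechocystis_sp:1,Nostoc_punctiforme:1,",
    "((Euglena_gracilis:1,Ostreococcus_tauri:1)95:1,",
    "(Micromonas_pusilla:1,Arabidopsis_thaliana:1)95:1)90:1);")),
    "bootstrap_pct")
  cl <- classify_gene_tree(green_tree, QUERY, tax)
  expect_equal(cl$category, "GREEN")
})

test_that("red-only clades without CR members are not designated red-lineage", {
  # triose-phosphate-isomerase-like topology: query + red algae, no CR
  tim <- set_support_scale(ape::read.tree(text = paste0(
    "(Synechocystis_sp:1,Nostoc_punctiforme:1,",
    "(((Euglena_gracilis:1,(Porphyra_yezoensis:1,Cyanidioschyzon_merolae:1)96:1)97:1,",
    "(Ostreococcus_tauri:1,Arabidopsis_thaliana:1)95:1)92:1,Homo_sapiens:2)90:1);")),
    "bootstrap_pct")
  cl <- classify_gene_tree(tim, QUERY, tax)
  expect_equal(cl$category, "UNCLASSIFIED")
  expect_match(cl$notes, "red-only")
})

test_that("peranema co-clade flag keys on the genus inside the defining clade", {
  expect_true(peranema_coclade(c("Euglena_gracilis", "Peranema_trichophorum",
                                 "Emiliania_huxleyi"), tax))
  expect_false(peranema_coclade(c("Euglena_gracilis", "Emiliania_huxleyi"), tax))
  expect_false(peranema_coclade(character(), tax))
})

test_that("summaries count categories and Peranema flags consistently", {
  fx <- make_table1_fixtures()
  res <- classify_gene_trees(setNames(fx$tree, fx$gene_id), QUERY, tax)
  sm <- summarize_classifications(res)
  g <- glance(sm)
  expect_equal(g$cr_red, 4L)
  expect_equal(g$cr_green, 2L)
  expect_equal(g$red_other, 8L)
  expect_equal(g$red_lineage_total, 14L)
  expect_equal(g$peranema_coclade, 2L)
  expect_equal(sum(sm$counts$n_genes), nrow(res))

  empty <- summarize_classifications(
    tibble::tibble(gene_id = character(), category = character(),
                   peranema_in_clade = logical()))
  expect_equal(sum(empty$counts$n_genes), 0L)

  one <- summarize_classifications(
    tibble::tibble(gene_id = "g", category = "GREEN",
                   peranema_in_clade = FALSE))
  expect_equal(glance(one)$green, 1L)
  expect_equal(glance(one)$red_lineage_total, 0L)
})

test_that("support changes move categories monotonically", {
  fx <- make_table1_fixtures()
  red_cats <- c("CR_RED", "CR_GREEN", "RED_OTHER")
  for (k in seq_len(nrow(fx))) {
    tr <- fx$tree[[k]]
    base <- classify_gene_tree(tr, QUERY, tax)$category
    # raising every support never leaves the red-lineage set
    up <- classify_gene_tree(set_all_supports(tr, 100), QUERY, tax)$category
    if (base %in% red_cats) expect_true(up %in% red_cats)
    # lowering every support below threshold always yields UNCLASSIFIED
    down <- classify_gene_tree(set_all_supports(tr, 60), QUERY, tax)$category
    expect_equal(down, "UNCLASSIFIED")
  }
})

test_that("classification is invariant under leaf reordering", {
  fx <- make_table1_fixtures()
  for (k in c(1, 5, 10)) {
    tr <- fx$tree[[k]]
    rot <- set_support_scale(ape::ladderize(tr), "bootstrap_pct")
    expect_equal(classify_gene_tree(rot, QUERY, tax)$category,
                 fx$expected_category[k])
  }
})

test_that("posterior-scaled trees use the posterior threshold", {
  fx <- make_table1_fixtures()
  hpt <- fx$tree[[match("HPT", fx$gene_id)]]
  post_ok <- set_all_supports(hpt, 0.95, "posterior")
  expect_equal(classify_gene_tree(post_ok, QUERY, tax)$category, "CR_RED")
  post_low <- set_all_supports(hpt, 0.85, "posterior")
  expect_equal(classify_gene_tree(post_low, QUERY, tax)$category,
               "UNCLASSIFIED")
  # boundary is inclusive on both scales
  expect_equal(classify_gene_tree(set_all_supports(hpt, 0.9, "posterior"),
                                  QUERY, tax)$category, "CR_RED")
  expect_equal(classify_gene_tree(set_all_supports(hpt, 70),
                                  QUERY, tax)$category, "CR_RED")
})
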