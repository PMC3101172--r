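test_that("neighbor joining handles the 2- and 3-taxon closed forms", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- neighbor_joining(d2)
  expect_setequal(t2$tip.label, c("A", "B"))
  expect_equal(sum(t2$edge.length), 0.4)

  # pendant lengths a = (dAB + dAC - dBC)/2 etc.
  d3 <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d3["A", "B"] <- d3["B", "A"] <- 0.6
  d3["A", "C"] <- d3["C", "A"] <- 0.8
  d3["B", "C"] <- d3["C", "B"] <- 1.0
  t3 <- neighbor_joining(d3)
  pend <- setNames(t3$edge.length[t3$edge[, 2] <= 3],
                   t3$tip.label[t3$edge[t3$edge[, 2] <= 3, 2]])
  expect_equal(pend[["A"]], 0.2)
  expect_equal(pend[["B"]], 0.4)
  expect_equal(pend[["C"]], 0.6)
})

test_that("neighbor joining is exact on additive matrices", {
  # hand-built additive 4-taxon matrix from ((A:1,B:2):1,(C:3,D:4))
  d4 <- matrix(c(0, 3, 5, 6,
                 3, 0, 6, 7,
                 5, 6, 0, 7,
                 6, 7, 7, 0), 4, 4,
               dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  t4 <- neighbor_joining(d4)
  truth <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  expect_equal(phangorn::RF.dist(t4, ape::unroot(truth)), 0)
  # brute force over the 3 quartet topologies: AB|CD is the only one
  # admitting non-negative additive lengths reproducing d4
  got <- ape::cophenetic.phylo(t4)[rownames(d4), colnames(d4)]
  expect_equal(got, d4, tolerance = 1e-12)

  # random binary trees, branch lengths in [0.1, 2]: topology and lengths
  # recovered to 1e-9 from the path-length matrix
  for (seed in 1:30) {
    tr <- random_additive_tree(sample(4:12, 1), seed)
    njt <- neighbor_joining(additive_matrix(tr))
    expect_equal(phangorn::RF.dist(tr, njt), 0)
    d_in <- additive_matrix(tr)
    d_out <- ape::cophenetic.phylo(njt)[rownames(d_in), colnames(d_in)]
    expect_lt(max(abs(d_in - d_out)), 1e-9)
  }
})

test_that("neighbor joining agrees with ape's implementation on noisy matrices", {
  set.seed(23)
  for (rep_i in 1:5) {
    tr <- random_additive_tree(8, 100 + rep_i)
    d <- additive_matrix(tr)
    noise <- matrix(runif(64, 0, 0.02), 8, 8)
    noise <- (noise + t(noise)) / 2
    diag(noise) <- 0
    dn <- d + noise
    expect_equal(phangorn::RF.dist(neighbor_joining(dn), ape::nj(dn)), 0)
  }
})

test_that("invalid distance matrices are rejected", {
  d <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(neighbor_joining(d), class = "mosaic_invalid_matrix")
  dn <- matrix(c(0, NA, NA, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(neighbor_joining(dn), class = "mosaic_invalid_matrix")
  expect_error(neighbor_joining(matrix(0, 2, 2)), class = "mosaic_invalid_matrix")
})

test_that("bootstrap supports are deterministic, bounded and high for clear splits", {
  tr <- ape::read.tree(text = "((A_x:0.02,B_x:0.02):0.6,(C_x:0.02,D_x:0.02):0.6);")
  set.seed(5)
  aln <- protein_msa(toupper(as.character(phangorn::simSeq(tr, l = 300, type = "AA"))))
  bt1 <- bootstrap_supports(aln, n_reps = 100, seed = 11)
  bt2 <- bootstrap_supports(aln, n_reps = 100, seed = 11)
  expect_identical(ape::write.tree(bt1), ape::write.tree(bt2))
  sup <- suppressWarnings(as.numeric(bt1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  expect_equal(supported_bipartition(bt1, c("A_x", "B_x"), 70), "present")
  expect_true(all(sup == 100))  # long internal branch: every replicate finds it

  # invariance under leaf-order permutation of the alignment
  perm <- protein_msa(unclass(aln)[c(3, 1, 4, 2), ])
  bt3 <- bootstrap_supports(perm, n_reps = 100, seed = 11)
  key_sup <- function(tree) {
    bp <- mosaicscreen:::tree_bipartitions(tree)
    setNames(tree$node.label[bp$node - length(tree$tip.label)], bp$key)
  }
  expect_equal(key_sup(bt3), key_sup(bt1))
  expect_error(bootstrap_supports(aln, n_reps = 0), class = "mosaic_config_error")
})

test_that("patristic distances are path sums, symmetric and four-point", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  expect_equal(patristic_distance(tr, "A", "A"), 0)
  expect_equal(patristic_distance(tr, "A", "C"), 5)
  expect_equal(patristic_distance(tr, "C", "A"), 5)
  expect_error(patristic_distance(tr, "A", "Zq"), class = "mosaic_unknown_taxon")

  for (seed in 1:10) {
    tr <- random_additive_tree(9, 300 + seed)
    tips <- tr$tip.label
    pick <- sample(tips, 4)
    d <- function(x, y) patristic_distance(tr, x, y)
    # agreement with an independent path-walking oracle
    expect_equal(d(pick[1], pick[2]),
                 brute_patristic(tr, pick[1], pick[2]), tolerance = 1e-12)
    # four-point condition: the two largest of the three pairings tie
    s1 <- d(pick[1], pick[2]) + d(pick[3], pick[4])
    s2 <- d(pick[1], pick[3]) + d(pick[2], pick[4])
    s3 <- d(pick[1], pick[4]) + d(pick[2], pick[3])
    sums <- sort(c(s1, s2, s3), decreasing = TRUE)
    expect_equal(sums[1], sums[2], tolerance = 1e-9)
  }
})

test_that("single-genus clades collapse to one representative, protecting the query", {
  tax <- default_taxonomy()
  tr <- ape::read.tree(text = paste0(
    "(((Ostreococcus_tauri:1,Ostreococcus_lucimarinus:1):1,",
    "(Micromonas_pusilla:1,(Arabidopsis_thaliana:1,Euglena_gracilis:1):1):1):1,",
    "(Porphyra_yezoensis:1,Cyanidioschyzon_merolae:1):1);"))
  out <- collapse_single_genus_clades(tr, tax, protected = "Euglena_gracilis")
  kept_ostreo <- grep("Ostreococcus", out$tip.label, value = TRUE)
  expect_equal(kept_ostreo, "Ostreococcus_lucimarinus")  # lexicographic representative
  expect_true("Euglena_gracilis" %in% out$tip.label)
  # genus-mixed clades untouched
  expect_true(all(c("Porphyra_yezoensis", "Cyanidioschyzon_merolae") %in%
                    out$tip.label))

  # output bipartitions equal the input's restricted to retained leaves
  bip_keys <- function(tree) {
    ntip <- length(tree$tip.label)
    keep <- out$tip.label
    ref <- min(keep)
    ks <- purrr::map_chr(mosaicscreen:::tree_bipartitions(tree)$tips, function(tp) {
      s <- intersect(tp, keep)
      if (ref %in% s) s <- setdiff(keep, s)
      if (length(s) <= 1 || length(s) >= length(keep) - 1) return(NA_character_)
      paste(sort(s), collapse = "|")
    })
    sort(unique(ks[!is.na(ks)]))
  }
  expect_equal(bip_keys(out), bip_keys(tr))

  # tree whose every clade is genus-mixed is unchanged
  mixed <- ape::read.tree(text = paste0(
    "((Euglena_gracilis:1,Porphyra_yezoensis:1):1,",
    "(Micromonas_pusilla:1,Cyanidioschyzon_merolae:1):1);"))
  out2 <- collapse_single_genus_clades(mixed, tax, protected = "Euglena_gracilis")
  expect_setequal(out2$tip.label, mixed$tip.label)
})

test_that("nested single-genus clades collapse without touching mixed parents", {
  tax <- taxonomy_map(tibble::tibble(
    otu_id = c("Micromonas_a", "Micromonas_b", "Micromonas_c",
               "Porphyra_a", "Euglena_gracilis", "Synechocystis_a"),
    genus = c("Micromonas", "Micromonas", "Micromonas", "Porphyra",
              "Euglena", "Synechocystis"),
    group = c("GREEN", "GREEN", "GREEN", "RED", "EUGLENID", "CYANOBACTERIA")))
  tr <- ape::read.tree(text = paste0(
    "((((Micromonas_a:1,Micromonas_b:1):1,Micromonas_c:1):1,Porphyra_a:1):1,",
    "(Euglena_gracilis:1,Synechocystis_a:1):1);"))
  out <- collapse_single_genus_clades(tr, tax, protected = "Euglena_gracilis")
  expect_equal(sum(startsWith(out$tip.label, "Micromonas")), 1L)
  expect_true("Porphyra_a" %in% out$tip.label)
  expect_equal(length(out$tip.label), 4L)
})

test_that("supported bipartitions use inclusive thresholds on the tree's scale", {
  tr <- set_support_scale(ape::read.tree(
    text = "((A_x:1,B_x:1)70:1,(C_x:1,D_x:1)65:1,E_x:2);"), "bootstrap_pct")
  expect_equal(supported_bipartition(tr, "A_x", 70), "present")  # singleton
  expect_equal(supported_bipartition(tr, c("A_x", "B_x"), 70), "present")
  expect_equal(supported_bipartition(tr, c("C_x", "D_x"), 70),
               "present_unsupported")
  expect_equal(supported_bipartition(tr, c("A_x", "C_x"), 70), "absent")
  # complement side names the same split
  expect_equal(supported_bipartition(tr, c("C_x", "D_x", "E_x"), 70), "present")
  expect_error(supported_bipartition(tr, tr$tip.label, 70),
               class = "mosaic_invalid_taxa_set")
  expect_error(supported_bipartition(tr, character(), 70),
               class = "mosaic_invalid_taxa_set")
})

test_that("newick round-trip preserves supports and branch lengths", {
  txt <- "((A_x:0.1,B_x:0.2)95:0.3,(C_x:0.4,D_x:0.5)40:0.6,E_x:0.7);"
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines(txt, path)
  tr <- read_gene_tree(path)
  expect_equal(attr(tr, "support_scale"), "bootstrap_pct")
  out_path <- withr::local_tempfile(fileext = ".nwk")
  write_gene_tree(tr, out_path)
  expect_equal(ape::write.tree(ape::read.tree(out_path)), ape::write.tree(tr))
})
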