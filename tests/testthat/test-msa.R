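test_that("column trimming keeps exactly the columns at or below the gap threshold", {
  gapless <- tiny_aln(c(A_x = "MKLVARWQYT", B_x = "MKLVARWQYT",
                        C_x = "MKIVARWQYT", D_x = "MKLVPRWQYT"))
  expect_equal(unclass(trim_gappy_columns(gapless, 0.5)), unclass(gapless))

  # one column with 3/4 gaps (fraction 0.75) goes at threshold 0.5
  aln <- tiny_aln(c(A_x = "M-KL", B_x = "M-KL", C_x = "M-KL", D_x = "MAKL"))
  trimmed <- trim_gappy_columns(aln, 0.5)
  expect_equal(ncol(trimmed), 3L)
  expect_equal(rownames(trimmed), rownames(aln))
  expect_equal(unclass(trim_gappy_columns(aln, 1.0)), unclass(aln))

  all_gap <- tiny_aln(c(A_x = "--", B_x = "--", C_x = "--", D_x = "--"))
  expect_error(trim_gappy_columns(all_gap, 0.5), class = "mosaic_empty_alignment")

  # idempotence: trimming twice with the same threshold changes nothing
  set.seed(41)
  chars <- matrix(sample(c("A", "C", "-", "G"), 8 * 40, replace = TRUE,
                         prob = c(.4, .3, .25, .05)),
                  nrow = 8, dimnames = list(sprintf("T%d_x", 1:8), NULL))
  r <- protein_msa(chars)
  once <- trim_gappy_columns(r, 0.3)
  expect_equal(unclass(trim_gappy_columns(once, 0.3)), unclass(once))
})

test_that("taxon trimming drops gappy rows but never the protected query", {
  aln <- tiny_aln(c(Euglena_gracilis = "MKLVARWQYT",
                    A_x = "MKLVARWQYT", B_x = "MKIVARWQYT",
                    C_x = "MKLVPRWQYT", D_x = "M---------"))
  kept <- drop_gappy_taxa(aln, 0.8, query = "Euglena_gracilis")
  expect_false("D_x" %in% rownames(kept))
  expect_equal(nrow(kept), 4L)

  none <- drop_gappy_taxa(aln, 0.95, query = "Euglena_gracilis")
  expect_equal(rownames(none), rownames(aln))

  gappy_query <- tiny_aln(c(Euglena_gracilis = "M---------",
                            A_x = "MKLVARWQYT", B_x = "MKIVARWQYT",
                            C_x = "MKLVPRWQYT", D_x = "MKLVPRWQYA"))
  expect_error(drop_gappy_taxa(gappy_query, 0.8, query = "Euglena_gracilis"),
               class = "mosaic_query_too_gappy")

  few <- tiny_aln(c(A_x = "MKLV", B_x = "MKLV", C_x = "M---", D_x = "M---"))
  expect_error(drop_gappy_taxa(few, 0.5), class = "mosaic_too_few_taxa")
})

test_that("protein distances use pairwise deletion and the Poisson correction", {
  ident <- tiny_aln(c(A_x = "MKLVA", B_x = "MKLVA"))
  expect_equal(pairwise_distance(ident, "p_distance")["A_x", "B_x"], 0)
  expect_equal(pairwise_distance(ident, "poisson")["A_x", "B_x"], 0)

  # 10 comparable columns, 5 mismatches -> p = 0.5
  half <- tiny_aln(c(A_x = "AAAAAAAAAA", B_x = "AAAAACCCCC"))
  expect_equal(pairwise_distance(half, "p_distance")["A_x", "B_x"], 0.5)
  expect_equal(pairwise_distance(half, "poisson")["A_x", "B_x"], -log(0.5))

  # gap and X columns are excluded from the comparison
  gx <- tiny_aln(c(A_x = "AXAA-C", B_x = "ACA-AC"))  # comparable: cols 1,3,6
  expect_equal(pairwise_distance(gx, "p_distance")["A_x", "B_x"], 0)

  no_overlap <- tiny_aln(c(A_x = "AA--", B_x = "--CC"))
  expect_error(pairwise_distance(no_overlap), class = "mosaic_no_overlap")

  # saturation cap keeps the matrix finite
  sat <- tiny_aln(c(A_x = paste(rep("A", 200), collapse = ""),
                    B_x = paste(rep("C", 200), collapse = "")))
  expect_equal(pairwise_distance(sat, "poisson")["A_x", "B_x"], -log(0.01))

  # properties on random alignments: p in [0,1], poisson >= p, symmetry,
  # agreement with ape's independent p-distance implementation
  set.seed(17)
  aa20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  for (rep_i in 1:5) {
    chars <- matrix(sample(c(aa20, "-"), 6 * 80, replace = TRUE),
                    nrow = 6, dimnames = list(sprintf("T%d_x", 1:6), NULL))
    aln <- protein_msa(chars)
    p <- pairwise_distance(aln, "p_distance")
    pois <- pairwise_distance(aln, "poisson")
    expect_true(all(p >= 0 & p <= 1))
    expect_true(all(pois - p >= -1e-12))
    expect_equal(p, t(p))
    # independent oracle: explicit per-pair column loop
    ref <- matrix(0, nrow(aln), nrow(aln))
    for (i in seq_len(nrow(aln) - 1)) {
      for (j in (i + 1):nrow(aln)) {
        ri <- unclass(aln)[i, ]
        rj <- unclass(aln)[j, ]
        comp <- ri %in% aa20 & rj %in% aa20
        ref[i, j] <- ref[j, i] <- sum(ri[comp] != rj[comp]) / sum(comp)
      }
    }
    expect_equal(unname(p), ref, tolerance = 1e-12)
  }
})

test_that("shared indel signatures are exclusive, maximal and disjoint", {
  gapless <- tiny_aln(c(A_x = "MKLVA", B_x = "MKLVA", C_x = "MKIVA"))
  sig <- find_shared_indels(gapless, c("A_x", "B_x"))
  expect_equal(nrow(sig), 0L)

  # a 3-column gap carried by exactly the candidates: one deletion block
  aln <- tiny_aln(c(A_x = "MK---VA", B_x = "MK---VA",
                    C_x = "MKRRRVA", D_x = "MKRRRVA"))
  sig <- find_shared_indels(aln, c("A_x", "B_x"))
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$start_col, 2L)
  expect_equal(sig$end_col, 5L)
  expect_equal(sig$state, "deletion_block")
  expect_equal(sig$carriers[[1]], c("A_x", "B_x"))

  # the converse orientation is an insertion block
  ins <- find_shared_indels(aln, c("C_x", "D_x"))
  expect_equal(ins$state, "insertion_block")
  expect_equal(ins$start_col, 2L)

  # a gap column shared by every row is not discriminative
  univ <- tiny_aln(c(A_x = "M-KV", B_x = "M-KV", C_x = "M-KV", D_x = "M-KV"))
  expect_equal(nrow(find_shared_indels(univ, c("A_x", "B_x"))), 0L)

  # maximality: extending either endpoint breaks the carrier condition
  two <- tiny_aln(c(A_x = "A--C--G", B_x = "A--C--G", C_x = "ARRCRRG"))
  sig2 <- find_shared_indels(two, c("A_x", "B_x"))
  expect_equal(nrow(sig2), 2L)
  expect_true(all(sig2$end_col[-nrow(sig2)] <= sig2$start_col[-1]))
  expect_equal(nrow(find_shared_indels(two, c("A_x", "B_x"), min_len = 3L)), 0L)

  expect_error(find_shared_indels(aln, character()),
               class = "mosaic_invalid_candidate_set")
  expect_error(find_shared_indels(aln, rownames(aln)),
               class = "mosaic_invalid_candidate_set")
})

test_that("aligned FASTA round-trips with row order preserved", {
  aln <- tiny_aln(c(Euglena_gracilis = paste(rep("MKLVARWQYT", 9), collapse = ""),
                    Zeta_sp = paste(rep("MKIVARWQYT", 9), collapse = ""),
                    Alpha_sp = paste(rep("MK-VARW-YT", 9), collapse = "")))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, path)
  lines <- readLines(path)
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 60))
  back <- read_alignment(path)
  expect_equal(unclass(back), unclass(aln))
  expect_equal(rownames(back), rownames(aln))  # not resorted
})
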