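AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                "M", "F", "P", "S", "T", "W", "Y", "V")

#' Construct a protein multiple alignment
#'
#' Alignments are stored as an uppercase character matrix (rows = OTUs,
#' columns = aligned sites) over the 20 amino-acid letters plus `-` (gap)
#' and `X` (ambiguous/unknown residue). All rows must have equal length and
#' unique labels.
#'
#' @param x A named character vector of aligned sequences, a character
#'   matrix with rownames, or a data frame with columns `otu_id` and `seq`.
#' @return An object of class `protein_msa`.
#' @export
#' @examples
#' protein_msa(c(Euglena_gracilis = "MK-LV", Porphyra_yezoensis = "MKRLV"))
protein_msa <- function(x) {
  if (is.data.frame(x)) {
    x <- setNames(as.character(x$seq), x$otu_id)
  }
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x)) || any(names(x) == "")) {
      abort("aligned sequences must be named by OTU", class = "mosaic_config_error")
    }
    lens <- nchar(x)
    if (length(unique(lens)) != 1) {
      abort("alignment rows have unequal lengths", class = "mosaic_alignment_error")
    }
    m <- matrix(unlist(strsplit(toupper(x), "", fixed = TRUE)),
                nrow = length(x), byrow = TRUE,
                dimnames = list(names(x), NULL))
  } else if (is.matrix(x)) {
    if (is.null(rownames(x))) {
      abort("alignment matrix needs OTU rownames", class = "mosaic_config_error")
    }
    m <- x
    m[] <- toupper(m)
  } else {
    abort("cannot build an alignment from this input", class = "mosaic_config_error")
  }
  if (ncol(m) < 1) abort("alignment has zero columns", class = "mosaic_alignment_error")
  if (anyDuplicated(rownames(m))) {
    abort("duplicated OTU labels in alignment", class = "mosaic_alignment_error")
  }
  bad <- setdiff(unique(as.vector(m)), c(AA_LETTERS, "-", "X"))
  if (length(bad) > 0) {
    abort(paste0("non-amino-acid characters in alignment: ",
                 paste(bad, collapse = " ")), class = "mosaic_alignment_error")
  }
  structure(m, class = c("protein_msa", "matrix", "array"))
}

#' @export
print.protein_msa <- function(x, ...) {
  cat("protein alignment:", nrow(x), "OTUs x", ncol(x), "columns\n")
  show <- utils::head(rownames(x), 8)
  for (r in show) {
    s <- paste(x[r, seq_len(min(50, ncol(x)))], collapse = "")
    cat(sprintf("  %-30s %s%s\n", r, s, if (ncol(x) > 50) "..." else ""))
  }
  if (nrow(x) > 8) cat("  ...", nrow(x) - 8, "more rows\n")
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.protein_msa <- function(x, ...) {
  tibble::tibble(otu_id = rownames(x),
                 seq = apply(unclass(x), 1, paste, collapse = ""))
}

msa_seq_strings <- function(aln) {
  setNames(apply(unclass(aln), 1, paste, collapse = ""), rownames(aln))
}

#' Read / write an aligned protein FASTA
#'
#' Reading goes through `Biostrings::readAAStringSet()`; writing wraps
#' sequence lines at 60 columns and preserves row order.
#'
#' @param path FASTA file path.
#' @return `read_alignment()` returns a [protein_msa()]; `write_alignment()`
#'   returns `path` invisibly.
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  protein_msa(setNames(as.character(ss), sub("\\s.*$", "", names(ss))))
}

#' @rdname read_alignment
#' @param aln A [protein_msa()].
#' @export
write_alignment <- function(aln, path) {
  ss <- Biostrings::AAStringSet(msa_seq_strings(aln))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

gap_frac_by_col <- function(aln) colMeans(unclass(aln) == "-")
gap_frac_by_row <- function(aln) rowMeans(unclass(aln) == "-")

#' Remove indel-rich alignment columns
#'
#' Retains exactly the columns whose gap fraction is `<= max_gap_frac`;
#' row order and labels are preserved. This is the automated "indel-rich
#' site" removal step that precedes distance and tree estimation.
#'
#' @param aln A [protein_msa()].
#' @param max_gap_frac Maximum tolerated fraction of gap characters per
#'   column, in `[0, 1]`. Default 0.5.
#' @return A trimmed [protein_msa()].
#' @export
trim_gappy_columns <- function(aln, max_gap_frac = 0.5) {
  stopifnot(inherits(aln, "protein_msa"))
  if (max_gap_frac < 0 || max_gap_frac > 1) {
    abort("max_gap_frac must be in [0, 1]", class = "mosaic_config_error")
  }
  keep <- gap_frac_by_col(aln) <= max_gap_frac
  if (!any(keep)) {
    abort("all alignment columns exceed the gap threshold",
          class = "mosaic_empty_alignment")
  }
  protein_msa(unclass(aln)[, keep, drop = FALSE])
}

#' Remove indel-rich taxa from an alignment
#'
#' Drops rows whose gap fraction exceeds `max_gap_frac`. The designated
#' query row is never dropped: if the query itself exceeds the threshold
#' the alignment is unusable for that gene and an error of class
#' `mosaic_query_too_gappy` is raised.
#'
#' @inheritParams trim_gappy_columns
#' @param max_gap_frac Maximum tolerated per-row gap fraction. Default 0.75.
#' @param query Optional OTU label of the protected query row.
#' @return A [protein_msa()] with gappy taxa removed.
#' @export
drop_gappy_taxa <- function(aln, max_gap_frac = 0.75, query = NULL) {
  stopifnot(inherits(aln, "protein_msa"))
  gf <- gap_frac_by_row(aln)
  if (!is.null(query)) {
    if (!query %in% rownames(aln)) {
      abort(paste0("query ", sQuote(query), " is not in the alignment"),
            class = "mosaic_unknown_taxon")
    }
    if (gf[query] > max_gap_frac) {
      abort(paste0("query row ", sQuote(query), " exceeds the gap threshold (",
                   signif(gf[query], 3), " > ", max_gap_frac, ")"),
            class = "mosaic_query_too_gappy")
    }
  }
  keep <- gf <= max_gap_frac
  if (!is.null(query)) keep[query] <- TRUE
  out <- unclass(aln)[keep, , drop = FALSE]
  if (nrow(out) < 4) {
    abort(paste0("fewer than 4 taxa remain after trimming (",
                 nrow(out), ")"), class = "mosaic_too_few_taxa")
  }
  protein_msa(out)
}

#' Pairwise protein distances from an alignment
#'
#' Pairs are compared only on columns where both rows carry an unambiguous
#' residue (`-` and `X` are treated as missing). `p_distance` is the
#' mismatch fraction over compared columns; `poisson` applies the
#' correction `-log(1 - p)`, capped at `-log(0.01)` once `p >= 0.99` so
#' saturated pairs stay finite.
#'
#' @param aln A [protein_msa()] with at least 2 rows.
#' @param model `"poisson"` (default) or `"p_distance"`.
#' @return A symmetric numeric matrix with OTU dimnames and zero diagonal.
#' @export
pairwise_distance <- function(aln, model = c("poisson", "p_distance")) {
  model <- match.arg(model)
  stopifnot(inherits(aln, "protein_msa"))
  if (nrow(aln) < 2) abort("need at least 2 sequences", class = "mosaic_config_error")
  m <- unclass(aln)
  n <- nrow(m)
  # one-hot encode residues; crossprod gives match and comparable counts for
  # all pairs at once
  ok <- (m != "-") & (m != "X")
  codes <- match(m, AA_LETTERS)            # NA for gap/X
  L <- ncol(m)
  onehot <- matrix(0L, nrow = n, ncol = L * 20L)
  idx <- which(!is.na(codes))
  onehot[cbind(((idx - 1L) %% n) + 1L,
               (((idx - 1L) %/% n)) * 20L + codes[idx])] <- 1L
  matches <- tcrossprod(onehot)
  comparable <- tcrossprod(ok * 1L)
  offdiag <- upper.tri(comparable)
  if (any(comparable[offdiag] == 0)) {
    bad <- which(comparable == 0 & offdiag, arr.ind = TRUE)[1, ]
    abort(paste0("no comparable columns between ", sQuote(rownames(m)[bad[1]]),
                 " and ", sQuote(rownames(m)[bad[2]])),
          class = "mosaic_no_overlap")
  }
  p <- 1 - matches / comparable
  diag(p) <- 0
  d <- if (model == "p_distance") {
    p
  } else {
    pc <- pmin(p, 0.99)
    ifelse(p >= 0.99, -log(0.01), -log1p(-pc))
  }
  diag(d) <- 0
  d <- (d + t(d)) / 2  # enforce exact symmetry against float noise
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Find indel blocks shared exclusively by a candidate OTU set
#'
#' Scans the alignment for maximal runs of columns that discriminate the
#' candidate set from every other row: a `deletion_block` is a run where
#' every candidate is gapped and every non-candidate carries a residue; an
#' `insertion_block` is the converse. Shared indels of this kind are used
#' as independent evidence that the candidate taxa form a clade.
#' Columns gapped (or residue-bearing) in *all* rows are not discriminative
#' and never appear in a signature.
#'
#' @param aln A [protein_msa()].
#' @param candidate_set Character vector of OTU labels; must be a proper,
#'   non-empty subset of the alignment rows.
#' @param min_len Minimum run length (columns) to report. Default 1.
#' @return A tibble with columns `start_col`, `end_col` (0-based half-open),
#'   `state` and `carriers` (list column), one row per signature.
#' @export
find_shared_indels <- function(aln, candidate_set, min_len = 1L) {
  stopifnot(inherits(aln, "protein_msa"))
  rows <- rownames(aln)
  if (length(candidate_set) == 0 || !all(candidate_set %in% rows) ||
      length(candidate_set) >= length(rows)) {
    abort("candidate_set must be a non-empty proper subset of alignment rows",
          class = "mosaic_invalid_candidate_set")
  }
  m <- unclass(aln) == "-"
  in_set <- rows %in% candidate_set
  del <- colSums(m[in_set, , drop = FALSE]) == sum(in_set) &
    colSums(m[!in_set, , drop = FALSE]) == 0
  ins <- colSums(m[in_set, , drop = FALSE]) == 0 &
    colSums(m[!in_set, , drop = FALSE]) == sum(!in_set)
  runs_of <- function(flag, state) {
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_len
    if (!any(keep)) return(NULL)
    tibble::tibble(start_col = starts[keep] - 1L, end_col = ends[keep],
                   state = state)
  }
  out <- dplyr::bind_rows(runs_of(del, "deletion_block"),
                          runs_of(ins, "insertion_block"))
  if (nrow(out) == 0) {
    return(tibble::tibble(start_col = integer(), end_col = integer(),
                          state = character(), carriers = list()))
  }
  out <- dplyr::arrange(out, .data$start_col)
  out$carriers <- rep(list(sort(candidate_set)), nrow(out))
  out
}

#' Write indel signatures as TSV
#'
#' @param signatures Output of [find_shared_indels()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_indel_signatures <- function(signatures, path) {
  out <- signatures
  out$carriers <- purrr::map_chr(out$carriers, paste, collapse = ",")
  readr::write_tsv(out, path)
  invisible(path)
}
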