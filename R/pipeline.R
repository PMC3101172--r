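log_line <- function(level, event, ..., .min_level = "info") {
  levels <- c(quiet = 0, info = 1, debug = 2)
  if (levels[[.min_level]] < 1) return(invisible(NULL))
  payload <- c(list(level = level, event = event), list(...))
  message(jsonlite::toJSON(payload, auto_unbox = TRUE))
  invisible(NULL)
}

config_get <- function(config, path, default = NULL, required = FALSE) {
  node <- config
  for (key in strsplit(path, ".", fixed = TRUE)[[1]]) {
    if (!is.list(node) || is.null(node[[key]])) {
      if (required) {
        abort(paste0("config field missing: ", path),
              class = "mosaic_config_error")
      }
      return(default)
    }
    node <- node[[key]]
  }
  node
}

digest_of <- function(...) {
  parts <- list(...)
  txt <- paste(vapply(parts, function(p) {
    if (is.character(p) && length(p) == 1 && file.exists(p)) {
      unname(tools::md5sum(p))
    } else {
      paste(utils::capture.output(dput(p)), collapse = "")
    }
  }, character(1)), collapse = "&")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(txt, tf)
  unname(tools::md5sum(tf))
}

write_screen_report <- function(report, path) {
  out <- report
  out$tied_otus <- purrr::map_chr(out$tied_otus, paste, collapse = ",")
  out$tree <- NULL
  con <- file(path, "w")
  writeLines("# closest taxon rule: nearest single OTU by patristic distance (not nearest-clade majority)", con)
  close(con)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

write_classification_report <- function(classifications, path) {
  out <- classifications
  out$clade <- purrr::map_chr(out$clade, paste, collapse = ",")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Run the full mosaicism screen pipeline
#'
#' Orchestrates simulate (or ingest) -> screen -> classify -> report as a
#' single reproducible run. The configuration is a YAML file (or an
#' equivalent nested list) with a master `seed`, a `query` label, either
#' a `simulate:` section (scenario parameters for a planted benchmark) or
#' an `input:` section (`alignments_dir`, `taxonomy`), and optional
#' `screen:` / `classify:` parameter sections mirroring [screen_config()]
#' and [classify_config()]. Completed stages are recorded with input
#' digests in `manifest.json`; re-running with an unchanged config reuses
#' completed stage outputs, and per-gene failures are recorded in
#' `errors.tsv` without aborting the remaining genes.
#'
#' @param config Path to a YAML config file, or a nested list.
#' @param out_dir Output directory; overrides `out_dir` in the config.
#' @param log_level `"info"` (ndjson log lines on stderr) or `"quiet"`.
#' @return The run manifest, invisibly: config snapshot, seed, per-stage
#'   input digests and output paths, package version.
#' @export
run_pipeline <- function(config, out_dir = NULL, log_level = "info") {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      abort(paste0("config file not found: ", config),
            class = "mosaic_config_error")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    abort("config must be a YAML file path or a list", class = "mosaic_config_error")
  }
  out_dir <- out_dir %||% config_get(config, "out_dir", required = TRUE)
  seed <- config_get(config, "seed", default = 1L)
  query <- config_get(config, "query", default = "Euglena_gracilis")
  has_sim <- !is.null(config_get(config, "simulate"))
  has_input <- !is.null(config_get(config, "input"))
  if (has_sim == has_input) {
    abort("config needs exactly one of 'simulate' or 'input'",
          class = "mosaic_config_error")
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "alignments"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "trees"), showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)
  } else {
    list(tool = "mosaicscreen",
         version = as.character(utils::packageVersion("mosaicscreen")),
         seed = seed, config = config, stages = list())
  }
  save_manifest <- function() {
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  stage_current <- function(name, digest, outputs) {
    st <- manifest$stages[[name]]
    !is.null(st) && identical(st$digest, digest) &&
      all(file.exists(unlist(st$outputs))) &&
      setequal(unlist(st$outputs), outputs)
  }

  screen_opts <- config_get(config, "screen", default = list())
  screen_opts$seed <- NULL
  scfg <- do.call(screen_config, c(screen_opts, list(seed = seed)))
  ccfg <- do.call(classify_config, config_get(config, "classify", default = list()))

  # ---- stage 1: simulate or ingest ------------------------------------
  tax_path <- file.path(out_dir, "taxonomy.tsv")
  if (has_sim) {
    sim <- config_get(config, "simulate")
    n_per_label <- sim$n_per_label %||% 2L
    tmpl <- scenario(
      "VERTICAL",
      internal_branch = sim$internal_branch %||% 0.5,
      tip_branch_mean = sim$tip_branch_mean %||% 0.2,
      seq_length = sim$seq_length %||% 500L,
      indel_rate = sim$indel_rate %||% 0.2,
      model = sim$model %||% "poisson"
    )
    dg <- digest_of(sim, seed, "simulate")
    truth_path <- file.path(out_dir, "truth.tsv")
    bench <- simulate_benchmark(n_per_label, tmpl, seed = seed)
    aln_paths <- file.path(out_dir, "alignments",
                           paste0(bench$family_id, ".fasta"))
    outputs <- c(aln_paths, tax_path, truth_path)
    if (!stage_current("simulate", dg, outputs)) {
      purrr::walk2(bench$alignment, aln_paths, write_alignment)
      write_taxonomy(attr(bench, "taxonomy"), tax_path)
      readr::write_tsv(bench[, c("family_id", "true_label",
                                 "expected_category", "seed")], truth_path)
      manifest$stages$simulate <- list(digest = dg, outputs = outputs)
      save_manifest()
      log_line("info", "stage_done", stage = "simulate",
               n_families = nrow(bench), .min_level = log_level)
    } else {
      log_line("info", "stage_skipped", stage = "simulate",
               .min_level = log_level)
    }
    taxonomy <- attr(bench, "taxonomy")
    alignments <- setNames(bench$alignment, bench$family_id)
  } else {
    inp <- config_get(config, "input")
    aln_dir <- inp$alignments_dir
    if (is.null(aln_dir) || !dir.exists(aln_dir)) {
      abort("config field input.alignments_dir must name an existing directory",
            class = "mosaic_config_error")
    }
    paths <- sort(list.files(aln_dir, pattern = "\\.fa(sta)?$",
                             full.names = TRUE))
    if (length(paths) == 0) {
      abort(paste0("no FASTA alignments in ", aln_dir),
            class = "mosaic_config_error")
    }
    taxonomy <- read_taxonomy(inp$taxonomy %||%
                                abort("config field missing: input.taxonomy",
                                      class = "mosaic_config_error"))
    write_taxonomy(taxonomy, tax_path)
    alignments <- setNames(lapply(paths, read_alignment),
                           sub("\\.fa(sta)?$", "", basename(paths)))
  }

  # ---- stage 2: screen -------------------------------------------------
  report_path <- file.path(out_dir, "screen_report.tsv")
  tally_path <- file.path(out_dir, "tally.tsv")
  errors_path <- file.path(out_dir, "errors.tsv")
  tree_paths <- file.path(out_dir, "trees", paste0(names(alignments), ".nwk"))
  dg_screen <- digest_of(unclass(scfg), names(alignments), seed, "screen")
  outputs_screen <- c(report_path, tally_path)
  errors <- tibble::tibble(gene_id = character(), stage = character(),
                           message = character())
  if (!stage_current("screen", dg_screen, outputs_screen)) {
    rows <- list()
    for (gene_id in names(alignments)) {
      cfg_g <- scfg
      cfg_g$seed <- (seed + match(gene_id, names(alignments)) * 7919L) %%
        .Machine$integer.max
      res <- tryCatch(
        screen_gene(alignments[[gene_id]], query, taxonomy, cfg_g),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        errors <- dplyr::bind_rows(errors, tibble::tibble(
          gene_id = gene_id, stage = "screen",
          message = conditionMessage(res)))
        log_line("warn", "gene_failed", stage = "screen", gene = gene_id,
                 error = conditionMessage(res), .min_level = log_level)
        next
      }
      write_gene_tree(res$tree, file.path(out_dir, "trees",
                                          paste0(gene_id, ".nwk")))
      rep_row <- res$report
      rep_row$query_id <- NULL
      rows[[gene_id]] <- tibble::tibble(gene_id = gene_id, rep_row)
      log_line("info", "gene_screened", gene = gene_id,
               closest = rows[[gene_id]]$closest_otu,
               group = rows[[gene_id]]$closest_group,
               n_leaves = length(res$tree$tip.label),
               .min_level = log_level)
    }
    report <- dplyr::bind_rows(rows)
    if (nrow(report) == 0) {
      abort("screen stage produced no gene reports (see errors.tsv)",
            class = "mosaic_stage_error")
    }
    write_screen_report(report, report_path)
    readr::write_tsv(tally_by_group(report), tally_path)
    if (nrow(errors) > 0) readr::write_tsv(errors, errors_path)
    manifest$stages$screen <- list(digest = dg_screen,
                                   outputs = outputs_screen)
    save_manifest()
    log_line("info", "stage_done", stage = "screen",
             n_genes = nrow(report), .min_level = log_level)
  } else {
    log_line("info", "stage_skipped", stage = "screen",
             .min_level = log_level)
  }

  # ---- stage 3: classify ----------------------------------------------
  class_path <- file.path(out_dir, "classification.tsv")
  summary_path <- file.path(out_dir, "summary.json")
  dg_class <- digest_of(unclass(ccfg), dg_screen, "classify")
  outputs_class <- c(class_path, summary_path)
  if (!stage_current("classify", dg_class, outputs_class)) {
    trees <- list()
    for (p in tree_paths[file.exists(tree_paths)]) {
      trees[[sub("\\.nwk$", "", basename(p))]] <- read_gene_tree(p)
    }
    cls_rows <- list()
    for (gene_id in names(trees)) {
      res <- tryCatch(
        classify_gene_tree(trees[[gene_id]], query, taxonomy, ccfg,
                           gene_id = gene_id),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        errors <- dplyr::bind_rows(errors, tibble::tibble(
          gene_id = gene_id, stage = "classify",
          message = conditionMessage(res)))
        log_line("warn", "gene_failed", stage = "classify", gene = gene_id,
                 error = conditionMessage(res), .min_level = log_level)
        next
      }
      row <- tidy(res)
      row$clade <- list(res$clade)
      cls_rows[[gene_id]] <- row
      log_line("info", "gene_classified", gene = gene_id,
               category = res$category, support = res$defining_support,
               .min_level = log_level)
    }
    classifications <- dplyr::bind_rows(cls_rows)
    write_classification_report(classifications, class_path)
    sm <- summarize_classifications(classifications)
    jsonlite::write_json(
      list(counts = setNames(as.list(sm$counts$n_genes), sm$counts$category),
           peranema_coclade = sm$n_peranema, n_genes = sm$n_total),
      summary_path, auto_unbox = TRUE, pretty = TRUE)
    if (nrow(errors) > 0) readr::write_tsv(errors, errors_path)
    manifest$stages$classify <- list(digest = dg_class,
                                     outputs = outputs_class)
    save_manifest()
    log_line("info", "stage_done", stage = "classify",
             n_genes = nrow(classifications), .min_level = log_level)
  } else {
    log_line("info", "stage_skipped", stage = "classify",
             .min_level = log_level)
  }

  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
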