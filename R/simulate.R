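SCENARIO_LABELS <- c("VERTICAL", "GREEN_EGT", "CR_RED", "CR_GREEN", "RED_OTHER")

scenario_group_pool <- function() {
  list(
    EUGLENID = c("Euglena_gracilis", "Peranema_trichophorum",
                 "Eutreptiella_gymnastica", "Colacium_vesiculosum"),
    OTHER_EXCAVATA = c("Trypanosoma_brucei", "Leishmania_major",
                       "Naegleria_gruberi", "Giardia_intestinalis"),
    CR = c("Thalassiosira_pseudonana", "Emiliania_huxleyi",
           "Bigelowiella_natans", "Perkinsus_marinus", "Phytophthora_sojae",
           "Guillardia_theta", "Phaeodactylum_tricornutum",
           "Aureococcus_anophagefferens"),
    RED = c("Cyanidioschyzon_merolae", "Porphyra_yezoensis",
            "Galdieria_sulphuraria", "Gracilaria_changii"),
    GREEN = c("Chlamydomonas_reinhardtii", "Ostreococcus_tauri",
              "Arabidopsis_thaliana", "Micromonas_pusilla",
              "Physcomitrella_patens"),
    UNIKONT = c("Homo_sapiens", "Saccharomyces_cerevisiae",
                "Monosiga_brevicollis", "Dictyostelium_discoideum"),
    CYANOBACTERIA = c("Synechocystis_sp", "Nostoc_punctiforme",
                      "Anabaena_variabilis", "Prochlorococcus_marinus"),
    OTHER_BACTERIA = c("Escherichia_coli", "Bacillus_subtilis")
  )
}

#' Define a planted-history simulation scenario
#'
#' A scenario fixes the evolutionary history planted into a simulated
#' gene family and the parameters of sequence evolution. The five
#' histories mirror the hypotheses the screen discriminates:
#' `VERTICAL` (euglenids stay with the other excavates), `GREEN_EGT`
#' (transfer from the green secondary endosymbiont, euglenids inside the
#' green lineage), `CR_RED` (euglenids inside the CR assemblage, which is
#' sister to red algae), `CR_GREEN` (euglenid+CR clade sister to the
#' green lineage), and `RED_OTHER` (euglenids sister to CR, but the
#' placement of that clade left unresolvable by a zero-length stem).
#'
#' @param label One of `VERTICAL`, `GREEN_EGT`, `CR_RED`, `CR_GREEN`,
#'   `RED_OTHER`.
#' @param taxa_per_group Named integer vector, taxa sampled per lineage
#'   group. Default: 2 euglenids (including *Peranema*), 2 other
#'   excavates, 4 CR, 3 red, 3 green, 2 unikonts, 2 cyanobacteria.
#' @param internal_branch Internal branch length (substitutions/site).
#'   Default 0.5.
#' @param tip_branch_mean Mean terminal branch length (exponentially
#'   distributed). Default 0.2.
#' @param seq_length Alignment length before indels (>= 50). Default 500.
#' @param indel_rate Expected insertion events per unit branch length.
#'   Default 0.2.
#' @param model Substitution model: `"poisson"` (default; equal
#'   exchangeabilities, uniform frequencies) or `"wag"`.
#' @param seed Integer seed; every scenario output is bit-reproducible
#'   given `(scenario, seed)`.
#' @return A list of class `scenario`.
#' @export
scenario <- function(label,
                     taxa_per_group = NULL,
                     internal_branch = 0.5,
                     tip_branch_mean = 0.2,
                     seq_length = 500L,
                     indel_rate = 0.2,
                     model = c("poisson", "wag"),
                     seed = 1L) {
  if (!label %in% SCENARIO_LABELS) {
    abort(paste0("unknown scenario label ", sQuote(label)),
          class = "mosaic_scenario_error")
  }
  model <- match.arg(model)
  if (is.null(taxa_per_group)) {
    taxa_per_group <- c(EUGLENID = 2L, OTHER_EXCAVATA = 2L, CR = 4L,
                        RED = 3L, GREEN = 3L, UNIKONT = 2L,
                        CYANOBACTERIA = 2L)
  }
  required <- c("EUGLENID", "CR", "RED", "GREEN", "CYANOBACTERIA")
  if (!all(required %in% names(taxa_per_group)) ||
      any(taxa_per_group[required] < 1)) {
    abort(paste0("scenario needs at least one taxon in each of: ",
                 paste(required, collapse = ", ")),
          class = "mosaic_scenario_error")
  }
  pool <- scenario_group_pool()
  over <- names(taxa_per_group)[taxa_per_group >
                                  lengths(pool)[names(taxa_per_group)]]
  if (length(over) > 0) {
    abort(paste0("taxa_per_group exceeds the available pool for: ",
                 paste(over, collapse = ", ")),
          class = "mosaic_scenario_error")
  }
  if (internal_branch <= 0 || tip_branch_mean <= 0) {
    abort("branch lengths must be positive", class = "mosaic_scenario_error")
  }
  if (seq_length < 50) {
    abort("seq_length must be >= 50", class = "mosaic_scenario_error")
  }
  structure(list(label = label,
                 taxa_per_group = taxa_per_group,
                 internal_branch = internal_branch,
                 tip_branch_mean = tip_branch_mean,
                 seq_length = as.integer(seq_length),
                 indel_rate = indel_rate,
                 model = model,
                 seed = as.integer(seed)),
            class = "scenario")
}

scenario_taxa <- function(s) {
  pool <- scenario_group_pool()
  purrr::imap(as.list(s$taxa_per_group),
              function(n, g) pool[[g]][seq_len(n)])
}

#' Taxonomy map for a scenario's sampled taxa
#'
#' @param s A [scenario()].
#' @return A [taxonomy_map()] restricted to the scenario's OTUs.
#' @export
scenario_taxonomy <- function(s) {
  taxa <- unlist(scenario_taxa(s))
  full <- default_taxonomy()
  taxonomy_map(full[full$otu_id %in% taxa, ])
}

#' Build the gene tree a scenario plants
#'
#' Constructs the backbone species topology — bacteria-rooted, with
#' unikonts, then a split between the plant lineages (green vs red + CR)
#' and the excavates — and regrafts the euglenid subtree according to the
#' planted history. Internal branches take `internal_branch`; terminal
#' branches are exponential with mean `tip_branch_mean` (seeded). In the
#' `RED_OTHER` history the stem placing the euglenid+CR clade among the
#' other plant lineages has length zero, so no data can resolve its
#' sister group.
#'
#' @param s A [scenario()].
#' @return An unrooted `ape::phylo`; deterministic given the scenario seed.
#' @export
build_scenario_tree <- function(s) {
  taxa <- scenario_taxa(s)
  ib <- s$internal_branch
  set.seed(s$seed)
  fmt <- function(x) sprintf("%.10g", x)
  tip <- function(label) {
    paste0(label, ":", fmt(max(0.01, rexp(1, 1 / s$tip_branch_mean))))
  }
  ladder <- function(labels) {
    frags <- vapply(labels, tip, character(1))
    out <- frags[1]
    for (k in seq_along(frags)[-1]) {
      out <- paste0("(", out, ",", frags[k], ")")
      if (k < length(frags)) out <- paste0(out, ":", fmt(ib))
    }
    out
  }
  join <- function(a, b, len_a = ib, len_b = ib) {
    paste0("(", a, ":", fmt(len_a), ",", b, ":", fmt(len_b), ")")
  }
  g <- function(code) ladder(taxa[[code]])
  has <- function(code) !is.null(taxa[[code]]) && length(taxa[[code]]) > 0

  eu <- g("EUGLENID")
  plants <- switch(
    s$label,
    VERTICAL = join(g("GREEN"), join(g("RED"), g("CR"))),
    GREEN_EGT = join(join(eu, g("GREEN")), join(g("RED"), g("CR"))),
    CR_RED = join(g("GREEN"), join(g("RED"), join(eu, g("CR")))),
    CR_GREEN = join(join(g("GREEN"), join(eu, g("CR"))), g("RED")),
    RED_OTHER = paste0("(", join(g("RED"), join(eu, g("CR"))), ":0,",
                       g("GREEN"), ":", fmt(ib), ")")
  )
  exc <- if (s$label == "VERTICAL") {
    if (has("OTHER_EXCAVATA")) join(eu, g("OTHER_EXCAVATA")) else eu
  } else {
    if (has("OTHER_EXCAVATA")) g("OTHER_EXCAVATA") else NULL
  }
  ingroup <- if (is.null(exc)) plants else join(plants, exc)
  rest <- if (has("UNIKONT")) join(g("UNIKONT"), ingroup) else ingroup
  txt <- paste0(join(g("CYANOBACTERIA"), rest), ";")
  tree <- ape::read.tree(text = txt)
  ape::unroot(tree)
}

#' Evolve an alignment along a tree, with insertion indels
#'
#' Substitutions are simulated by `phangorn::simSeq()` under the
#' scenario's model (root sequence from the model equilibrium,
#' continuous-time substitution along each branch). Insertion events are
#' then layered into the alignment coordinate frame: on each branch the
#' number of events is Poisson with mean `indel_rate * branch_length`,
#' each event inserts a block of geometric length (mean 3 columns) carried
#' by exactly the taxa below that branch, with all other rows gapped —
#' producing the shared-indel signatures [find_shared_indels()] detects.
#'
#' @param tree A binary `ape::phylo` with non-negative branch lengths.
#' @param s A [scenario()] (lengths, model, rates, seed).
#' @return A [protein_msa()]; deterministic given `(tree, s)`.
#' @export
evolve_alignment <- function(tree, s) {
  if (!inherits(s, "scenario")) {
    abort("s must be a scenario object", class = "mosaic_config_error")
  }
  set.seed((s$seed + 104729L) %% .Machine$integer.max)
  sim <- if (s$model == "wag") {
    phangorn::simSeq(tree, l = s$seq_length, type = "AA", model = "WAG")
  } else {
    phangorn::simSeq(tree, l = s$seq_length, type = "AA")
  }
  m <- toupper(as.character(sim))
  ntip <- length(tree$tip.label)
  if (s$indel_rate > 0) {
    for (e in seq_len(nrow(tree$edge))) {
      bl <- tree$edge.length[e]
      if (is.na(bl) || bl <= 0) next
      n_ev <- rpois(1, s$indel_rate * bl)
      if (n_ev == 0) next
      child <- tree$edge[e, 2]
      carriers <- if (child <= ntip) {
        tree$tip.label[child]
      } else {
        tree$tip.label[phangorn::Descendants(tree, child, "tips")[[1]]]
      }
      if (length(carriers) >= ntip) next
      for (k in seq_len(n_ev)) {
        len <- rgeom(1, 1 / 3) + 1L
        pos <- sample.int(ncol(m) + 1L, 1L) - 1L
        block <- matrix("-", nrow = ntip, ncol = len,
                        dimnames = list(rownames(m), NULL))
        block[carriers, ] <- sample(AA_LETTERS, len * length(carriers),
                                    replace = TRUE)
        m <- cbind(m[, seq_len(pos), drop = FALSE], block,
                   m[, seq_len(ncol(m)) > pos, drop = FALSE])
      }
    }
  }
  protein_msa(m)
}

#' Supports a noise-free planted tree would earn
#'
#' Assigns full support to every internal edge with positive length and
#' zero support to zero-length edges: a zero-length stem (the `RED_OTHER`
#' history's placement edge) carries no signal, so no amount of data can
#' support the corresponding split.
#'
#' @param tree An `ape::phylo` with branch lengths.
#' @param high Support given to resolvable edges (default 100).
#' @param scale Support scale tag (default `"bootstrap_pct"`).
#' @return The tree with node labels set and the scale attribute tagged.
#' @export
planted_supports <- function(tree, high = 100, scale = "bootstrap_pct") {
  ntip <- length(tree$tip.label)
  labs <- rep("", tree$Nnode)
  internal <- tree$edge[, 2] > ntip
  children <- tree$edge[internal, 2]
  lens <- tree$edge.length[internal]
  labs[children - ntip] <- ifelse(lens > 0, as.character(high), "0")
  tree$node.label <- labs
  set_support_scale(tree, scale)
}

#' Simulate one gene family under a scenario
#'
#' @param s A [scenario()].
#' @return A list with `tree` (planted gene tree), `alignment`
#'   ([protein_msa()]), `taxonomy` and the scenario itself.
#' @export
simulate_family <- function(s) {
  tree <- build_scenario_tree(s)
  list(tree = tree, alignment = evolve_alignment(tree, s),
       taxonomy = scenario_taxonomy(s), scenario = s)
}

#' Expected classifier category for a planted history
#'
#' @param label Scenario label(s).
#' @return Character vector: `VERTICAL` maps to `UNCLASSIFIED`,
#'   `GREEN_EGT` to `GREEN`, the transfer labels to themselves.
#' @export
planted_expected_category <- function(label) {
  map <- c(VERTICAL = "UNCLASSIFIED", GREEN_EGT = "GREEN",
           CR_RED = "CR_RED", CR_GREEN = "CR_GREEN", RED_OTHER = "RED_OTHER")
  unname(map[label])
}

#' Simulate a benchmark of gene families with planted histories
#'
#' Generates `n_per_label` families for each of the five planted
#' histories, with per-family seeds derived deterministically from the
#' master seed.
#'
#' @param n_per_label Families per scenario label (>= 1).
#' @param s_template A [scenario()] whose parameters (taxon sampling,
#'   branch lengths, sequence length, rates, model) are reused for every
#'   family; its label and seed are overridden.
#' @param seed Master seed.
#' @return A tibble: `family_id`, `true_label`, `expected_category`,
#'   `seed`, plus `tree` and `alignment` list columns. The shared
#'   [taxonomy_map()] is attached as attribute `taxonomy`.
#' @export
simulate_benchmark <- function(n_per_label, s_template = scenario("VERTICAL"),
                               seed = 1L) {
  if (n_per_label < 1) {
    abort("n_per_label must be >= 1", class = "mosaic_config_error")
  }
  rows <- purrr::imap(setNames(SCENARIO_LABELS, SCENARIO_LABELS),
                      function(label, nm) {
    j <- match(label, SCENARIO_LABELS)
    purrr::map(seq_len(n_per_label), function(i) {
      child_seed <- (seed + 7907L * j + 131L * i) %% .Machine$integer.max
      s <- s_template
      s$label <- label
      s$seed <- child_seed
      fam <- simulate_family(s)
      tibble::tibble(
        family_id = sprintf("%s_%03d", label, i),
        true_label = label,
        expected_category = planted_expected_category(label),
        seed = child_seed,
        tree = list(fam$tree),
        alignment = list(fam$alignment)
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  attr(rows, "taxonomy") <- scenario_taxonomy(
    scenario(SCENARIO_LABELS[1],
             taxa_per_group = s_template$taxa_per_group))
  rows
}
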