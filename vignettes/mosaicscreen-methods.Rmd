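---
title: "Methods: screening euglenid gene families for red-lineage transfers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening euglenid gene families for red-lineage transfers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicscreen)
```

## The problem

Euglenophytes carry a secondary plastid of green-algal origin, yet their
nuclear genomes also contain genes whose closest relatives sit in the
"red lineage" — red algae and the secondary algae whose plastids derive
from red algae (stramenopiles, alveolates, cryptophytes, haptophytes,
here grouped with Rhizaria as the CR assemblage). Such genes are
candidate lateral or endosymbiotic transfers from red-lineage algae into
an ancestor of euglenids, and their tree topologies — where exactly the
euglenid sequence nests, and what the euglenid+CR clade is sister to —
are the evidence. `mosaicscreen` implements that screen as a reusable,
fully testable pipeline:

1. **taxonomy registry** — a fixed palette of nine lineage groups and an
   explicit OTU-to-group map; unregistered labels are errors, never
   silent defaults.
2. **alignment processing** — aligned-FASTA I/O, removal of indel-rich
   sites and then taxa, corrected protein distances, and shared-indel
   diagnostics.
3. **tree engine** — neighbor joining with nonparametric bootstrap,
   patristic queries, single-genus clade collapsing, and
   support-thresholded monophyly tests.
4. **screen** — E-value gates for hit tables and, per gene, the lineage
   group patristically closest to the query.
5. **topology classifier** — the CR+Red / CR+Green / red-other
   categories, with a Peranema co-clade flag.
6. **scenario simulator** — gene families with planted histories so that
   every stage has a ground truth.
7. **pipeline** — one reproducible run with config, manifest and logs.

## Alignment processing

Alignments are consumed, not built (alignment construction is out of
scope). Trimming is two-pass: columns whose gap fraction exceeds
`max_gap_frac_col` (default 0.5) are removed first, then rows whose gap
fraction exceeds `max_gap_frac_taxon` (default 0.75). "Indel-rich" has
no canonical definition, so both thresholds sit in the configuration
rather than being buried in code; the defaults follow common trimming
practice. The order — columns, then taxa — is likewise a configuration
level decision made once. The designated query row is never dropped: a
query too gappy to trust fails the gene loudly
(`mosaic_query_too_gappy`) instead of silently degrading the screen.

Distances compare each pair only on columns where both rows carry an
unambiguous residue; `X` (frequent in EST translations) counts as
missing. The default model is the Poisson correction `-log(1 - p)` of
the mismatch fraction `p`, as used by the QuickTree-era NJ tools this
stage mirrors; `p >= 0.99` is capped at `-log(0.01)` so saturated pairs
stay finite and the matrix remains NJ-usable. A pair with *no*
comparable columns is an error naming the pair, because any imputed
distance would silently place that taxon arbitrarily.

Shared-indel signatures are maximal runs of columns in which every
member of a candidate OTU set is gapped and every other row is not
(deletion block), or the converse (insertion block). Columns gapped in
all rows discriminate nothing and never form a signature. Intervals are
0-based half-open throughout, which keeps interval arithmetic uniform.

## Tree engine

Neighbor joining is the standard agglomerative algorithm (minimise
`Q(i,j) = (n-2) d(i,j) - r_i - r_j`, join, reduce). Two conventions make
it bit-reproducible and invariant-friendly:

* **Tie-breaking.** When several pairs share the minimal `Q` (within
  1e-12), the pair whose sorted smallest-leaf labels are
  lexicographically smallest is joined. Random tie-breaking would make
  bootstrap supports irreproducible across runs.
* **Negative branch lengths.** NJ's three-point estimates can be
  negative; estimates are clamped to zero with the deficit moved to the
  sibling branch, preserving the pair's estimated total — the standard
  remedy, and required by the invariant that branch lengths are
  non-negative.

On additive matrices NJ is exact; the test suite verifies topology and
branch-length recovery to 1e-9 on random trees of up to 12 leaves, and
the three-point closed forms directly.

Bootstrap supports are computed by resampling alignment columns with
replacement (same length), rebuilding the NJ tree, and counting for each
internal edge of the point-estimate tree the percentage of replicates
containing the same leaf bipartition. Supports live on internal node
labels in newick output — the de facto standard — and every tree carries
a `support_scale` tag (`bootstrap_pct` on 0–100 or `posterior` on 0–1)
because both conventions occur in the wild and a bare number cannot be
interpreted safely. The pipeline computes supports on the full tree and
collapses afterwards (full tree → supports → collapse), a fixed order
recorded here because the original description leaves it open.

Single-genus collapsing reduces every maximal clade composed exclusively
of one genus to its lexicographically smallest leaf (the representative
is otherwise arbitrary; determinism again), repeating to a fixpoint.
Clades are read relative to the protected query, which is never pruned.

Monophyly tests are inclusive at the threshold: support exactly 70 (or
posterior exactly 0.9) passes, because the thresholds are stated as
values, not strict bounds.

## The screen

The two-step homology gate keeps genes with a green-plant hit at
E-value strictly below `1e-5` and then selects homologues strictly below
`1e-3`, at most 500, sorted by `(evalue, subject_id)` — strict
inequalities because the gates are described as "smaller than"/"less
than". Hit tables are consumed, never produced: running BLAST is out of
scope.

Per gene, the screen reports the leaf minimising patristic distance to
the query on the collapsed bootstrapped NJ tree, excluding the query's
own group (euglenids) so conspecific sequences cannot mask the donor
signal. Exact ties are recorded and broken lexicographically. The
"closest" notion is the nearest single OTU, not a nearest-clade
majority; the report header flags this choice.

## Topology classification

The classifier formalises what was originally a manual topology check.
After orienting the tree by the first outgroup group present (preference
order: cyanobacteria, other eubacteria, unikonts), it proceeds:

1. **Red-lineage monophyly.** Find the smallest clade containing the
   query whose other members are all euglenid, CR or red-algal, with at
   least one CR/RED member, and whose subtending edge meets the support
   threshold (70% bootstrap or 0.9 posterior, inclusive, on the tree's
   own scale). If none exists, the gene is `GREEN` when the smallest
   supported mixed clade around the query is purely green(+euglenid),
   otherwise `UNCLASSIFIED`.
2. **Sister-group reading.** From that clade, walk rootward absorbing
   sisters dominated by CR(+euglenid) leaves — this assembles the full
   euglenid+CR clade even when the query nests deep inside the CR
   assemblage. The first non-CR sister decides the category: at least
   80% red-algal leaves with the joining edge supported is `CR_RED`; at
   least 80% green with support is `CR_GREEN`; anything mixed, or a
   joining edge below threshold, leaves the affiliation unclear —
   `RED_OTHER`. The 80% majority tolerates the odd straggler real sister
   clades contain.
3. **Red-only guard.** A defining clade with red algae but *no* CR
   member is reported `UNCLASSIFIED` with a note — the convention
   applied to triose-phosphate isomerase, which was deliberately not
   designated a red-lineage gene for exactly this reason.
4. **Peranema flag.** The gene is flagged when the defining clade
   contains a sequence of the aplastidic eukaryovorous euglenid
   *Peranema* — evidence the transfer predates the divergence of
   euglenophytes from eukaryovorous euglenids.

Two readings were genuinely open. "Nested in, or specifically associated
with, the red lineage" is formalised as the smallest *supported*
qualifying clade — the weakest reading that still demands explicit
support for the euglenid/red-lineage association. And for `CR_RED` /
`CR_GREEN` the support requirement sits on the edge *joining* the
euglenid+CR clade to its sister (the monophyly of the union), not on the
sister's internal edge: an unresolvable placement stem then correctly
yields `RED_OTHER` even when the sister clade itself is rock solid.
Every decision records the supporting edge and support value in `notes`,
so a human can audit the call the way the original manual check did.

## The scenario simulator

`scenario()` plants one of five histories into a backbone species
topology (bacterial outgroup; unikonts; a plant split of green vs
red + CR; excavates including euglenids):

* `VERTICAL` — euglenids remain with the other excavates;
* `GREEN_EGT` — euglenids inside the green lineage;
* `CR_RED` — euglenids inside CR, euglenid+CR sister to red algae;
* `CR_GREEN` — euglenid+CR sister to the green lineage;
* `RED_OTHER` — euglenids sister to CR, with the stem placing that clade
  among the plant lineages set to length zero, so its sister group is
  unresolvable *by construction*.

Defaults are the study conditions of the package's own validation:
internal branches 0.5 substitutions/site, terminal branches exponential
with mean 0.2, alignment length 500, taxon sampling of 2 euglenids
(including *Peranema*), 2 other excavates, 4 CR, 3 red, 3 green, 2
unikonts and 2 cyanobacteria — small enough to run hundreds of families
in minutes, deep enough that internal edges earn decisive bootstrap
support. Sequences evolve under a Poisson (equal-exchangeability) amino
acid model by default; WAG is available, but the equal-rates model is
the right default for testing pipeline logic, where the substitution
process is not the question. Rate heterogeneity across sites is *not*
simulated; it matters for real inference, and its absence here is
deliberate and documented rather than silently included.

Indels are insertion-only in the alignment frame: each branch receives
Poisson(`indel_rate` × length) insertion events of geometric length
(mean 3), carried by exactly the taxa below the branch and gapped in all
others. This produces the clade-exclusive indel signatures the
diagnostics detect without requiring a full indel-evolution model, and a
zero-length tree therefore yields a gap-free alignment of identical
rows.

What the simulator does *not* emulate: alignment error, compositional
heterogeneity, rate variation, long-branch attraction regimes, paralogy
mixtures, and partial (EST-fragment) sequences. Passing the planted
benchmarks shows the pipeline's logic is correct under honest signal; it
does not certify behaviour on pathological real data.

The 14 worked-example gene trees (`make_table1_fixtures()`) encode the
verbally described topologies of the published screen's red-lineage
genes: 4 CR+Red (HPT, a hypothetical oxidoreductase-domain protein,
glucokinase, ClpP), 2 CR+Green (PRK, FBT), and 8 with unclear sisters
(ZEP, plastidic and cytosolic FBP, GND, the ADP/ATP transporter, LepA,
MAT, a fatty acid desaturase); GND and the ADP/ATP transporter carry a
*Peranema* leaf inside the defining clade. The ClpP fragment is too
short for a reliable tree, so its fixture encodes the topology implied
by residue-level evidence and says so in its note. Supports are 92+
except where the described topology requires an unresolved edge.

```{r fixtures}
fx <- make_table1_fixtures()
res <- classify_gene_trees(setNames(fx$tree, fx$gene_id),
                           query = "Euglena_gracilis",
                           taxonomy = default_taxonomy())
glance(summarize_classifications(res))
```

## Planted-truth subtlety

Classifying a *noise-free* planted tree requires supports; assigning
full support to every edge would also "support" the `RED_OTHER`
scenario's zero-length stem, which by construction carries no signal.
`planted_supports()` therefore gives full support to positive-length
edges and zero to zero-length ones. Under that convention every planted
history classifies as its expected category (`VERTICAL` →
`UNCLASSIFIED`, `GREEN_EGT` → `GREEN`, transfer labels to themselves).

## Numerical and procedural choices, collected

| choice | value | why |
|---|---|---|
| column gap threshold | 0.5 | common practice; configurable |
| taxon gap threshold | 0.75 | looser than columns: keep taxa, trust trimmed sites |
| distance model | Poisson-corrected, cap at −log(0.01) | corrected distances for NJ; finite matrix |
| `X` residues | missing | EST translations carry ambiguity |
| NJ ties | lexicographic smallest label pair | bit-reproducibility |
| negative NJ lengths | clamp to 0, deficit to sibling | non-negative lengths invariant |
| support thresholds | ≥ 70 bootstrap / ≥ 0.9 posterior, inclusive | stated as values, not strict bounds |
| sister majority | 0.8 | tolerate stragglers in real sisters |
| collapse representative | smallest label | determinism |
| pipeline order | trim columns → taxa; full tree → supports → collapse | fixed once, surfaced in config |
| coordinates | 0-based half-open | uniform interval arithmetic |

## Validation sizes

The shipped tests run the worked example (14 trees), a
20-families-per-history benchmark (100 families, alignment length 500,
100 bootstrap replicates) requiring ≥95% planted-label recovery
end-to-end, 200 random additive matrices for NJ exactness, and
property suites for the four-point condition, collapse bipartition
restriction, trimming idempotence and seeded determinism. These sizes
were chosen so the whole suite completes in a few minutes on one CPU
while leaving each check statistically meaningful.

## Limitations

* Only NJ + bootstrap inference is built in; likelihood and Bayesian
  trees are consumed (with their supports) but never inferred.
* The classifier reads one tree per gene; it does not combine loci or
  adjudicate LGT vs EGT — that distinction is an interpretive question
  the topology alone cannot settle.
* Corpus-scale results of the original screen (thousands of queries
  against a contemporary sequence database) are not reproducible from a
  desk and are out of scope; the planted benchmarks and invariants above
  are the package's acceptance surface.
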