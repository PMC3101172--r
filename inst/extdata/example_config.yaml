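# Example configuration for `run_pipeline()` / `mosaicscreen.R run`.
# Paper-derived thresholds are annotated; everything here is overridable.

seed: 1
out_dir: "mosaicscreen_run"
query: "Euglena_gracilis"

# Either a `simulate:` section (planted benchmark) or an `input:` section
# (your own data):
#
# input:
#   alignments_dir: "alignments/"   # aligned FASTA per gene family
#   taxonomy: "taxonomy.tsv"        # otu_id, genus, group, subgroup
simulate:
  n_per_label: 2        # families per planted history (5 histories)
  internal_branch: 0.5  # substitutions/site on internal edges
  tip_branch_mean: 0.2  # mean terminal branch length (exponential)
  seq_length: 500       # alignment columns before indels
  indel_rate: 0.2       # insertion events per unit branch length
  model: poisson        # or "wag"

screen:
  n_bootstrap: 100          # bootstrap replicates for NJ supports
  max_gap_frac_col: 0.5     # drop columns with > 50% gaps
  max_gap_frac_taxon: 0.75  # then rows with > 75% gaps (query protected)
  model: poisson            # protein distance: poisson | p_distance
  stage1_evalue_max: 1.0e-5 # green-hit gate, strict ("smaller than")
  stage2_evalue_max: 1.0e-3 # homologue fetch, strict ("less than")
  max_hits: 500             # homologue cap

classify:
  min_bootstrap: 70    # inclusive, on bootstrap-scaled trees
  min_posterior: 0.9   # inclusive, on posterior-scaled trees
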