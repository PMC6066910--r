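# Example regulonet pipeline configuration: a compact synthetic experiment
# with three sorted subsets (HE, nonHE, CD43pos) x two genotypes (WT, KO),
# four replicates each, and four active regulons per contrast.
seed: 1
out_dir: regulonet_artifacts
simulate:
  n_genes: 2000
  n_tfs: 60
  n_targets: 1800
  mean_regulon_size: 15
  regulon_overlap: 0.1
  baseline_mean: 400
  dispersion: 0.05
  n_replicates: 4
  active_auto: {n_per_contrast: 4, lfc: 2.5, fraction_responsive: 0.9}
  annotations: {n_categories: 25, mean_category_size: 40}
thresholds:
  fdr: 0.05
  lfc: 1.0
  alpha_select: 0.05
  k_min: 3
  or_min: 2
anchors: [GATA2]
panels: default
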