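# Example run configuration: host transcriptome as the central layer,
# flanked by an amplicon (16S) layer and a metatranscriptome, as in a
# feeding-trial design. Paths are placeholders; tables are plain TSV
# feature tables (first column "id").
layers:
  - id: host
    path: data/host_transcriptome.tsv
    orientation: samples-in-rows
    network:
      power: auto          # or a fixed integer, e.g. 6
      rsq_target: 0.8
      min_module_size: 20
      merge_cut_height: 0.25
  - id: asv
    path: data/asv_table.tsv
    orientation: features-in-rows
    preprocessing:
      min_prevalence: 0.25 # drop ASVs seen in < 25% of samples
      clr: true            # centered log-ratio for the compositional layer
    network:
      power: auto
      min_module_size: 10
  - id: metatx
    path: data/metatranscriptome.tsv
    network:
      power: auto
      min_module_size: 20
central_layer: host
metadata:
  path: data/metadata.tsv
  kinds:
    diet: categorical      # e.g. CTR / MC1 / MC2 / MN3
    time_point: categorical
    water: binary          # fresh / salt
    weight: numeric
correlation:
  method: pearson
  use: pairwise.complete.obs
  adjust: fdr
  annotation: asterisks
figure:
  format: svg
  scaling: row-z
  sample_annotations: [time_point, diet]
seed: 1
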