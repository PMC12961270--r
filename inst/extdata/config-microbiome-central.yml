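# Example run configuration with a microbial layer as the centrepiece:
# methanogen/bacterial metaproteome central, other microbial eukaryote
# layers and host-tissue proteomes correlated against it, plus a numeric
# emission phenotype in the metadata. Paths are placeholders.
layers:
  - id: arcbac
    path: data/arcbac_metaproteome.tsv
    network:
      power: auto
      min_module_size: 10
  - id: ciliates
    path: data/ciliate_metaproteome.tsv
    network:
      power: auto
      min_module_size: 10
  - id: fungi
    path: data/fungal_metaproteome.tsv
    network:
      power: auto
      min_module_size: 5
  - id: liver
    path: data/host_liver_proteome.tsv
    network:
      power: auto
      min_module_size: 15
  - id: rumen_wall
    path: data/host_rumen_wall_proteome.tsv
    network:
      power: auto
      min_module_size: 15
central_layer: arcbac
metadata:
  path: data/metadata.tsv
  kinds:
    methane_g_kg_dmi: numeric   # respiration-chamber emission measurement
    breed: categorical
    emitter_class: binary       # high / low
correlation:
  method: spearman
  use: pairwise.complete.obs
  adjust: fdr
  annotation: asterisks
figure:
  format: pdf
  scaling: row-z
  sample_annotations: [emitter_class]
seed: 1
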