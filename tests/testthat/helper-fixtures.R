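# small builders shared by the tests; everything generated in code

tiny_layer <- function(values, samples = NULL, features = NULL, id = "toy") {
  values <- as.matrix(values)
  if (is.null(samples)) {
    samples <- if (!is.null(rownames(values))) rownames(values)
               else paste0("s", seq_len(nrow(values)))
  }
  if (is.null(features)) {
    features <- if (!is.null(colnames(values))) colnames(values)
                else paste0("f", seq_len(ncol(values)))
  }
  omics_layer(values, sample_ids = samples, feature_ids = features,
              layer_id = id)
}

# one-layer spec with four planted modules (the standard recovery benchmark)
recovery_spec <- function(seed, n_samples = 40, n_features = 40,
                          loading = 0.85, n_background = 40) {
  simulation_spec(
    n_samples = n_samples,
    layers = list(list(
      layer_id = "host",
      modules = lapply(c("A", "B", "C", "D"), function(m)
        list(module_id = m, n_features = n_features, loading = loading)),
      n_background = n_background)),
    seed = seed)
}

# two layers with one planted cross-layer coupling
coupling_spec <- function(seed, rho = 0.8, n_samples = 40, loading = 0.85) {
  simulation_spec(
    n_samples = n_samples,
    layers = list(
      list(layer_id = "host",
           modules = lapply(c("A", "B", "C"), function(m)
             list(module_id = m, n_features = 25, loading = loading)),
           n_background = 15),
      list(layer_id = "micro",
           modules = lapply(c("X", "Y", "Z"), function(m)
             list(module_id = m, n_features = 25, loading = loading)),
           n_background = 15)),
    couplings = list(list(layer_a = "host", module_a = "A",
                          layer_b = "micro", module_b = "X", rho = rho)),
    seed = seed)
}

planted_params <- function(min_module_size = 15) {
  network_params(power = 6, min_module_size = min_module_size)
}

# run detection on both layers of a coupling_spec bundle and correlate hubs
run_coupling_analysis <- function(seed, rho = 0.8) {
  sim <- simulate_bundle(coupling_spec(seed, rho = rho))
  dh <- detect_modules(sim$bundle$layers$host, planted_params())
  dm <- detect_modules(sim$bundle$layers$micro, planted_params())
  rh <- evaluate_recovery(sim$truth, dh, "host")
  rmm <- evaluate_recovery(sim$truth, dm, "micro")
  cc <- calculate_correlations(dh$hub_layer, dm$hub_layer,
                               correlation_options())
  list(sim = sim, det_host = dh, det_micro = dm, rec_host = rh,
       rec_micro = rmm, corr = cc,
       eval = evaluate_detection(sim$truth, cc, dh$hubs, dm$hubs,
                                 rh$matching, rmm$matching))
}

# demo three-layer bundle + metadata written to disk with a pipeline config
write_demo_inputs <- function(dir, seed = 11) {
  spec <- simulation_spec(
    n_samples = 40,
    layers = list(
      list(layer_id = "host",
           modules = lapply(c("A", "B", "C"), function(m)
             list(module_id = m, n_features = 25, loading = 0.85)),
           n_background = 15),
      list(layer_id = "micro",
           modules = lapply(c("X", "Y"), function(m)
             list(module_id = m, n_features = 25, loading = 0.85)),
           n_background = 15),
      list(layer_id = "metab",
           modules = lapply(c("P", "Q"), function(m)
             list(module_id = m, n_features = 25, loading = 0.85)),
           n_background = 15)),
    couplings = list(list(layer_a = "host", module_a = "A",
                          layer_b = "micro", module_b = "X", rho = 0.8)),
    metadata_links = list(
      list(name = "weight", layer = "host", module = "B",
           effect = 0.8, kind = "numeric"),
      list(name = "water", layer = "host", module = "A",
           effect = 0.9, kind = "binary")),
    seed = seed)
  sim <- suppressMessages(simulate_bundle(spec))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(sim$bundle$layers)) {
    write_feature_table(sim$bundle$layers[[id]],
                        file.path(dir, paste0(id, ".tsv")))
  }
  write_metadata_table(sim$bundle$metadata, file.path(dir, "metadata.tsv"))
  cfg <- list(
    layers = lapply(c("host", "micro", "metab"), function(id)
      list(id = id, path = file.path(dir, paste0(id, ".tsv")),
           network = list(power = 6, min_module_size = 15))),
    central_layer = "host",
    metadata = list(path = file.path(dir, "metadata.tsv")),
    correlation = list(method = "pearson", adjust = "fdr"),
    figure = list(format = "svg", sample_annotations = list("water")),
    seed = 3)
  cfg_path <- file.path(dir, "config.yml")
  yaml::write_yaml(cfg, cfg_path)
  list(sim = sim, config = cfg_path)
}
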