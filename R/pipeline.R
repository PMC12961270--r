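# config helpers: pull NetworkParams / CorrelationOptions out of the YAML
.params_from_config <- function(cfg) {
  cfg <- cfg %||% list()
  do.call(network_params, cfg[intersect(names(cfg),
    names(formals(network_params)))])
}

.options_from_config <- function(cfg) {
  cfg <- cfg %||% list()
  do.call(correlation_options, cfg[intersect(names(cfg),
    names(formals(correlation_options)))])
}

#' Run the full integration pipeline from a config file
#'
#' Reads every layer, aligns samples, applies the built-in preprocessing
#' (prevalence filter, centered log-ratio) where requested, detects modules
#' and hubs per layer, orders the central layer, correlates the central hubs
#' against every other layer's hubs and against the encoded metadata, writes
#' all tables, renders the integrated figure, and records a run manifest
#' (inputs with checksums, parameters, outputs, seed, timestamp). The run is
#' deterministic for fixed inputs and config. An existing manifest in
#' `out_dir` aborts the run unless `overwrite = TRUE`, which removes the
#' previous run's listed outputs first — never a silent overwrite.
#'
#' @param config_path Path to a YAML run configuration. Top-level keys:
#'   `layers` (list of `id`, `path`, `orientation`, `delimiter`,
#'   `preprocessing` (`min_prevalence`, `clr`), `network`, `labels`),
#'   `central_layer`, `metadata` (`path`, `delimiter`, `kinds`),
#'   `correlation`, `figure` (`format`, `width`, `height`, `scaling`,
#'   `sample_annotations`: metadata variables drawn as sample tracks),
#'   `seed`.
#' @param out_dir Output directory (created if needed).
#' @param overwrite Remove a previous run's outputs first (default `FALSE`).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config_path, out_dir, overwrite = FALSE) {
  stage <- "config"
  fail <- function(e) stop(sprintf("pipeline stage '%s' failed: %s",
                                   stage, conditionMessage(e)), call. = FALSE)
  tryCatch({
    cfg <- yaml::read_yaml(config_path)
    if (is.null(cfg$layers) || !length(cfg$layers)) stop("config lists no layers")
    ids <- vapply(cfg$layers, `[[`, character(1), "id")
    if (is.null(cfg$central_layer)) stop("config must designate a central_layer")
    if (!cfg$central_layer %in% ids) {
      stop("central_layer '", cfg$central_layer, "' is not among the layers")
    }
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    manifest_path <- file.path(out_dir, "manifest.json")
    if (file.exists(manifest_path)) {
      if (!overwrite) {
        stop("output directory already holds a run manifest; pass overwrite = TRUE ",
             "or choose another out_dir")
      }
      old <- jsonlite::read_json(manifest_path)
      for (f in unlist(old$outputs)) {
        fp <- file.path(out_dir, f)
        if (file.exists(fp)) unlink(fp)
      }
      unlink(manifest_path)
    }
    seed <- cfg$seed %||% 1L
    set.seed(seed)
    inputs <- list()
    outputs <- character(0)
    emit <- function(rel) outputs <<- c(outputs, rel)

    stage <- "read"
    layers <- lapply(cfg$layers, function(lc) {
      if (!file.exists(lc$path)) stop("layer file not found: ", lc$path)
      inputs[[lc$id]] <<- list(path = lc$path,
                               md5 = unname(tools::md5sum(lc$path)))
      read_feature_table(lc$path,
                         orientation = lc$orientation %||% "samples-in-rows",
                         delimiter = lc$delimiter %||% "\t",
                         layer_id = lc$id)
    })
    metadata <- NULL
    if (!is.null(cfg$metadata)) {
      inputs[["metadata"]] <- list(path = cfg$metadata$path,
                                   md5 = unname(tools::md5sum(cfg$metadata$path)))
      kinds <- if (!is.null(cfg$metadata$kinds)) unlist(cfg$metadata$kinds)
      metadata <- read_metadata_table(cfg$metadata$path,
                                      delimiter = cfg$metadata$delimiter %||% "\t",
                                      kinds = kinds)
    }

    stage <- "align"
    bundle <- align_samples(layers, metadata)

    stage <- "preprocess"
    for (i in seq_along(cfg$layers)) {
      lc <- cfg$layers[[i]]
      pp <- lc$preprocessing %||% list()
      lay <- bundle$layers[[lc$id]]
      if (!is.null(pp$min_prevalence)) {
        lay <- filter_low_prevalence(lay, pp$min_prevalence,
                                     zero_is_absent = pp$zero_is_absent %||% TRUE)
      }
      if (isTRUE(pp$clr)) lay <- clr_transform(lay, pseudocount = pp$pseudocount)
      bundle$layers[[lc$id]] <- lay
    }

    stage <- "detect_modules"
    detections <- list()
    for (i in seq_along(cfg$layers)) {
      lc <- cfg$layers[[i]]
      params <- .params_from_config(lc$network)
      det <- detect_modules(bundle$layers[[lc$id]], params)
      if (!is.null(lc$labels)) det <- relabel_modules(det, unlist(lc$labels))
      detections[[lc$id]] <- det
      write_module_table(det, file.path(out_dir, sprintf("modules_%s.tsv", lc$id)),
                         scan_path = file.path(out_dir,
                                               sprintf("power_scan_%s.tsv", lc$id)))
      emit(sprintf("modules_%s.tsv", lc$id))
      if (!is.null(det$power_scan)) emit(sprintf("power_scan_%s.tsv", lc$id))
      if (is.null(det$hub_layer)) stop("layer '", lc$id, "' produced no modules")
      write_feature_table(det$hub_layer,
                          file.path(out_dir, sprintf("hubs_%s.tsv", lc$id)))
      emit(sprintf("hubs_%s.tsv", lc$id))
    }

    stage <- "order_central"
    central_id <- cfg$central_layer
    central_hubs <- detections[[central_id]]$hub_layer
    fig_cfg <- cfg$figure %||% list()
    ordering <- order_central_layer(central_hubs,
                                    distance = fig_cfg$distance %||% "correlation",
                                    linkage = fig_cfg$linkage %||% "average")

    stage <- "correlate"
    opts <- .options_from_config(cfg$correlation)
    right_blocks <- list()
    for (id in setdiff(names(detections), central_id)) {
      res <- calculate_correlations(central_hubs, detections[[id]]$hub_layer, opts)
      rel <- basename(write_correlation_result(res, out_dir))
      for (f in rel) emit(f)
      right_blocks[[id]] <- res
    }
    left_blocks <- list()
    if (!is.null(bundle$metadata)) {
      md_layer <- suppressMessages(encode_metadata(bundle$metadata))
      res <- calculate_correlations(central_hubs, md_layer, opts)
      rel <- basename(write_correlation_result(res, out_dir))
      for (f in rel) emit(f)
      left_blocks[["metadata"]] <- res
    }

    stage <- "figure"
    ann <- NULL
    if (!is.null(fig_cfg$sample_annotations) && !is.null(bundle$metadata)) {
      vars <- intersect(unlist(fig_cfg$sample_annotations),
                        names(bundle$metadata$data))
      if (length(vars)) {
        ann <- bundle$metadata$data[, vars, drop = FALSE]
      }
    }
    fspec <- integrated_figure_spec(central_hubs, ordering,
                                    left_blocks = left_blocks,
                                    right_blocks = right_blocks,
                                    sample_annotations = ann,
                                    scaling = fig_cfg$scaling %||% "row-z")
    fmt <- fig_cfg$format %||% "svg"
    fig_file <- paste0("integrated_heatmap.", fmt)
    assemble_integrated_figure(fspec, file.path(out_dir, fig_file), format = fmt,
                               width = fig_cfg$width %||% 12,
                               height = fig_cfg$height %||% 6,
                               dpi = fig_cfg$dpi %||% 150)
    emit(fig_file)

    stage <- "manifest"
    manifest <- list(
      config = cfg,
      inputs = inputs,
      outputs = as.list(outputs),
      seed = seed,
      n_common_samples = length(bundle$common_samples),
      dropped_samples = bundle$dropped,
      package_version = as.character(utils::packageVersion("holocorr")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, null = "null")
    invisible(manifest)
  }, error = fail)
}
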