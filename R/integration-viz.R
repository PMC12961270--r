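#' Hierarchically order the central layer's hubs
#'
#' Clusters the hub profiles (rows of the transposed hub table) and returns
#' the tree plus the leaf order. Distance `"correlation"` is `1 - pearson r`
#' between hub profiles; linkage defaults to average. `hclust` breaks merge
#' ties toward the smaller original index, so the order is deterministic.
#'
#' @param hub_layer An [omics_layer()] of hub profiles (samples x hubs),
#'   no missing values.
#' @param distance `"correlation"` or `"euclidean"`.
#' @param linkage `"average"`, `"complete"` or `"ward"` (Ward D2).
#' @return A `central_ordering`: list with `tree` (hclust or NULL for a
#'   single hub), `leaf_order` (hub ids in display order), `merge_tree`
#'   (data.frame a, b, height).
#' @export
order_central_layer <- function(hub_layer,
                                distance = c("correlation", "euclidean"),
                                linkage = c("average", "complete", "ward")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  stopifnot(inherits(hub_layer, "omics_layer"))
  if (anyNA(hub_layer$values)) stop("hub layer has missing values")
  ids <- hub_layer$feature_ids
  if (length(ids) < 2L) {
    warning("single hub: trivial ordering, no dendrogram")
    return(structure(list(tree = NULL, leaf_order = ids,
                          merge_tree = data.frame(a = integer(0), b = integer(0),
                                                  height = numeric(0))),
                     class = "central_ordering"))
  }
  M <- t(hub_layer$values)  # hubs x samples
  d <- if (distance == "correlation") {
    stats::as.dist(1 - stats::cor(t(M)))
  } else {
    stats::dist(M)
  }
  method <- c(average = "average", complete = "complete", ward = "ward.D2")[[linkage]]
  tree <- stats::hclust(d, method = method)
  structure(list(tree = tree, leaf_order = ids[tree$order],
                 merge_tree = data.frame(a = tree$merge[, 1L],
                                         b = tree$merge[, 2L],
                                         height = tree$height)),
            class = "central_ordering")
}

#' Display matrix for the central heatmap
#'
#' Transposes the hub table to modules x samples and (by default)
#' standardizes each module row to mean 0, sd 1 so modules with different
#' dynamic ranges are comparable. Rows follow `ordering` when given.
#'
#' @param hub_layer An [omics_layer()] (samples x hubs).
#' @param scaling `"row-z"` (default) or `"none"`.
#' @param ordering Optional `central_ordering`; its `leaf_order` sets the
#'   row order.
#' @return Numeric matrix, modules (hubs) x samples.
#' @export
central_heatmap_matrix <- function(hub_layer, scaling = c("row-z", "none"),
                                   ordering = NULL) {
  scaling <- match.arg(scaling)
  stopifnot(inherits(hub_layer, "omics_layer"))
  M <- t(hub_layer$values)
  if (scaling == "row-z") {
    sds <- apply(M, 1L, stats::sd)
    flat <- sds == 0 | is.na(sds)
    if (any(flat)) {
      warning("zero-variance row(s) rendered as zeros: ",
              paste(rownames(M)[flat], collapse = ", "))
    }
    M <- (M - rowMeans(M)) / ifelse(sds == 0, 1, sds)
    M[flat, ] <- 0
  }
  if (!is.null(ordering)) {
    stopifnot(setequal(ordering$leaf_order, rownames(M)))
    M <- M[ordering$leaf_order, , drop = FALSE]
  }
  M
}

#' Layout contract for the integrated figure
#'
#' Binds the central heatmap, its dendrogram, metadata correlation block(s)
#' (drawn to the left) and cross-layer correlation blocks (drawn to the
#' right) into one row-aligned figure. Every block's rows must be the central
#' hubs; blocks are reordered to the central leaf order here, and any id
#' mismatch is an error.
#'
#' @param central_layer The central [omics_layer()] of hub profiles.
#' @param ordering A `central_ordering` from [order_central_layer()].
#' @param left_blocks List of `correlation_result`s (typically hubs x
#'   metadata).
#' @param right_blocks List of `correlation_result`s (hubs x other layers'
#'   hubs).
#' @param sample_annotations Optional data.frame of categorical sample tracks
#'   (rownames = sample ids); also sets the sample order (grouped), else
#'   samples are clustered.
#' @param scaling Central heatmap scaling, see [central_heatmap_matrix()].
#' @return An `integrated_figure_spec`.
#' @export
integrated_figure_spec <- function(central_layer, ordering,
                                   left_blocks = list(), right_blocks = list(),
                                   sample_annotations = NULL,
                                   scaling = "row-z") {
  stopifnot(inherits(central_layer, "omics_layer"),
            inherits(ordering, "central_ordering"))
  check_block <- function(b) {
    stopifnot(inherits(b, "correlation_result"))
    if (!setequal(b$row_ids, ordering$leaf_order)) {
      stop(sprintf("block %s x %s rows do not match the central hubs", b$x_id, b$y_id))
    }
    b
  }
  left_blocks <- lapply(left_blocks, check_block)
  right_blocks <- lapply(right_blocks, check_block)
  if (!is.null(sample_annotations)) {
    stopifnot(setequal(rownames(sample_annotations), central_layer$sample_ids))
    sample_annotations <- sample_annotations[central_layer$sample_ids, , drop = FALSE]
  }
  structure(list(central_layer = central_layer, ordering = ordering,
                 left_blocks = left_blocks, right_blocks = right_blocks,
                 sample_annotations = sample_annotations, scaling = scaling),
            class = "integrated_figure_spec")
}

# reorder a correlation block's matrices to the central leaf order
.block_in_order <- function(block, leaf_order) {
  if (!setequal(block$row_ids, leaf_order)) {
    stop(sprintf("block %s x %s rows do not match the central ordering",
                 block$x_id, block$y_id))
  }
  for (k in c("r", "p", "p_adj", "labels", "n_pairs")) {
    block[[k]] <- block[[k]][leaf_order, , drop = FALSE]
  }
  block$row_ids <- leaf_order
  block
}

#' Render the integrated annotated heatmap
#'
#' Central heatmap (with dendrogram) in the middle, metadata correlation
#' block(s) on the left, one correlation block per additional omics layer on
#' the right. Correlation blocks use a diverging scale fixed to `[-1, 1]`
#' and overlay their significance labels per cell.
#'
#' @param spec An [integrated_figure_spec()].
#' @param path Output file path.
#' @param format `"svg"`, `"pdf"` or `"png"`.
#' @param width,height Figure size in inches.
#' @param dpi Raster resolution for PNG.
#' @return `path`, invisibly.
#' @export
assemble_integrated_figure <- function(spec, path, format = c("svg", "pdf", "png"),
                                       width = 12, height = 6, dpi = 150) {
  format <- match.arg(format)
  stopifnot(inherits(spec, "integrated_figure_spec"))
  leaf <- spec$ordering$leaf_order
  central <- central_heatmap_matrix(spec$central_layer, spec$scaling)
  central <- central[leaf, , drop = FALSE]

  lim <- max(abs(central), 1e-9)
  central_col <- circlize::colorRamp2(c(-lim, 0, lim),
                                      c("#2166AC", "#F7F7F7", "#B2182B"))
  corr_col <- circlize::colorRamp2(c(-1, 0, 1),
                                   c("#2166AC", "#F7F7F7", "#B2182B"))

  row_dend <- if (!is.null(spec$ordering$tree)) {
    stats::as.dendrogram(spec$ordering$tree)
  } else FALSE

  top_anno <- NULL
  cluster_cols <- is.null(spec$sample_annotations)
  col_order <- NULL
  if (!is.null(spec$sample_annotations)) {
    ann <- spec$sample_annotations
    col_order <- order(do.call(paste, c(ann, sep = "\r")))
    top_anno <- ComplexHeatmap::HeatmapAnnotation(
      df = ann[col_order, , drop = FALSE])
    central <- central[, col_order, drop = FALSE]
  }

  block_heatmap <- function(block, title) {
    b <- .block_in_order(block, leaf)
    labs <- b$labels
    ComplexHeatmap::Heatmap(
      b$r, name = title, col = corr_col,
      cluster_rows = FALSE, cluster_columns = FALSE,
      column_title = title,
      na_col = "grey85",
      cell_fun = function(j, i, x, y, w, h, fill) {
        if (!is.na(labs[i, j]) && nzchar(labs[i, j])) {
          grid::grid.text(labs[i, j], x, y, gp = grid::gpar(fontsize = 8))
        }
      },
      width = grid::unit(8 * ncol(b$r), "mm"))
  }

  central_hm <- ComplexHeatmap::Heatmap(
    central, name = "profile", col = central_col,
    cluster_rows = row_dend, cluster_columns = cluster_cols,
    row_order = if (isFALSE(row_dend)) seq_len(nrow(central)) else NULL,
    column_title = spec$central_layer$layer_id,
    top_annotation = top_anno,
    show_column_names = ncol(central) <= 40)

  hm_list <- NULL
  for (b in spec$left_blocks) {
    blk <- block_heatmap(b, paste0(b$y_id))
    hm_list <- if (is.null(hm_list)) blk else hm_list + blk
  }
  hm_list <- if (is.null(hm_list)) central_hm else hm_list + central_hm
  for (b in spec$right_blocks) {
    hm_list <- hm_list + block_heatmap(b, paste0(b$y_id))
  }

  switch(format,
         svg = grDevices::svg(path, width = width, height = height),
         pdf = grDevices::pdf(path, width = width, height = height),
         png = grDevices::png(path, width = width, height = height,
                              units = "in", res = dpi))
  on.exit(grDevices::dev.off(), add = TRUE)
  ComplexHeatmap::draw(hm_list, main_heatmap = length(spec$left_blocks) + 1L,
                       merge_legends = TRUE)
  invisible(path)
}
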