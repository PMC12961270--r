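#' Parameters for weighted correlation network module detection
#'
#' @param correlation_method `"pearson"` or `"spearman"`; similarity used to
#'   build the network (independent of the cross-layer correlation method).
#' @param sign_mode `"unsigned"` (adjacency `|r|^beta`) or `"signed"`
#'   (`((1+r)/2)^beta`; anti-correlated features get adjacency near 0).
#' @param power Soft-threshold exponent beta (>= 1), or `"auto"` to pick the
#'   smallest candidate on `power_grid` whose scale-free fit reaches
#'   `rsq_target`. Block-structured data (a few large modules) is not
#'   scale-free; supply a fixed beta (6 is the common unsigned default) there.
#' @param power_grid Candidate betas scanned when `power = "auto"`.
#' @param rsq_target Scale-free model fit (signed R^2) considered adequate.
#' @param cut_height Static dendrogram cut, as a fraction of the maximum
#'   merge height of the average-linkage tree on `1 - TOM`.
#' @param min_module_size Smallest branch kept as a module; smaller branches
#'   become `"unassigned"`.
#' @param merge_cut_height Modules whose eigengenes correlate above
#'   `1 - merge_cut_height` are merged (0 disables merging).
#' @param max_features Single-block size guard; larger inputs are refused.
#' @return A `network_params` list.
#' @export
network_params <- function(correlation_method = c("pearson", "spearman"),
                           sign_mode = c("unsigned", "signed"),
                           power = "auto", power_grid = 1:20,
                           rsq_target = 0.8, cut_height = 0.99,
                           min_module_size = 20, merge_cut_height = 0.25,
                           max_features = 20000) {
  correlation_method <- match.arg(correlation_method)
  sign_mode <- match.arg(sign_mode)
  if (!identical(power, "auto")) {
    power <- as.numeric(power)
    stopifnot(length(power) == 1L, is.finite(power), power >= 1)
  }
  stopifnot(all(power_grid >= 1),
            rsq_target > 0, rsq_target <= 1,
            cut_height > 0, cut_height <= 1,
            min_module_size >= 2,
            merge_cut_height >= 0, merge_cut_height <= 1,
            max_features >= 2)
  structure(list(correlation_method = correlation_method,
                 sign_mode = sign_mode, power = power,
                 power_grid = power_grid, rsq_target = rsq_target,
                 cut_height = cut_height, min_module_size = min_module_size,
                 merge_cut_height = merge_cut_height,
                 max_features = max_features),
            class = "network_params")
}

.unassigned_label <- "unassigned"

.check_variances <- function(layer) {
  v <- apply(layer$values, 2L, stats::var)
  bad <- layer$feature_ids[v == 0 | !is.finite(v)]
  if (length(bad)) {
    stop("zero-variance feature(s): ", paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (+%d more)", length(bad) - 5) else "",
         "; filter before module detection")
  }
  invisible(TRUE)
}

.feature_correlation <- function(layer, method) {
  if (anyNA(layer$values)) {
    stop("missing values are not allowed inside module detection; impute or filter first")
  }
  stats::cor(layer$values, method = method)
}

#' Soft-threshold adjacency from a correlation matrix
#'
#' Unsigned mode raises `|r|` to the power beta; signed mode raises
#' `(1 + r)/2`, so perfect anti-correlation maps to 0. The diagonal is 1.
#'
#' @param R Symmetric feature correlation matrix, unit diagonal.
#' @param beta Soft-threshold power (>= 1).
#' @param sign_mode `"unsigned"` or `"signed"`.
#' @return Symmetric adjacency matrix with entries in `[0, 1]`.
#' @export
adjacency_from_correlation <- function(R, beta, sign_mode = c("unsigned", "signed")) {
  sign_mode <- match.arg(sign_mode)
  R <- as.matrix(R)
  if (nrow(R) != ncol(R) || max(abs(R - t(R))) > 1e-8) {
    stop("correlation matrix must be symmetric")
  }
  stopifnot(beta >= 1, all(abs(R) <= 1 + 1e-8))
  A <- if (sign_mode == "unsigned") abs(R)^beta else ((1 + R) / 2)^beta
  A <- (A + t(A)) / 2
  A[A > 1] <- 1
  diag(A) <- 1
  A
}

#' Topological overlap similarity
#'
#' For adjacency `A` with connectivity `k_i = sum_{u != i} A_iu`:
#' `TOM_ij = (sum_{u != i,j} A_iu A_uj + A_ij) / (min(k_i, k_j) + 1 - A_ij)`,
#' `TOM_ii = 1`. Shared-neighbor structure stabilizes the clustering relative
#' to raw adjacency.
#'
#' @param A Adjacency matrix (symmetric, entries in `[0,1]`, unit diagonal).
#' @return The TOM matrix (same shape, symmetric, entries in `[0,1]`, unit
#'   diagonal).
#' @export
tom_similarity <- function(A) {
  A <- as.matrix(A)
  stopifnot(nrow(A) == ncol(A))
  if (max(abs(A - t(A))) > 1e-8) stop("adjacency must be symmetric")
  if (min(A) < -1e-12 || max(A) > 1 + 1e-12) stop("adjacency entries must lie in [0,1]")
  A0 <- A
  diag(A0) <- 0
  k <- colSums(A0)
  shared <- A0 %*% A0                     # sum_u A_iu A_uj; diag(A0)=0 removes u=i and u=j
  kmin <- outer(k, k, pmin)
  tom <- (shared + A0) / (kmin + 1 - A0)
  tom[!is.finite(tom)] <- 0               # isolated node pairs (k_i = k_j = A_ij = 0)
  tom <- (tom + t(tom)) / 2
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  diag(tom) <- 1
  dimnames(tom) <- dimnames(A)
  tom
}

#' Scan soft-threshold powers for scale-free fit
#'
#' For each candidate beta the network connectivities are binned (<= 10
#' occupied bins of log10 k) and `log10 p(k)` is regressed on `log10 k`;
#' the fit is reported as R^2 signed by the slope (a negative slope, the
#' scale-free direction, gives a positive value). The chosen beta is the
#' smallest candidate reaching `rsq_target`, else the candidate with maximal
#' fit (with a warning).
#'
#' @param layer An [omics_layer()] without missing values.
#' @param params A [network_params()].
#' @return List with `fit_table` (data.frame: power, scale_free_rsq,
#'   mean_connectivity) and `chosen_power`.
#' @export
soft_threshold_scan <- function(layer, params = network_params()) {
  stopifnot(inherits(layer, "omics_layer"))
  if (length(layer$sample_ids) < 8) {
    warning("fewer than 8 samples: network inference is unreliable")
  }
  if (length(layer$feature_ids) < 2) stop("need at least 2 features")
  .check_variances(layer)
  R <- .feature_correlation(layer, params$correlation_method)
  rows <- lapply(params$power_grid, function(beta) {
    A <- adjacency_from_correlation(R, beta, params$sign_mode)
    k <- colSums(A) - 1
    data.frame(power = beta,
               scale_free_rsq = .scale_free_fit(k),
               mean_connectivity = mean(k))
  })
  fit <- do.call(rbind, rows)
  hit <- which(fit$scale_free_rsq >= params$rsq_target)
  if (length(hit)) {
    chosen <- fit$power[hit[1L]]
  } else {
    chosen <- fit$power[which.max(fit$scale_free_rsq)]
    warning(sprintf(
      "no candidate power reached scale-free fit %.2f; using power %g (fit %.3f)",
      params$rsq_target, chosen, max(fit$scale_free_rsq)))
  }
  list(fit_table = fit, chosen_power = chosen)
}

# signed scale-free model fit of a connectivity vector: bin log10(k) into
# <= n_bins occupied bins, regress log10(p(k)) on mean log10(k) per bin,
# return sign(-slope) * R^2
.scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < 3) return(NA_real_)
  if (max(k) - min(k) < 1e-12) return(NA_real_)  # degenerate: all equal
  lk <- log10(k)
  breaks <- unique(seq(min(lk), max(lk), length.out = n_bins + 1))
  bin <- cut(lk, breaks = breaks, include.lowest = TRUE)
  kmid <- tapply(lk, bin, mean)
  pk <- tapply(lk, bin, length) / length(lk)
  keep <- !is.na(kmid) & pk > 0
  if (sum(keep) < 3) return(NA_real_)
  x <- kmid[keep]; y <- log10(pk[keep])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  r <- stats::cor(x, y)
  -sign(r) * r^2
}

#' Cut the TOM dendrogram into modules
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, cut at a fixed
#' height (`cut_height` times the maximum merge height). Branches of at least
#' `min_module_size` features become modules, labelled `"M1"`, `"M2"`, ... by
#' decreasing size; everything else is `"unassigned"`.
#'
#' @param tom TOM matrix from [tom_similarity()], with feature dimnames.
#' @param params A [network_params()].
#' @return A `module_assignment`: list with `feature_ids`, `labels`,
#'   `unassigned_label`, and the `hclust` tree (`tree`).
#' @export
cut_dendrogram_to_modules <- function(tom, params = network_params()) {
  ids <- colnames(tom)
  if (is.null(ids)) ids <- paste0("f", seq_len(ncol(tom)))
  n <- length(ids)
  if (n < params$min_module_size) {
    warning("fewer features than min_module_size: all features unassigned")
    return(structure(list(feature_ids = ids,
                          labels = rep(.unassigned_label, n),
                          unassigned_label = .unassigned_label, tree = NULL),
                     class = "module_assignment"))
  }
  d <- stats::as.dist(1 - tom)
  tree <- stats::hclust(d, method = "average")
  h <- params$cut_height * max(tree$height)
  raw <- stats::cutree(tree, h = h)
  labels <- .size_rank_labels(raw, params$min_module_size)
  structure(list(feature_ids = ids, labels = labels,
                 unassigned_label = .unassigned_label, tree = tree),
            class = "module_assignment")
}

# relabel integer clusters as M1.. by decreasing size (ties: smallest first
# member index), branches under min_size -> unassigned
.size_rank_labels <- function(raw, min_size) {
  tab <- table(raw)
  big <- names(tab)[tab >= min_size]
  first_idx <- vapply(big, function(g) which(raw == g)[1L], integer(1))
  ord <- big[order(-tab[big], first_idx)]
  map <- stats::setNames(paste0("M", seq_along(ord)), ord)
  out <- rep(.unassigned_label, length(raw))
  hit <- as.character(raw) %in% names(map)
  out[hit] <- unname(map[as.character(raw)[hit]])
  out
}

#' Module eigengene
#'
#' First principal component of the column-standardized member submatrix,
#' scaled to unit Euclidean norm, with sign oriented so that it correlates
#' positively with the mean standardized member profile.
#'
#' @param layer An [omics_layer()].
#' @param members Feature ids of the module.
#' @return Numeric vector over samples, unit norm.
#' @export
module_eigengene <- function(layer, members) {
  stopifnot(length(members) >= 1L, all(members %in% layer$feature_ids))
  X <- layer$values[, members, drop = FALSE]
  if (anyNA(X)) stop("missing values among module members; impute or drop first")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance member(s): ", paste(members[sds == 0], collapse = ", "))
  }
  Z <- scale(X)
  e <- svd(Z, nu = 1L, nv = 0L)$u[, 1L]
  e <- e / sqrt(sum(e^2))
  profile <- rowMeans(Z)
  if (stats::sd(profile) > 0 && stats::cor(e, profile) < 0) e <- -e
  stats::setNames(e, layer$sample_ids)
}

#' Merge modules with near-identical eigengenes
#'
#' Iteratively merges the most-correlated module pair while the correlation
#' is at least `1 - merge_cut_height`, then relabels by size.
#'
#' @param layer The [omics_layer()] the assignment was computed on.
#' @param assignment A `module_assignment`.
#' @param merge_cut_height Eigengene-dissimilarity threshold in `[0, 1]`.
#' @return The merged `module_assignment`.
#' @export
merge_close_modules <- function(layer, assignment, merge_cut_height = 0.25) {
  stopifnot(merge_cut_height >= 0, merge_cut_height <= 1)
  labels <- assignment$labels
  repeat {
    mods <- setdiff(unique(labels), assignment$unassigned_label)
    if (length(mods) < 2L) break
    E <- vapply(mods, function(m)
      module_eigengene(layer, assignment$feature_ids[labels == m]),
      numeric(length(layer$sample_ids)))
    C <- stats::cor(E)
    diag(C) <- -Inf
    best <- which(C == max(C), arr.ind = TRUE)[1L, ]
    if (C[best[1L], best[2L]] < 1 - merge_cut_height) break
    labels[labels == mods[best[2L]]] <- mods[best[1L]]
  }
  # relabel by decreasing size over the surviving modules
  mods <- setdiff(unique(labels), assignment$unassigned_label)
  if (length(mods)) {
    sizes <- vapply(mods, function(m) sum(labels == m), integer(1))
    first_idx <- vapply(mods, function(m) which(labels == m)[1L], integer(1))
    ord <- mods[order(-sizes, first_idx)]
    map <- stats::setNames(paste0("M", seq_along(ord)), ord)
    hit <- labels %in% names(map)
    labels[hit] <- unname(map[labels[hit]])
  }
  structure(list(feature_ids = assignment$feature_ids, labels = labels,
                 unassigned_label = assignment$unassigned_label,
                 tree = assignment$tree),
            class = "module_assignment")
}

#' Intramodular connectivity
#'
#' `k_within(i)` is the sum of feature i's adjacency to the other members of
#' its module; 0 for unassigned features. The basis for hub selection.
#'
#' @param A Adjacency matrix with feature dimnames.
#' @param assignment A `module_assignment` over the same features.
#' @return Named numeric vector of per-feature `k_within`.
#' @export
intramodular_connectivity <- function(A, assignment) {
  ids <- assignment$feature_ids
  stopifnot(identical(colnames(A), ids))
  k <- stats::setNames(numeric(length(ids)), ids)
  for (m in setdiff(unique(assignment$labels), assignment$unassigned_label)) {
    idx <- which(assignment$labels == m)
    sub <- A[idx, idx, drop = FALSE]
    k[idx] <- rowSums(sub) - diag(sub)
  }
  k
}

#' Extract the top hub of each module
#'
#' The hub is the member with maximal intramodular connectivity (ties broken
#' toward the lexicographically smallest feature id, with a message). The hub
#' layer collects the hubs' original profiles: samples x hubs.
#'
#' @param layer The source [omics_layer()].
#' @param assignment A `module_assignment`.
#' @param k_within Connectivity from [intramodular_connectivity()].
#' @return List with `hubs` (named character: module -> hub feature id) and
#'   `hub_layer` (an [omics_layer()] with provenance `"hubs"`).
#' @export
top_hub_per_module <- function(layer, assignment, k_within) {
  mods <- setdiff(unique(assignment$labels), assignment$unassigned_label)
  mods <- mods[order(as.integer(sub("^M", "", mods)))]
  hubs <- vapply(mods, function(m) {
    members <- assignment$feature_ids[assignment$labels == m]
    kv <- k_within[members]
    top <- members[kv == max(kv)]
    if (length(top) > 1L) {
      top <- sort(top)
      message(sprintf("module %s: k_within tie among {%s}; taking '%s'",
                      m, paste(top, collapse = ", "), top[1L]))
    }
    top[1L]
  }, character(1))
  hub_layer <- if (length(hubs)) {
    omics_layer(layer$values[, unname(hubs), drop = FALSE],
                layer_id = layer$layer_id, provenance = "hubs")
  } else NULL
  list(hubs = hubs, hub_layer = hub_layer)
}

#' Detect co-varying feature modules and their hubs
#'
#' The full reduction of one omics layer: feature correlation network with
#' soft thresholding, topological overlap, static dendrogram cut with a
#' minimum module size, eigengene-based merging, intramodular connectivity,
#' and one hub per module. Deterministic for fixed input and parameters.
#'
#' @param layer An [omics_layer()] with no missing values and no
#'   zero-variance features.
#' @param params A [network_params()].
#' @return A `module_detection_result`: list with `assignment`, `eigengenes`
#'   (samples x modules matrix), `k_within`, `hubs`, `hub_layer`, `params`,
#'   `power_scan` (NULL when a fixed power was supplied) and `power` used.
#' @export
detect_modules <- function(layer, params = network_params()) {
  stopifnot(inherits(layer, "omics_layer"))
  if (length(layer$feature_ids) > params$max_features) {
    stop(sprintf("layer has %d features, above the single-block cap of %d; pre-filter the layer",
                 length(layer$feature_ids), params$max_features))
  }
  .check_variances(layer)
  scan <- NULL
  if (identical(params$power, "auto")) {
    scan <- soft_threshold_scan(layer, params)
    beta <- scan$chosen_power
  } else {
    beta <- params$power
  }
  R <- .feature_correlation(layer, params$correlation_method)
  A <- adjacency_from_correlation(R, beta, params$sign_mode)
  tom <- tom_similarity(A)
  assignment <- cut_dendrogram_to_modules(tom, params)
  if (params$merge_cut_height > 0 &&
      length(setdiff(unique(assignment$labels), assignment$unassigned_label)) > 1L) {
    assignment <- merge_close_modules(layer, assignment, params$merge_cut_height)
  }
  k_within <- intramodular_connectivity(A, assignment)
  th <- top_hub_per_module(layer, assignment, k_within)
  mods <- setdiff(unique(assignment$labels), assignment$unassigned_label)
  mods <- mods[order(as.integer(sub("^M", "", mods)))]
  eig <- if (length(mods)) {
    vapply(mods, function(m)
      module_eigengene(layer, assignment$feature_ids[assignment$labels == m]),
      numeric(length(layer$sample_ids)))
  } else NULL
  structure(list(assignment = assignment, eigengenes = eig,
                 k_within = k_within, hubs = th$hubs,
                 hub_layer = th$hub_layer, params = params,
                 power = beta, power_scan = scan),
            class = "module_detection_result")
}

#' @export
print.module_detection_result <- function(x, ...) {
  mods <- setdiff(unique(x$assignment$labels), x$assignment$unassigned_label)
  cat(sprintf("<module_detection_result '%s'> %d modules (power %g), %d/%d features assigned\n",
              x$hub_layer$layer_id %||% "?", length(mods), x$power,
              sum(x$assignment$labels != x$assignment$unassigned_label),
              length(x$assignment$feature_ids)))
  if (length(x$hubs)) {
    cat("hubs:", paste(sprintf("%s=%s", names(x$hubs), x$hubs), collapse = ", "), "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rename modules with user-supplied labels
#'
#' Applies an external label map (e.g. enrichment-derived names) to a
#' detection result, renaming the assignment, eigengenes, hubs and hub-layer
#' columns consistently.
#'
#' @param result A `module_detection_result`.
#' @param label_map Named character vector, `c(M1 = "carbohydrate", ...)`.
#' @return The relabelled result.
#' @export
relabel_modules <- function(result, label_map) {
  stopifnot(inherits(result, "module_detection_result"))
  unknown <- setdiff(names(label_map), result$assignment$labels)
  if (length(unknown)) stop("label map names unknown modules: ",
                            paste(unknown, collapse = ", "))
  ren <- function(x) ifelse(x %in% names(label_map), unname(label_map[x]), x)
  result$assignment$labels <- ren(result$assignment$labels)
  names(result$hubs) <- ren(names(result$hubs))
  if (!is.null(result$eigengenes)) colnames(result$eigengenes) <- ren(colnames(result$eigengenes))
  result
}

#' Write the module table and power-scan diagnostics
#'
#' The module table has columns `feature_id`, `module`, `k_within`,
#' `is_hub` (0/1); the scan table `power`, `scale_free_rsq`,
#' `mean_connectivity`.
#'
#' @param result A `module_detection_result`.
#' @param path Output TSV path for the module table.
#' @param scan_path Optional output path for the power-scan table.
#' @return `path`, invisibly.
#' @export
write_module_table <- function(result, path, scan_path = NULL) {
  a <- result$assignment
  df <- data.frame(feature_id = a$feature_ids, module = a$labels,
                   k_within = unname(result$k_within[a$feature_ids]),
                   is_hub = as.integer(a$feature_ids %in% result$hubs))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(scan_path) && !is.null(result$power_scan)) {
    utils::write.table(result$power_scan$fit_table, scan_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
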