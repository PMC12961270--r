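#' Specification for a simulated holo-omics bundle
#'
#' The generator plants the statistical structure the module-first workflow
#' assumes: within each layer, modules of features loading on a Gaussian
#' latent factor; cross-layer interactions as correlated factors; metadata
#' variables driven by factors. Feature j of a module with loading `a` is
#' `a * f + sqrt(1 - a^2) * e` with standard-normal factor `f` and noise `e`,
#' so the expected within-module feature correlation is `a^2` and the
#' expected hub-hub correlation of two coupled modules is `a_a * a_b * rho`.
#'
#' @param n_samples Number of samples shared by all layers.
#' @param layers List of layer specs: each a list with `layer_id`, `modules`
#'   (list of `list(module_id, n_features, loading)` with loading in (0,1];
#'   loading 1 is the noiseless limit),
#'   and `n_background` pure-noise features.
#' @param couplings List of `list(layer_a, module_a, layer_b, module_b, rho)`
#'   with `|rho| <= 1`; factors of coupled modules are drawn jointly
#'   bivariate normal.
#' @param metadata_links List of `list(name, layer, module, effect, kind)`;
#'   kind `"numeric"` gives `effect * f + sqrt(1 - effect^2) * e`, kind
#'   `"binary"` gives `indicator(f > 0)` with flip probability
#'   `(1 - effect)/2`.
#' @param missing_rate Completely-at-random knockout fraction in [0, 0.5].
#' @param compositional If `TRUE`, layer rows are exponentiated and closed to
#'   the unit simplex (feeds the centered log-ratio tests); default off.
#' @param seed Master seed; all draws flow from it through fixed sub-streams
#'   (factors, then each layer's feature noise, then metadata, then
#'   missingness) so one layer's feature noise does not depend on another's.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_samples, layers, couplings = list(),
                            metadata_links = list(), missing_rate = 0,
                            compositional = FALSE, seed = 1L) {
  stopifnot(n_samples >= 2, length(layers) >= 1,
            missing_rate >= 0, missing_rate <= 0.5)
  layer_ids <- vapply(layers, `[[`, character(1), "layer_id")
  stopifnot(!anyDuplicated(layer_ids))
  mod_keys <- character(0)
  for (l in layers) {
    for (m in l$modules) {
      stopifnot(m$loading > 0, m$loading <= 1, m$n_features >= 1)
      mod_keys <- c(mod_keys, paste0(l$layer_id, ":", m$module_id))
    }
  }
  stopifnot(!anyDuplicated(mod_keys))
  for (cp in couplings) {
    stopifnot(abs(cp$rho) <= 1,
              paste0(cp$layer_a, ":", cp$module_a) %in% mod_keys,
              paste0(cp$layer_b, ":", cp$module_b) %in% mod_keys)
  }
  for (ml in metadata_links) {
    stopifnot(ml$kind %in% c("numeric", "binary"),
              paste0(ml$layer, ":", ml$module) %in% mod_keys,
              ml$effect > 0, ml$effect <= 1)
  }
  structure(list(n_samples = as.integer(n_samples), layers = layers,
                 couplings = couplings, metadata_links = metadata_links,
                 missing_rate = missing_rate, compositional = compositional,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# factor correlation matrix over all planted modules; identity plus rho at
# coupled pairs; must be positive semidefinite or the couplings are infeasible
.factor_cor_matrix <- function(spec) {
  keys <- unlist(lapply(spec$layers, function(l)
    vapply(l$modules, function(m) paste0(l$layer_id, ":", m$module_id),
           character(1))))
  S <- diag(length(keys))
  dimnames(S) <- list(keys, keys)
  for (cp in spec$couplings) {
    a <- paste0(cp$layer_a, ":", cp$module_a)
    b <- paste0(cp$layer_b, ":", cp$module_b)
    S[a, b] <- S[b, a] <- cp$rho
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    deg <- names(which(colSums(S != 0) > 2))
    stop("coupling correlations are not jointly feasible (factor matrix not positive semidefinite); check modules coupled to several partners: ",
         paste(deg, collapse = ", "))
  }
  S
}

#' Simulate a multi-layer holo-omics bundle with planted truth
#'
#' @param spec A [simulation_spec()].
#' @return List with `bundle` (an `aligned_bundle`) and `truth`
#'   (a `planted_truth`: per-layer assignments, the factor matrix, couplings
#'   with realized correlations, and metadata links).
#' @export
simulate_bundle <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  n <- spec$n_samples
  samples <- sprintf("s%03d", seq_len(n))
  S <- .factor_cor_matrix(spec)
  keys <- colnames(S)

  set.seed(spec$seed)
  Z <- matrix(stats::rnorm(n * length(keys)), n, length(keys))
  ev <- eigen(S, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), length(keys)) %*% t(ev$vectors)
  FActs <- Z %*% L
  colnames(FActs) <- keys
  rownames(FActs) <- samples

  layers <- list()
  assignments <- list()
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    set.seed(spec$seed + 1000L * i)
    cols <- list()
    truth <- character(0)
    for (m in l$modules) {
      f <- FActs[, paste0(l$layer_id, ":", m$module_id)]
      a <- m$loading
      eps <- matrix(stats::rnorm(n * m$n_features), n, m$n_features)
      X <- a * f + sqrt(1 - a^2) * eps
      colnames(X) <- sprintf("%s_%s_f%02d", l$layer_id, m$module_id,
                             seq_len(m$n_features))
      cols[[m$module_id]] <- X
      truth <- c(truth, stats::setNames(rep(m$module_id, m$n_features),
                                        colnames(X)))
    }
    nb <- l$n_background %||% 0L
    if (nb > 0) {
      B <- matrix(stats::rnorm(n * nb), n, nb)
      colnames(B) <- sprintf("%s_bg_f%02d", l$layer_id, seq_len(nb))
      cols[["..background"]] <- B
      truth <- c(truth, stats::setNames(rep("background", nb), colnames(B)))
    }
    vals <- do.call(cbind, unname(cols))
    if (isTRUE(spec$compositional)) {
      e <- exp(vals)
      vals <- e / rowSums(e)
    }
    layers[[l$layer_id]] <- omics_layer(vals, sample_ids = samples,
                                        layer_id = l$layer_id,
                                        provenance = if (isTRUE(spec$compositional))
                                          "simulated-compositional" else "simulated")
    assignments[[l$layer_id]] <- truth
  }

  metadata <- NULL
  if (length(spec$metadata_links)) {
    set.seed(spec$seed + 500000L)
    md <- list()
    kinds <- character(0)
    for (ml in spec$metadata_links) {
      f <- FActs[, paste0(ml$layer, ":", ml$module)]
      b <- ml$effect
      if (ml$kind == "numeric") {
        md[[ml$name]] <- b * f + sqrt(1 - b^2) * stats::rnorm(n)
        kinds[ml$name] <- "numeric"
      } else {
        flip_p <- (1 - b) / 2
        message(sprintf("binary metadata '%s': flip probability %.3f from effect %.2f",
                        ml$name, flip_p, b))
        bit <- as.integer(f > 0)
        flip <- stats::runif(n) < flip_p
        bit[flip] <- 1L - bit[flip]
        md[[ml$name]] <- c("low", "high")[bit + 1L]
        kinds[ml$name] <- "binary"
      }
    }
    metadata <- sample_metadata(as.data.frame(md, check.names = FALSE),
                                sample_ids = samples, kinds = kinds)
  }

  if (spec$missing_rate > 0) {
    set.seed(spec$seed + 600000L)
    for (id in names(layers)) {
      v <- layers[[id]]$values
      knock <- matrix(stats::runif(length(v)) < spec$missing_rate,
                      nrow(v), ncol(v))
      v[knock] <- NA_real_
      layers[[id]] <- omics_layer(v, layer_id = id,
                                  provenance = layers[[id]]$provenance)
    }
  }

  realized <- lapply(spec$couplings, function(cp) {
    a <- paste0(cp$layer_a, ":", cp$module_a)
    b <- paste0(cp$layer_b, ":", cp$module_b)
    cp$realized_rho <- stats::cor(FActs[, a], FActs[, b])
    cp
  })

  bundle <- structure(list(layers = layers, metadata = metadata,
                           common_samples = samples,
                           dropped = list()),
                      class = "aligned_bundle")
  truth <- structure(list(assignments = assignments, factors = FActs,
                          couplings = realized,
                          metadata_links = spec$metadata_links,
                          spec = spec),
                     class = "planted_truth")
  list(bundle = bundle, truth = truth)
}

#' Adjusted Rand index between two labelled partitions
#'
#' Chance-corrected agreement; 1 for identical partitions (up to label
#' permutation), ~0 for independent ones.
#'
#' @param a,b Label vectors of equal length.
#' @return The ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}

#' Score module recovery against the planted truth
#'
#' Background features and the detector's `"unassigned"` label each count as
#' their own class. Modules are matched greedily by maximal member overlap
#' (largest overlap first), then hubs and eigengenes are scored against their
#' matched true module and factor.
#'
#' @param truth A `planted_truth` from [simulate_bundle()].
#' @param result A `module_detection_result` for layer `layer_id`.
#' @param layer_id Which simulated layer the result was computed on.
#' @return List with `ari`, `matching` (data.frame inferred/true/overlap),
#'   `hub_in_true_module` (fraction), and `eigengene_factor_cor` (named
#'   absolute correlations per matched module).
#' @export
evaluate_recovery <- function(truth, result, layer_id) {
  stopifnot(inherits(truth, "planted_truth"),
            inherits(result, "module_detection_result"))
  true_lab <- truth$assignments[[layer_id]]
  if (is.null(true_lab)) stop("unknown layer: ", layer_id)
  ids <- result$assignment$feature_ids
  stopifnot(all(ids %in% names(true_lab)))
  inf_lab <- stats::setNames(result$assignment$labels, ids)
  true_lab <- true_lab[ids]

  ari <- adjusted_rand_index(true_lab, inf_lab)

  inf_mods <- setdiff(unique(inf_lab), result$assignment$unassigned_label)
  true_mods <- setdiff(unique(true_lab), "background")
  ov <- outer(inf_mods, true_mods, Vectorize(function(i, t)
    sum(inf_lab == i & true_lab == t)))
  dimnames(ov) <- list(inf_mods, true_mods)
  matching <- data.frame(inferred = character(0), true = character(0),
                         overlap = integer(0))
  ov_work <- ov
  while (length(ov_work) && any(ov_work > 0)) {
    best <- which(ov_work == max(ov_work), arr.ind = TRUE)[1L, ]
    matching <- rbind(matching, data.frame(
      inferred = rownames(ov_work)[best[1L]],
      true = colnames(ov_work)[best[2L]],
      overlap = ov_work[best[1L], best[2L]]))
    ov_work <- ov_work[-best[1L], -best[2L], drop = FALSE]
  }

  hub_ok <- NA_real_
  eig_cor <- numeric(0)
  if (nrow(matching)) {
    hub_hits <- vapply(seq_len(nrow(matching)), function(i) {
      hub <- result$hubs[[matching$inferred[i]]]
      true_lab[[hub]] == matching$true[i]
    }, logical(1))
    hub_ok <- mean(hub_hits)
    eig_cor <- vapply(seq_len(nrow(matching)), function(i) {
      e <- result$eigengenes[, matching$inferred[i]]
      f <- truth$factors[, paste0(layer_id, ":", matching$true[i])]
      abs(stats::cor(e, f))
    }, numeric(1))
    names(eig_cor) <- matching$inferred
  }
  list(ari = ari, matching = matching, hub_in_true_module = hub_ok,
       eigengene_factor_cor = eig_cor)
}

#' Score cross-layer coupling detection on hub tables
#'
#' Power is the fraction of planted couplings whose matched hub-pair cell is
#' significant at `alpha` (adjusted p); couplings whose modules were not
#' recovered count as misses and are flagged via `unmatched`. The
#' false-positive rate is the fraction of non-planted pairs below `alpha`.
#'
#' @param truth A `planted_truth`.
#' @param result A `correlation_result` whose rows are layer `x_id` hubs and
#'   columns layer `y_id` hubs.
#' @param hubs_x,hubs_y Named character vectors (module label -> hub feature
#'   id) from the two layers' detection results.
#' @param matching_x,matching_y Matching data.frames from
#'   [evaluate_recovery()].
#' @param alpha Significance level on adjusted p-values.
#' @return List with `power` (NA when no couplings were planted), `fpr`,
#'   `n_couplings`, `unmatched`.
#' @export
evaluate_detection <- function(truth, result, hubs_x, hubs_y,
                               matching_x, matching_y, alpha = 0.05) {
  stopifnot(inherits(truth, "planted_truth"),
            inherits(result, "correlation_result"))
  cps <- Filter(function(cp)
    (cp$layer_a == result$x_id && cp$layer_b == result$y_id) ||
    (cp$layer_b == result$x_id && cp$layer_a == result$y_id),
    truth$couplings)
  planted <- matrix(FALSE, length(result$row_ids), length(result$col_ids),
                    dimnames = list(result$row_ids, result$col_ids))
  hits <- logical(0)
  unmatched <- 0L
  for (cp in cps) {
    if (cp$layer_a == result$x_id) { ma <- cp$module_a; mb <- cp$module_b }
    else { ma <- cp$module_b; mb <- cp$module_a }
    ia <- matching_x$inferred[matching_x$true == ma]
    ib <- matching_y$inferred[matching_y$true == mb]
    if (!length(ia) || !length(ib)) {
      unmatched <- unmatched + 1L
      hits <- c(hits, FALSE)
      next
    }
    hub_a <- hubs_x[[ia[1L]]]; hub_b <- hubs_y[[ib[1L]]]
    planted[hub_a, hub_b] <- TRUE
    padj <- result$p_adj[hub_a, hub_b]
    hits <- c(hits, !is.na(padj) && padj < alpha)
  }
  sig <- !is.na(result$p_adj) & result$p_adj < alpha
  null_cells <- !planted & !is.na(result$p_adj)
  list(power = if (length(hits)) mean(hits) else NA_real_,
       fpr = if (any(null_cells)) mean(sig[null_cells]) else NA_real_,
       n_couplings = length(cps), unmatched = unmatched)
}

#' Write a planted truth as JSON
#'
#' @param truth A `planted_truth`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  obj <- list(
    assignments = lapply(truth$assignments, as.list),
    factors = as.data.frame(truth$factors),
    couplings = truth$couplings,
    metadata_links = truth$metadata_links)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
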