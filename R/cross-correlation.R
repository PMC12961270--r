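#' Options for cross-layer correlation analysis
#'
#' @param method Correlation coefficient: `"pearson"`, `"spearman"` or
#'   `"kendall"` (tau-b).
#' @param use Missing-data policy: `"all.obs"` (missing data is an error),
#'   `"complete.obs"` (samples missing in any feature of either layer are
#'   dropped once), or `"pairwise.complete.obs"` (per-pair deletion).
#' @param adjust Multiple-testing adjustment over the whole matrix of one
#'   layer pair, as one family: `"fdr"` (Benjamini-Hochberg), `"bonferroni"`,
#'   `"holm"` or `"none"`.
#' @param annotation How cells are labelled: `"asterisks"`, `"pvalue"`
#'   (adjusted p to 3 significant digits) or `"correlation"` (r to 2
#'   decimals).
#' @param star_thresholds Three strictly decreasing p cutoffs for
#'   `*`, `**`, `***`, applied to adjusted p-values.
#' @param min_pairs Minimum per-pair sample count; pairs below it get missing
#'   r and p.
#' @return A `correlation_options` list.
#' @export
correlation_options <- function(method = c("pearson", "spearman", "kendall"),
                                use = c("pairwise.complete.obs", "all.obs",
                                        "complete.obs"),
                                adjust = c("fdr", "bonferroni", "holm", "none"),
                                annotation = c("asterisks", "pvalue", "correlation"),
                                star_thresholds = c(0.05, 0.01, 0.001),
                                min_pairs = 5L) {
  method <- match.arg(method)
  use <- match.arg(use)
  adjust <- match.arg(adjust)
  annotation <- match.arg(annotation)
  stopifnot(length(star_thresholds) == 3L,
            all(diff(star_thresholds) < 0),
            all(star_thresholds > 0), all(star_thresholds < 1),
            min_pairs >= 3L)
  structure(list(method = method, use = use, adjust = adjust,
                 annotation = annotation, star_thresholds = star_thresholds,
                 min_pairs = as.integer(min_pairs)),
            class = "correlation_options")
}

# exact two-sided Kendall p from the inversion-count (Mahonian) distribution:
# under the null every ranking is equally likely and the number of discordant
# pairs D is the number of inversions; P(|C - D| >= |observed|) with
# C - D = n(n-1)/2 - 2D
.kendall_exact_p <- function(n, s_obs) {
  counts <- 1
  for (m in 2:n) {   # counts[k+1] = #permutations of m elements with k inversions
    new <- numeric(length(counts) + m - 1)
    for (j in 0:(m - 1)) {
      new[seq_along(counts) + j] <- new[seq_along(counts) + j] + counts
    }
    counts <- new
  }
  total <- sum(counts)
  d <- seq_along(counts) - 1
  s <- n * (n - 1) / 2 - 2 * d
  sum(counts[abs(s) >= abs(s_obs) - 1e-9]) / total
}

#' Correlation test for one pair of sample vectors
#'
#' Missing entries are pair-deleted first. Pearson uses the product-moment
#' coefficient with a two-sided p from `t = r * sqrt((n-2)/(1-r^2))` on
#' `n - 2` degrees of freedom; Spearman applies the same t approximation to
#' the mid-rank coefficient; Kendall reports tau-b with an exact two-sided p
#' for n <= 8 without ties and the tie-corrected normal approximation
#' otherwise. `|r| = 1` gives p = 0; a constant vector after deletion gives
#' missing r and p (with a message).
#'
#' @param x,y Numeric vectors of equal length.
#' @param method `"pearson"`, `"spearman"` or `"kendall"`.
#' @param min_pairs Minimum complete pairs required.
#' @return List with `r`, `p`, `n` (complete pairs used).
#' @export
correlation_test <- function(x, y, method = c("pearson", "spearman", "kendall"),
                             min_pairs = 5L) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < min_pairs) {
    message(sprintf("only %d complete pairs (min_pairs = %d); correlation not computed",
                    n, min_pairs))
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    message("constant vector after pair deletion; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  if (method == "kendall") {
    r <- stats::cor(x, y, method = "kendall")
    tx <- any(duplicated(x)); ty <- any(duplicated(y))
    if (n <= 8 && !tx && !ty) {
      conc <- 0
      for (i in seq_len(n - 1)) {
        conc <- conc + sum(sign(x[(i + 1):n] - x[i]) * sign(y[(i + 1):n] - y[i]))
      }
      p <- .kendall_exact_p(n, conc)
    } else {
      # tau-b z statistic with tie correction (normal approximation)
      cnt_x <- table(x); cnt_y <- table(y)
      s <- 0
      for (i in seq_len(n - 1)) {
        s <- s + sum(sign(x[(i + 1):n] - x[i]) * sign(y[(i + 1):n] - y[i]))
      }
      v0 <- n * (n - 1) * (2 * n + 5)
      vt <- sum(cnt_x * (cnt_x - 1) * (2 * cnt_x + 5))
      vu <- sum(cnt_y * (cnt_y - 1) * (2 * cnt_y + 5))
      v1 <- sum(cnt_x * (cnt_x - 1)) * sum(cnt_y * (cnt_y - 1)) / (2 * n * (n - 1))
      v2 <- sum(cnt_x * (cnt_x - 1) * (cnt_x - 2)) *
        sum(cnt_y * (cnt_y - 1) * (cnt_y - 2)) / (9 * n * (n - 1) * (n - 2))
      var_s <- (v0 - vt - vu) / 18 + v1 + v2
      z <- s / sqrt(var_s)
      p <- 2 * stats::pnorm(-abs(z))
    }
  } else {
    if (method == "spearman") { x <- rank(x); y <- rank(y) }
    r <- stats::cor(x, y)
    if (abs(r) >= 1 - 1e-15) {
      r <- sign(r)
      p <- 0
    } else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  if (abs(r) >= 1 - 1e-15) p <- 0
  list(r = unname(r), p = min(1, unname(p)), n = n)
}

#' Adjust a matrix of p-values for multiple testing
#'
#' One family per call: missing entries are excluded from the family size and
#' stay missing. `"fdr"` is Benjamini-Hochberg step-up, `"holm"` step-down,
#' `"bonferroni"` `min(1, m * p)`, `"none"` the identity.
#'
#' @param p Numeric matrix (or vector) of p-values in `[0, 1]`, NA allowed.
#' @param method `"fdr"`, `"bonferroni"`, `"holm"` or `"none"`.
#' @return Adjusted p-values, same shape as `p`.
#' @export
adjust_pvalues <- function(p, method = c("fdr", "bonferroni", "holm", "none")) {
  method <- match.arg(method)
  v <- as.vector(p)
  if (any(v < 0 | v > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  out <- p
  out[] <- stats::p.adjust(v, method = method)
  out
}

#' Render significance labels
#'
#' @param r Matrix of correlation coefficients.
#' @param p_adj Matrix of adjusted p-values.
#' @param options A [correlation_options()]; `annotation` and
#'   `star_thresholds` are used.
#' @return Character matrix of labels, same shape.
#' @export
annotate_significance <- function(r, p_adj, options = correlation_options()) {
  th <- options$star_thresholds
  lab <- switch(options$annotation,
    asterisks = {
      out <- matrix("", nrow(p_adj), ncol(p_adj))
      out[!is.na(p_adj) & p_adj < th[1L]] <- "*"
      out[!is.na(p_adj) & p_adj < th[2L]] <- "**"
      out[!is.na(p_adj) & p_adj < th[3L]] <- "***"
      out
    },
    pvalue = {
      out <- matrix("", nrow(p_adj), ncol(p_adj))
      out[!is.na(p_adj)] <- trimws(formatC(p_adj[!is.na(p_adj)],
                                           format = "g", digits = 3))
      out
    },
    correlation = {
      out <- matrix("", nrow(r), ncol(r))
      out[!is.na(r)] <- formatC(r[!is.na(r)], format = "f", digits = 2)
      out
    })
  dimnames(lab) <- dimnames(p_adj)
  lab
}

#' All-pairs correlation between two omics layers
#'
#' Correlates every feature of `X` with every feature of `Y` (typically hub
#' tables: modules represented by their hubs), applies the missing-data
#' policy, adjusts the full matrix of raw p-values as one family, and renders
#' significance labels.
#'
#' @param X,Y [omics_layer()] objects aligned on identical sample order
#'   (checked; a mismatch is an error, never silently reindexed).
#' @param options A [correlation_options()].
#' @return A `correlation_result`: list with `row_ids`, `col_ids`, matrices
#'   `r`, `p`, `p_adj`, `n_pairs`, `labels`, and `options`.
#' @export
calculate_correlations <- function(X, Y, options = correlation_options()) {
  stopifnot(inherits(X, "omics_layer"), inherits(Y, "omics_layer"))
  if (!identical(X$sample_ids, Y$sample_ids)) {
    stop("sample ids (or their order) differ between layers; run align_samples() first")
  }
  vx <- X$values; vy <- Y$values
  if (options$use == "all.obs" && (anyNA(vx) || anyNA(vy))) {
    src <- if (anyNA(vx)) list(X, vx) else list(Y, vy)
    idx <- which(is.na(src[[2L]]), arr.ind = TRUE)[1L, ]
    stop(sprintf("use = 'all.obs' but layer '%s' is missing sample '%s', feature '%s'",
                 src[[1L]]$layer_id, src[[1L]]$sample_ids[idx[1L]],
                 src[[1L]]$feature_ids[idx[2L]]))
  }
  if (options$use == "complete.obs") {
    keep <- stats::complete.cases(cbind(vx, vy))
    if (sum(keep) < options$min_pairs) {
      stop("fewer complete samples than min_pairs under use = 'complete.obs'")
    }
    vx <- vx[keep, , drop = FALSE]; vy <- vy[keep, , drop = FALSE]
  }
  nr <- ncol(vx); nc <- ncol(vy)
  r <- p <- matrix(NA_real_, nr, nc,
                   dimnames = list(X$feature_ids, Y$feature_ids))
  n_pairs <- matrix(0L, nr, nc, dimnames = dimnames(r))
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      res <- suppressMessages(
        correlation_test(vx[, i], vy[, j], options$method, options$min_pairs))
      r[i, j] <- res$r; p[i, j] <- res$p; n_pairs[i, j] <- res$n
    }
  }
  p_adj <- adjust_pvalues(p, options$adjust)
  labels <- annotate_significance(r, p_adj, options)
  structure(list(row_ids = X$feature_ids, col_ids = Y$feature_ids,
                 r = r, p = p, p_adj = p_adj, n_pairs = n_pairs,
                 labels = labels, options = options,
                 x_id = X$layer_id, y_id = Y$layer_id),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result %s x %s> %d x %d pairs (%s, %s-adjusted), %d significant at 0.05\n",
              x$x_id, x$y_id, length(x$row_ids), length(x$col_ids),
              x$options$method, x$options$adjust,
              sum(x$p_adj < 0.05, na.rm = TRUE)))
  invisible(x)
}

#' Encode sample metadata as a numeric layer
#'
#' Numeric variables pass through; binary variables become one 0/1 feature
#' (second sorted level coded 1, order logged); categorical variables with
#' k > 2 levels become k one-hot indicator features named `"var=level"`.
#' Variables with a single observed level are dropped with a warning. The
#' result feeds [calculate_correlations()] unchanged.
#'
#' @param metadata A [sample_metadata()].
#' @return An [omics_layer()] with layer id `"metadata"`.
#' @export
encode_metadata <- function(metadata) {
  stopifnot(inherits(metadata, "sample_metadata"))
  cols <- list()
  for (v in names(metadata$data)) {
    kind <- metadata$kinds[[v]]
    col <- metadata$data[[v]]
    if (kind == "numeric") {
      cols[[v]] <- as.numeric(col)
      next
    }
    lv <- metadata$levels[[v]]
    observed <- unique(stats::na.omit(col))
    if (length(observed) < 2L) {
      warning(sprintf("variable '%s' has a single observed level; dropped", v))
      next
    }
    if (kind == "binary") {
      message(sprintf("binary variable '%s': %s = 0, %s = 1", v, lv[1L], lv[2L]))
      cols[[v]] <- as.numeric(col == lv[2L])
    } else {
      for (l in lv) cols[[paste0(v, "=", l)]] <- as.numeric(col == l)
    }
  }
  if (!length(cols)) stop("no usable metadata variables after encoding")
  m <- do.call(cbind, cols)
  omics_layer(m, sample_ids = metadata$sample_ids,
              feature_ids = names(cols), layer_id = "metadata",
              provenance = "encoded-metadata")
}

#' Write a correlation result as four TSV matrices
#'
#' Files are named `<X>__<Y>.<kind>.tsv` for kind in r, p, p_adj, labels;
#' row ids are the X features, column ids the Y features.
#'
#' @param result A `correlation_result`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the four paths, invisibly.
#' @export
write_correlation_result <- function(result, dir) {
  stopifnot(inherits(result, "correlation_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, paste0(result$x_id, "__", result$y_id))
  kinds <- c("r", "p", "p_adj", "labels")
  paths <- character(0)
  for (k in kinds) {
    m <- result[[k]]
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    path <- paste0(stem, ".", k, ".tsv")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    paths <- c(paths, path)
  }
  invisible(paths)
}
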