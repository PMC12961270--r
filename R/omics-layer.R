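#' Construct an omics layer
#'
#' An `omics_layer` is the unit all tables move through: a numeric
#' samples x features matrix with unique sample and feature identifiers.
#' Missing measurements are `NA`; every non-missing entry must be finite.
#'
#' @param values Numeric matrix, samples in rows, features in columns.
#' @param sample_ids Character vector of unique sample identifiers
#'   (defaults to `rownames(values)`).
#' @param feature_ids Character vector of unique feature identifiers
#'   (defaults to `colnames(values)`).
#' @param layer_id Short name for the layer (e.g. "host", "microbiome").
#' @param provenance Free-text processing note, e.g. "raw", "clr", "hubs".
#' @return An object of class `omics_layer`.
#' @export
omics_layer <- function(values, sample_ids = rownames(values),
                        feature_ids = colnames(values),
                        layer_id = "layer", provenance = "raw") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids) || is.null(feature_ids)) {
    stop("sample_ids and feature_ids are required (or set dimnames on 'values')")
  }
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values)) {
    stop("length(sample_ids) must equal nrow(values)")
  }
  if (length(feature_ids) != ncol(values)) {
    stop("length(feature_ids) must equal ncol(values)")
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) {
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "))
  }
  dup_f <- unique(feature_ids[duplicated(feature_ids)])
  if (length(dup_f)) {
    stop("duplicate feature ids: ", paste(dup_f, collapse = ", "))
  }
  if (any(!is.na(values) & !is.finite(values))) {
    stop("non-finite values present (Inf/-Inf); only NA is allowed as missing")
  }
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(
    list(layer_id = layer_id, sample_ids = sample_ids,
         feature_ids = feature_ids, values = values,
         provenance = provenance),
    class = "omics_layer"
  )
}

#' @export
print.omics_layer <- function(x, ...) {
  cat(sprintf("<omics_layer '%s'> %d samples x %d features (%s), %d missing\n",
              x$layer_id, length(x$sample_ids), length(x$feature_ids),
              x$provenance, sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.omics_layer <- function(x) dim(x$values)

#' Sample metadata table
#'
#' Holds per-sample variables of declared kinds. Kinds are `"numeric"`,
#' `"categorical"` (explicit level set) or `"binary"` (exactly two levels).
#'
#' @param data A data.frame with one row per sample; non-numeric columns are
#'   treated as categorical (binary when exactly two observed levels) unless
#'   `kinds` overrides.
#' @param sample_ids Character vector of unique sample ids (defaults to
#'   `rownames(data)`).
#' @param kinds Optional named character vector mapping variable name to kind.
#' @return An object of class `sample_metadata` with elements `sample_ids`,
#'   `data`, `kinds`, and `levels` (a named list for non-numeric variables).
#' @export
sample_metadata <- function(data, sample_ids = rownames(data), kinds = NULL) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (is.null(sample_ids)) stop("sample_ids required")
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(data)) {
    stop("length(sample_ids) must equal nrow(data)")
  }
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup)) stop("duplicate sample ids: ", paste(dup, collapse = ", "))
  rownames(data) <- sample_ids

  inferred <- vapply(data, function(col) {
    if (is.numeric(col)) return("numeric")
    lv <- unique(stats::na.omit(as.character(col)))
    if (length(lv) == 2) "binary" else "categorical"
  }, character(1))
  if (!is.null(kinds)) {
    bad <- setdiff(names(kinds), names(data))
    if (length(bad)) stop("kinds name unknown variables: ", paste(bad, collapse = ", "))
    inferred[names(kinds)] <- unname(kinds)
  }
  ok <- inferred %in% c("numeric", "categorical", "binary")
  if (any(!ok)) stop("unknown variable kind: ", paste(unique(inferred[!ok]), collapse = ", "))

  lvls <- list()
  for (v in names(data)) {
    if (inferred[[v]] == "numeric") {
      data[[v]] <- as.numeric(data[[v]])
    } else {
      col <- as.character(data[[v]])
      lv <- sort(unique(stats::na.omit(col)))
      if (inferred[[v]] == "binary" && length(lv) != 2) {
        stop(sprintf("variable '%s' declared binary but has %d observed levels",
                     v, length(lv)))
      }
      lvls[[v]] <- lv
      data[[v]] <- col
    }
  }
  structure(list(sample_ids = sample_ids, data = data,
                 kinds = inferred, levels = lvls),
            class = "sample_metadata")
}

#' @export
print.sample_metadata <- function(x, ...) {
  cat(sprintf("<sample_metadata> %d samples, %d variables (%s)\n",
              length(x$sample_ids), ncol(x$data),
              paste(sprintf("%s:%s", names(x$kinds), x$kinds), collapse = ", ")))
  invisible(x)
}

# tokens accepted as missing on read; "NA" is emitted on write
.missing_tokens <- c("NA", "NaN", "")

#' Read a feature table into an omics layer
#'
#' Reads a delimited text table whose first field is `"id"`. The canonical
#' internal orientation is samples x features; tables stored features-in-rows
#' are transposed on read. Orientation is never guessed.
#'
#' @param path Path to a TSV/CSV file.
#' @param orientation `"samples-in-rows"` (default) or `"features-in-rows"`.
#' @param delimiter Field delimiter, default tab.
#' @param layer_id Layer name; defaults to the file name without extension.
#' @return An [omics_layer()].
#' @export
read_feature_table <- function(path, orientation = c("samples-in-rows", "features-in-rows"),
                               delimiter = "\t",
                               layer_id = tools::file_path_sans_ext(basename(path))) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "", na.strings = NULL)
  if (nrow(raw) == 0L || ncol(raw) < 2L) stop("empty table: ", path)
  row_ids <- raw[[1L]]
  mat_chr <- as.matrix(raw[, -1L, drop = FALSE])
  col_ids <- colnames(mat_chr)

  vals <- suppressWarnings(matrix(
    ifelse(trimws(mat_chr) %in% .missing_tokens, NA_real_,
           as.numeric(mat_chr)),
    nrow = nrow(mat_chr)))
  bad <- which(is.na(vals) & !(trimws(mat_chr) %in% .missing_tokens), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                 row_ids[bad[1, 1]], col_ids[bad[1, 2]],
                 mat_chr[bad[1, 1], bad[1, 2]]))
  }
  dimnames(vals) <- list(row_ids, col_ids)
  if (orientation == "features-in-rows") vals <- t(vals)
  omics_layer(vals, layer_id = layer_id, provenance = "raw")
}

#' Write an omics layer as a feature table
#'
#' Inverse of [read_feature_table()]: TSV/CSV with first column `id`
#' (sample ids), one column per feature, `NA` for missing.
#'
#' @param layer An [omics_layer()].
#' @param path Output file path.
#' @param delimiter Field delimiter, default tab.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(layer, path, delimiter = "\t") {
  stopifnot(inherits(layer, "omics_layer"))
  df <- data.frame(id = layer$sample_ids, layer$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a sample-metadata table
#'
#' First column holds sample ids; remaining columns are variables. A column
#' is numeric when every non-missing cell parses as a number, otherwise
#' categorical (binary when exactly two levels), unless `kinds` overrides.
#'
#' @inheritParams read_feature_table
#' @param kinds Optional named character vector of declared variable kinds.
#' @return A [sample_metadata()].
#' @export
read_metadata_table <- function(path, delimiter = "\t", kinds = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "", na.strings = NULL)
  if (nrow(raw) == 0L || ncol(raw) < 2L) stop("empty metadata table: ", path)
  ids <- raw[[1L]]
  df <- raw[, -1L, drop = FALSE]
  for (v in names(df)) {
    col <- trimws(df[[v]])
    col[col %in% .missing_tokens] <- NA_character_
    num <- suppressWarnings(as.numeric(col))
    if (all(is.na(num) == is.na(col))) df[[v]] <- num else df[[v]] <- col
  }
  sample_metadata(df, sample_ids = ids, kinds = kinds)
}

#' Write a sample-metadata table
#'
#' @param metadata A [sample_metadata()].
#' @param path Output file path.
#' @param delimiter Field delimiter, default tab.
#' @return `path`, invisibly.
#' @export
write_metadata_table <- function(metadata, path, delimiter = "\t") {
  stopifnot(inherits(metadata, "sample_metadata"))
  df <- data.frame(id = metadata$sample_ids, metadata$data,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Align layers and metadata on their common samples
#'
#' Restricts every layer (and the metadata, if given) to the intersection of
#' their sample sets, in lexicographic order, so all tables share one sample
#' axis. No layer is privileged: the order is the sorted intersection.
#'
#' @param layers A list of [omics_layer()] objects (names optional).
#' @param metadata Optional [sample_metadata()].
#' @return An `aligned_bundle`: list with `layers`, `metadata`,
#'   `common_samples`, and `dropped` (named list of dropped ids per table).
#' @export
align_samples <- function(layers, metadata = NULL) {
  if (inherits(layers, "omics_layer")) layers <- list(layers)
  stopifnot(length(layers) >= 1L)
  for (l in layers) stopifnot(inherits(l, "omics_layer"))
  sets <- lapply(layers, `[[`, "sample_ids")
  if (!is.null(metadata)) sets <- c(sets, list(metadata$sample_ids))
  common <- Reduce(intersect, sets)
  if (length(common) == 0L) {
    counts <- vapply(layers, function(l)
      sprintf("%s=%d", l$layer_id, length(l$sample_ids)), character(1))
    stop("no samples shared by all tables (per-layer counts: ",
         paste(counts, collapse = ", "), ")")
  }
  common <- sort(common)
  dropped <- list()
  out_layers <- lapply(layers, function(l) {
    drop <- setdiff(l$sample_ids, common)
    dropped[[l$layer_id]] <<- drop
    if (length(drop)) {
      message(sprintf("layer=%s dropped=%d ids=%s", l$layer_id,
                      length(drop), paste(drop, collapse = ",")))
    }
    omics_layer(l$values[common, , drop = FALSE], layer_id = l$layer_id,
                provenance = l$provenance)
  })
  names(out_layers) <- vapply(out_layers, `[[`, character(1), "layer_id")
  out_meta <- NULL
  if (!is.null(metadata)) {
    drop <- setdiff(metadata$sample_ids, common)
    dropped[["metadata"]] <- drop
    if (length(drop)) {
      message(sprintf("layer=metadata dropped=%d ids=%s",
                      length(drop), paste(drop, collapse = ",")))
    }
    out_meta <- sample_metadata(metadata$data[common, , drop = FALSE],
                                sample_ids = common, kinds = metadata$kinds)
  }
  structure(list(layers = out_layers, metadata = out_meta,
                 common_samples = common, dropped = dropped),
            class = "aligned_bundle")
}

#' @export
print.aligned_bundle <- function(x, ...) {
  cat(sprintf("<aligned_bundle> %d layers, %d common samples%s\n",
              length(x$layers), length(x$common_samples),
              if (is.null(x$metadata)) "" else ", with metadata"))
  invisible(x)
}

#' Remove low-prevalence features
#'
#' Keeps features observed in at least `min_prevalence` of samples.
#' "Observed" means non-missing and, when `zero_is_absent = TRUE` (the
#' default, matching amplicon/metaproteomic sparsity semantics), non-zero.
#'
#' @param layer An [omics_layer()].
#' @param min_prevalence Required fraction of samples in (0, 1].
#' @param zero_is_absent Treat exact zeros as absence (default `TRUE`).
#' @return The filtered [omics_layer()]; the number of removed features is in
#'   attribute `"n_removed"`. Feature order is preserved.
#' @export
filter_low_prevalence <- function(layer, min_prevalence, zero_is_absent = TRUE) {
  stopifnot(inherits(layer, "omics_layer"),
            min_prevalence > 0, min_prevalence <= 1)
  present <- !is.na(layer$values)
  if (zero_is_absent) present <- present & (layer$values != 0)
  prev <- colMeans(present)
  keep <- prev >= min_prevalence
  if (!any(keep)) {
    stop(sprintf("all %d features fall below prevalence %.3g; lower the threshold",
                 length(keep), min_prevalence))
  }
  out <- omics_layer(layer$values[, keep, drop = FALSE],
                     layer_id = layer$layer_id, provenance = layer$provenance)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Centered log-ratio transform
#'
#' Per sample (row): add `pseudocount`, divide by the row's geometric mean,
#' take the natural log. Each output row sums to zero. Intended for
#' compositional layers (relative abundances, closed counts).
#'
#' @param layer An [omics_layer()] with non-negative, complete values.
#' @param pseudocount Non-negative offset added before the log; default is
#'   half the smallest non-zero value in the table when zeros are present,
#'   else 0. Must be > 0 if any zeros are present.
#' @return The transformed [omics_layer()] with provenance `"clr"`.
#' @export
clr_transform <- function(layer, pseudocount = NULL) {
  stopifnot(inherits(layer, "omics_layer"))
  v <- layer$values
  if (anyNA(v)) {
    stop("missing entries present: the centered log-ratio is defined on complete compositions; impute or filter first")
  }
  if (any(v < 0)) {
    bad <- which(v < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative entry at sample '%s', feature '%s'",
                 layer$sample_ids[bad[1]], layer$feature_ids[bad[2]]))
  }
  if (is.null(pseudocount)) {
    pseudocount <- if (any(v == 0)) min(v[v > 0]) / 2 else 0
  }
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  if (any(v == 0) && pseudocount == 0) {
    stop("zeros present: a positive pseudocount is required")
  }
  lv <- log(v + pseudocount)
  out <- lv - rowMeans(lv)
  omics_layer(out, layer_id = layer$layer_id, provenance = "clr")
}
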