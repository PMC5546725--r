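#' Construct an expression dataset
#'
#' The atomic unit of a compendium: one genes x samples matrix of non-negative
#' expression values on linear scale, with unique gene identifiers as row names
#' and sample identifiers as column names.
#'
#' @param dataset_id Character scalar identifying the dataset.
#' @param values Numeric matrix, rows = genes (rownames required, unique),
#'   columns = samples (colnames required). All values must be finite.
#' @param log_rescaled Logical, whether the values were exponentiated from
#'   log2 scale by [rescale_if_log()].
#' @param n_dropped Number of gene rows dropped at load time because they
#'   contained missing or non-numeric cells.
#' @return An object of class `"clic_dataset"`.
#' @export
clic_dataset <- function(dataset_id, values, log_rescaled = FALSE, n_dropped = 0L) {
  if (!is.character(dataset_id) || length(dataset_id) != 1L || is.na(dataset_id))
    stop("'dataset_id' must be a single string")
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene row names and sample column names")
  if (nrow(values) == 0L) stop("dataset '", dataset_id, "' has zero genes")
  if (ncol(values) == 0L) stop("dataset '", dataset_id, "' has zero samples")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicated gene identifier(s) in dataset '", dataset_id, "': ",
         paste(unique(dup), collapse = ", "))
  if (!all(is.finite(values)))
    stop("dataset '", dataset_id, "' contains non-finite values")
  structure(
    list(dataset_id = dataset_id, values = values,
         log_rescaled = isTRUE(log_rescaled), n_dropped = as.integer(n_dropped)),
    class = "clic_dataset")
}

#' @export
print.clic_dataset <- function(x, ...) {
  cat("<clic_dataset> ", x$dataset_id, ": ", nrow(x$values), " genes x ",
      ncol(x$values), " samples", if (x$log_rescaled) " (rescaled from log2)",
      "\n", sep = "")
  invisible(x)
}

#' Read a tab-delimited expression matrix
#'
#' Reads a genes x samples matrix from tab-delimited text: first row sample
#' identifiers, first column gene identifiers, remaining cells numeric.
#' GCT files (first line `#1.2`) are accepted by skipping the two header
#' lines; a GCT `Description` column is dropped. Rows containing any missing
#' or non-numeric cell are dropped and counted in `$n_dropped`.
#'
#' @param path Path to the file.
#' @param dataset_id Identifier to assign; defaults to the file name without
#'   extension.
#' @return A [clic_dataset()].
#' @export
read_expression_matrix <- function(path, dataset_id = NULL) {
  if (!file.exists(path)) stop("cannot read expression matrix: '", path, "'")
  if (is.null(dataset_id))
    dataset_id <- sub("\\.[^.]*$", "", basename(path))
  first <- readLines(path, n = 1L)
  skip <- if (length(first) && startsWith(first, "#1.2")) 2L else 0L
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, skip = skip, check.names = FALSE,
                      stringsAsFactors = FALSE, na.strings = c("NA", "NaN", "")),
    error = function(e) stop("cannot read expression matrix '", path, "': ",
                             conditionMessage(e)))
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("expression matrix '", path, "' has zero genes or zero samples")
  gene_ids <- as.character(df[[1L]])
  df <- df[, -1L, drop = FALSE]
  if (skip == 2L && identical(tolower(names(df)[1L]), "description"))
    df <- df[, -1L, drop = FALSE]
  if (ncol(df) == 0L)
    stop("expression matrix '", path, "' has zero samples")
  vals <- suppressWarnings(
    vapply(df, function(col) as.numeric(as.character(col)), numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df), dimnames = list(gene_ids, names(df)))
  keep <- rowSums(!is.finite(vals)) == 0L
  n_dropped <- sum(!keep)
  dup <- gene_ids[keep][duplicated(gene_ids[keep])]
  if (length(dup))
    stop("duplicated gene identifier(s) in '", path, "': ",
         paste(unique(dup), collapse = ", "))
  if (!any(keep))
    stop("expression matrix '", path, "' has zero usable gene rows")
  clic_dataset(dataset_id, vals[keep, , drop = FALSE], n_dropped = n_dropped)
}

#' Write an expression dataset as tab-delimited text
#'
#' Inverse of [read_expression_matrix()]; round-trips identifiers and values.
#'
#' @param dataset A [clic_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(dataset, path) {
  df <- data.frame(gene_id = rownames(dataset$values), dataset$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Exponentiate log2-scale datasets
#'
#' Datasets with maximum expression below `threshold` are taken to be on log2
#' scale and every value v is replaced by 2^v; other datasets are returned
#' unchanged. The `$log_rescaled` flag records whether rescaling happened.
#'
#' @param dataset A [clic_dataset()].
#' @param threshold Maximum-expression cutoff below which a dataset is deemed
#'   log scale (default 30).
#' @return The dataset, on linear scale.
#' @export
rescale_if_log <- function(dataset, threshold = 30) {
  stopifnot(inherits(dataset, "clic_dataset"))
  if (max(dataset$values) < threshold) {
    dataset$values <- 2^dataset$values
    dataset$log_rescaled <- TRUE
  }
  dataset
}

#' Sample-count and expression-magnitude filters
#'
#' @param dataset A [clic_dataset()] on linear scale.
#' @param min_samples Minimum number of samples (default 6).
#' @param min_max_expression Minimum value of the dataset maximum (default
#'   1000); low maxima indicate truncated or mis-scaled uploads.
#' @return One of `"pass"`, `"too_few_samples"`, `"low_max_expression"`.
#'   `"pass"` is provisional: background QC (see [tv_distance_qc()]) can still
#'   reject the dataset.
#' @export
apply_sample_filters <- function(dataset, min_samples = 6, min_max_expression = 1000) {
  stopifnot(inherits(dataset, "clic_dataset"))
  if (ncol(dataset$values) < min_samples) return("too_few_samples")
  if (max(dataset$values) < min_max_expression) return("low_max_expression")
  "pass"
}

#' Equalize sample column means
#'
#' Scales each sample column so all column means equal the grand mean of the
#' original column means; relative values within a column are preserved and
#' total signal is conserved.
#'
#' @param dataset A [clic_dataset()].
#' @return The dataset with equalized column means.
#' @export
normalize_sample_means <- function(dataset) {
  stopifnot(inherits(dataset, "clic_dataset"))
  mu <- colMeans(dataset$values)
  if (any(mu == 0))
    stop("dataset '", dataset$dataset_id,
         "' has sample column(s) with mean zero; cannot scale")
  target <- mean(mu)
  dataset$values <- sweep(dataset$values, 2L, target / mu, `*`)
  dataset
}

#' Preprocess a compendium of expression datasets
#'
#' Runs the full preprocessing pipeline on each dataset: log-scale detection
#' and rescaling, sample filters, column-mean normalization, Fisher-z
#' background estimation and total-variation-distance QC. Datasets failing
#' any step are recorded in the manifest and excluded from analysis.
#'
#' @param datasets A list of [clic_dataset()] objects, or a directory path
#'   containing tab-delimited matrices (`.tsv`/`.txt`/`.gct`).
#' @param log_scale_threshold Passed to [rescale_if_log()].
#' @param min_samples,min_max_expression Passed to [apply_sample_filters()].
#' @param tv_threshold Maximum total-variation distance between the kernel
#'   and normal fits of the z background (default 0.1).
#' @param var_threshold Maximum background variance sigma0_sq (default 1).
#' @param max_tv_pairs Upper-triangle z values are subsampled to at most this
#'   many for the kernel-density QC (default 1e6); background moments are
#'   always exact.
#' @param seed Seed for the QC subsample (default 1).
#' @return An object of class `"clic_compendium"`: a list with `$datasets`
#'   (named list of entries for QC-passing datasets, each holding the
#'   normalized expression matrix and a [clic_background] summary) and
#'   `$manifest` (data frame with one row per input dataset and its
#'   `qc_status`).
#' @seealso [write_compendium()], [read_compendium()]
#' @export
build_compendium <- function(datasets,
                             log_scale_threshold = 30,
                             min_samples = 6,
                             min_max_expression = 1000,
                             tv_threshold = 0.1,
                             var_threshold = 1,
                             max_tv_pairs = 1e6,
                             seed = 1L) {
  if (is.character(datasets) && length(datasets) == 1L && dir.exists(datasets)) {
    paths <- list.files(datasets, pattern = "\\.(tsv|txt|gct)$", full.names = TRUE)
    if (!length(paths)) stop("no expression matrices found under '", datasets, "'")
    datasets <- lapply(paths, read_expression_matrix)
  }
  stopifnot(is.list(datasets), length(datasets) > 0L)
  entries <- list()
  man <- vector("list", length(datasets))
  for (ii in seq_along(datasets)) {
    ds <- datasets[[ii]]
    stopifnot(inherits(ds, "clic_dataset"))
    ds <- rescale_if_log(ds, threshold = log_scale_threshold)
    status <- apply_sample_filters(ds, min_samples = min_samples,
                                   min_max_expression = min_max_expression)
    tv <- NA_real_
    s0 <- NA_real_
    if (status == "pass") {
      ds <- normalize_sample_means(ds)
      bg <- dataset_background(ds, tv_threshold = tv_threshold,
                               var_threshold = var_threshold,
                               max_tv_pairs = max_tv_pairs, seed = seed)
      tv <- bg$tv_distance
      s0 <- bg$sigma0_sq
      status <- bg$status
      if (status == "pass")
        entries[[ds$dataset_id]] <- list(
          dataset_id = ds$dataset_id,
          expr = ds$values[bg$retained_genes, , drop = FALSE],
          background = bg)
    }
    man[[ii]] <- data.frame(
      dataset_id = ds$dataset_id,
      n_samples = ncol(ds$values),
      n_genes = nrow(ds$values),
      max_expression = max(ds$values),
      log_rescaled = ds$log_rescaled,
      n_dropped = ds$n_dropped,
      tv_distance = tv,
      sigma0_sq = s0,
      qc_status = status,
      stringsAsFactors = FALSE)
  }
  structure(list(datasets = entries, manifest = do.call(rbind, man)),
            class = "clic_compendium")
}

#' @export
print.clic_compendium <- function(x, ...) {
  cat("<clic_compendium> ", nrow(x$manifest), " dataset(s), ",
      length(x$datasets), " passing QC\n", sep = "")
  tab <- table(x$manifest$qc_status)
  for (s in names(tab)) cat("  ", s, ": ", tab[[s]], "\n", sep = "")
  invisible(x)
}

#' Persist and reload a preprocessed compendium
#'
#' Preprocessing (correlation backgrounds, QC) is done once per compendium;
#' the cache stores, per retained dataset, the normalized expression matrix,
#' the dataset and gene-specific backgrounds and the QC verdicts.
#'
#' @param compendium A `"clic_compendium"`.
#' @param path Cache file path.
#' @return `write_compendium()` returns `path` invisibly; `read_compendium()`
#'   returns the compendium.
#' @export
write_compendium <- function(compendium, path) {
  stopifnot(inherits(compendium, "clic_compendium"))
  saveRDS(compendium, path)
  invisible(path)
}

#' @rdname write_compendium
#' @export
read_compendium <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "clic_compendium")) stop("'", path, "' is not a compendium cache")
  x
}
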