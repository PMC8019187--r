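#' Binary sample-by-variable dataset
#'
#' The universal data container of the package: a samples x variables matrix
#' with entries in \{0, 1\}, plus unique sample identifiers and variable
#' names. Rows are samples (patients or haploid chromosomes), columns are
#' variables (typically minor-allele indicators of SNPs).
#'
#' @param values numeric matrix of 0/1 entries, samples in rows.
#' @param sample_ids character vector of unique row identifiers; defaults to
#'   existing rownames or `"s1"..."sn"`.
#' @param variable_names character vector of unique column names; defaults to
#'   existing colnames or `"v1"..."vk"`.
#' @return An object of class `binary_dataset` with fields `values`,
#'   `sample_ids` and `variable_names`.
#' @export
binary_dataset <- function(values, sample_ids = NULL, variable_names = NULL) {
  values <- as.matrix(values)
  if (length(values) > 0 && !all(values %in% c(0, 1))) {
    bad <- which(!(values %in% c(0, 1)))[1L]
    stopf("values must be 0 or 1; found %s at row %d, column %d",
          format(values[bad]),
          (bad - 1L) %% nrow(values) + 1L, (bad - 1L) %/% nrow(values) + 1L,
          class = "boltzgen_format_error")
  }
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  }
  if (is.null(variable_names)) {
    variable_names <- colnames(values)
    if (is.null(variable_names)) variable_names <- paste0("v", seq_len(ncol(values)))
  }
  sample_ids <- as.character(sample_ids)
  variable_names <- as.character(variable_names)
  if (length(sample_ids) != nrow(values)) {
    stopf("%d sample_ids for %d rows", length(sample_ids), nrow(values),
          class = "boltzgen_validation_error")
  }
  if (length(variable_names) != ncol(values)) {
    stopf("%d variable_names for %d columns", length(variable_names), ncol(values),
          class = "boltzgen_validation_error")
  }
  if (anyDuplicated(sample_ids)) {
    stopf("duplicate sample ids: %s",
          paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
          class = "boltzgen_validation_error")
  }
  if (anyDuplicated(variable_names)) {
    stopf("duplicate variable names: %s",
          paste(unique(variable_names[duplicated(variable_names)]), collapse = ", "),
          class = "boltzgen_validation_error")
  }
  dimnames(values) <- NULL
  structure(list(values = values, sample_ids = sample_ids,
                 variable_names = variable_names),
            class = "binary_dataset")
}

#' @export
print.binary_dataset <- function(x, ...) {
  cat(sprintf("<binary_dataset: %d samples x %d variables>\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.binary_dataset <- function(x) dim(x$values)

#' Number of samples / variables of a binary dataset
#' @param x a `binary_dataset`.
#' @return integer count.
#' @export
n_samples <- function(x) nrow(x$values)

#' @rdname n_samples
#' @export
n_variables <- function(x) ncol(x$values)

# Row subset preserving names; internal.
subset_samples <- function(x, idx) {
  binary_dataset(x$values[idx, , drop = FALSE], x$sample_ids[idx],
                 x$variable_names)
}

#' Read a binary matrix from disk
#'
#' Supports two plain-text layouts. `"delimited"` is a samples-in-rows table
#' with a header of variable names and an optional leading `sample_id`
#' column; the delimiter (comma or tab) is sniffed from the header unless
#' given. `"impute_hap"` is the IMPUTE haplotype convention: whitespace
#' separated 0/1, one SNP per row and one chromosome per column; it is
#' transposed on read so that downstream code always sees samples as rows.
#' An optional IMPUTE legend file (columns `id position a0 a1`) supplies
#' variable names.
#'
#' @param path file to read.
#' @param format `"delimited"` or `"impute_hap"`.
#' @param delimiter optional explicit delimiter for the delimited format.
#' @param legend optional path to an IMPUTE `.legend` file.
#' @return a [binary_dataset()].
#' @export
read_matrix <- function(path, format = c("delimited", "impute_hap"),
                        delimiter = NULL, legend = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stopf("file not found: %s", path, class = "boltzgen_io_error")
  }
  if (format == "delimited") {
    header <- readLines(path, n = 1L)
    if (is.null(delimiter)) {
      delimiter <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
    }
    df <- tryCatch(
      utils::read.table(path, header = TRUE, sep = delimiter,
                        colClasses = "character", check.names = FALSE),
      error = function(e) stopf("malformed delimited file %s: %s", path,
                                conditionMessage(e),
                                class = "boltzgen_format_error"))
    sample_ids <- NULL
    if (ncol(df) > 0 && names(df)[1L] == "sample_id") {
      sample_ids <- df[[1L]]
      df <- df[-1L]
    }
    vals <- as.matrix(df)
    check_binary_cells(vals, path)
    storage.mode(vals) <- "double"
    binary_dataset(vals, sample_ids = sample_ids, variable_names = names(df))
  } else {
    rows <- strsplit(trimws(readLines(path)), "[ \t]+")
    rows <- rows[lengths(rows) > 0L]
    if (length(rows) == 0L) {
      stopf("empty impute_hap file: %s", path, class = "boltzgen_format_error")
    }
    if (length(unique(lengths(rows))) != 1L) {
      stopf("ragged rows in %s: row lengths %s", path,
            paste(unique(lengths(rows)), collapse = ", "),
            class = "boltzgen_format_error")
    }
    vals <- do.call(rbind, lapply(rows, as.numeric))
    check_binary_cells(vals, path)
    variable_names <- NULL
    if (!is.null(legend)) {
      leg <- utils::read.table(legend, header = TRUE, colClasses = "character")
      if (nrow(leg) != nrow(vals)) {
        stopf("legend has %d rows for %d SNPs", nrow(leg), nrow(vals),
              class = "boltzgen_format_error")
      }
      variable_names <- leg$id
    }
    # transpose: SNPs were rows, chromosomes columns
    binary_dataset(t(vals), variable_names = variable_names)
  }
}

check_binary_cells <- function(vals, path) {
  suppressWarnings(num <- as.numeric(vals))
  bad <- which(is.na(num) | !(num %in% c(0, 1)))
  if (length(bad) > 0L) {
    b <- bad[1L]
    stopf("non-binary cell '%s' in %s at row %d, column %d",
          as.character(vals[b]), path,
          (b - 1L) %% nrow(vals) + 1L, (b - 1L) %/% nrow(vals) + 1L,
          class = "boltzgen_format_error")
  }
  invisible(TRUE)
}

#' Write a binary dataset as delimited text
#'
#' Writes the `"delimited"` layout accepted by [read_matrix()], including a
#' leading `sample_id` column, so that a read/write round trip reproduces
#' the dataset exactly (values, names, order).
#'
#' @param dataset a `binary_dataset`.
#' @param path destination file.
#' @param delimiter field separator, default comma.
#' @export
write_matrix <- function(dataset, path, delimiter = ",") {
  stopifnot(inherits(dataset, "binary_dataset"))
  df <- data.frame(sample_id = dataset$sample_ids, check.names = FALSE)
  vals <- dataset$values
  storage.mode(vals) <- "integer"
  df <- cbind(df, as.data.frame(vals))
  names(df) <- c("sample_id", dataset$variable_names)
  ok <- tryCatch({
    utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                       quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stopf("cannot write to %s", path, class = "boltzgen_io_error")
  invisible(path)
}

#' Filter variables by minor allele frequency
#'
#' Removes variables whose minor allele frequency, `min(f, 1 - f)` with `f`
#' the column mean, is strictly below `min_maf`. A frequency exactly equal
#' to the threshold is kept. Column order is preserved.
#'
#' @param dataset a `binary_dataset` with at least one sample.
#' @param min_maf threshold in `[0, 0.5]`.
#' @return the filtered `binary_dataset`.
#' @export
maf_filter <- function(dataset, min_maf) {
  stopifnot(inherits(dataset, "binary_dataset"))
  if (!is.numeric(min_maf) || length(min_maf) != 1L || min_maf < 0 || min_maf > 0.5) {
    stopf("min_maf must be in [0, 0.5], got %s", format(min_maf),
          class = "boltzgen_validation_error")
  }
  if (n_samples(dataset) == 0L) {
    stopf("cannot compute allele frequencies on an empty dataset",
          class = "boltzgen_validation_error")
  }
  f <- colMeans(dataset$values)
  keep <- pmin(f, 1 - f) >= min_maf
  binary_dataset(dataset$values[, keep, drop = FALSE], dataset$sample_ids,
                 dataset$variable_names[keep])
}

#' Extract a contiguous locus of variables
#'
#' @param dataset a `binary_dataset`.
#' @param start first column of the block (1-based, inclusive).
#' @param width number of consecutive columns.
#' @return the `binary_dataset` restricted to columns
#'   `start ... start + width - 1`.
#' @export
select_locus <- function(dataset, start, width) {
  stopifnot(inherits(dataset, "binary_dataset"))
  start <- check_count(start, "start")
  width <- check_count(width, "width")
  if (start + width - 1L > n_variables(dataset)) {
    stopf("locus [%d, %d] out of range for %d variables",
          start, start + width - 1L, n_variables(dataset),
          class = "boltzgen_index_error")
  }
  idx <- start:(start + width - 1L)
  binary_dataset(dataset$values[, idx, drop = FALSE], dataset$sample_ids,
                 dataset$variable_names[idx])
}

#' Disjoint random train/test/validation split
#'
#' Draws three non-overlapping uniform random subsamples of the stated
#' sizes, the protocol used ahead of every benchmarking experiment.
#' Deterministic given `seed`.
#'
#' @param dataset a `binary_dataset`.
#' @param n_train,n_test,n_val partition sizes; their sum may not exceed the
#'   number of samples.
#' @param seed integer RNG seed.
#' @return a list with class `split_result` and elements `train`, `test`,
#'   `validation`, each a `binary_dataset`.
#' @export
split_train_test_val <- function(dataset, n_train, n_test, n_val, seed) {
  stopifnot(inherits(dataset, "binary_dataset"))
  n_train <- check_count(n_train, "n_train", min = 0L)
  n_test <- check_count(n_test, "n_test", min = 0L)
  n_val <- check_count(n_val, "n_val", min = 0L)
  total <- n_train + n_test + n_val
  if (total > n_samples(dataset)) {
    stopf("split requires %d samples but only %d are available",
          total, n_samples(dataset), class = "boltzgen_validation_error")
  }
  idx <- withr::with_seed(seed, sample.int(n_samples(dataset), total))
  structure(list(
    train = subset_samples(dataset, idx[seq_len(n_train)]),
    test = subset_samples(dataset, idx[n_train + seq_len(n_test)]),
    validation = subset_samples(dataset, idx[n_train + n_test + seq_len(n_val)])
  ), class = "split_result")
}
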