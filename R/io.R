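#' Construct a dataset
#'
#' Bundles a numeric feature matrix with one or more continuous response
#' columns. This is the container every fitting and evaluation function in
#' the package takes.
#'
#' @param features numeric matrix or data frame, one row per sample.
#' @param responses numeric matrix, data frame or vector of response values;
#'   one column per target.
#' @param target_names optional column names for the responses (defaults to
#'   existing names, else `g1`, `g2`, ...).
#' @return an object of class `ensembin_dataset` with elements `x` (matrix)
#'   and `y` (matrix with named columns).
#' @export
as_dataset <- function(features, responses, target_names = NULL) {
  x <- as_feature_matrix(features)
  if (is.null(dim(responses))) responses <- matrix(responses, ncol = 1L)
  y <- as.matrix(responses)
  if (!is.numeric(y)) abort("responses must be numeric", "ensembin_input_error")
  if (nrow(y) != nrow(x)) {
    abort("features and responses must have the same number of rows",
          "ensembin_input_error")
  }
  if (is.null(target_names)) {
    target_names <- colnames(y) %||% paste0("g", seq_len(ncol(y)))
  }
  colnames(y) <- target_names
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  structure(list(x = x, y = y), class = "ensembin_dataset")
}

#' @export
print.ensembin_dataset <- function(x, ...) {
  cat(sprintf("<ensembin_dataset> %d samples, %d features, %d target(s): %s\n",
              nrow(x$x), ncol(x$x), ncol(x$y),
              paste(colnames(x$y), collapse = ", ")))
  invisible(x)
}

guess_delimiter <- function(path, delimiter = NULL) {
  if (!is.null(delimiter)) return(delimiter)
  if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a delimited table into a dataset
#'
#' Reads a CSV/TSV file with a header, pulls out the named target columns as
#' responses and treats every remaining column as a numeric feature. The
#' delimiter is inferred from the extension (`.tsv`/`.tab` means tab,
#' everything else comma) unless given explicitly.
#'
#' @param path file path.
#' @param targets character vector of response column names (must exist and
#'   be numeric).
#' @param delimiter optional explicit field delimiter.
#' @return an [as_dataset()] object.
#' @export
read_dataset <- function(path, targets, delimiter = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), "ensembin_io_error")
  }
  if (length(targets) < 1L) {
    abort("at least one target column name is required", "ensembin_input_error")
  }
  sep <- guess_delimiter(path, delimiter)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE, colClasses = NA),
    error = function(e) {
      abort(sprintf("cannot read %s: %s", path, conditionMessage(e)),
            "ensembin_io_error")
    })
  if (ncol(df) == 0L) {
    abort(sprintf("%s is empty", path), "ensembin_io_error")
  }
  missing_t <- setdiff(targets, colnames(df))
  if (length(missing_t) > 0L) {
    abort(sprintf("target column(s) not found in %s: %s", path,
                  paste(missing_t, collapse = ", ")), "ensembin_io_error")
  }
  feat_cols <- setdiff(colnames(df), targets)
  if (length(feat_cols) == 0L) {
    abort("no feature columns left after removing the targets",
          "ensembin_io_error")
  }
  coerce_numeric <- function(col, name) {
    if (is.numeric(col)) return(as.numeric(col))
    if (nrow(df) == 0L) return(numeric(0))
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & trimws(col) != "NA")
    if (length(bad) > 0L) {
      abort(sprintf("non-numeric value '%s' at row %d, column '%s' of %s",
                    col[bad[1L]], bad[1L], name, path), "ensembin_io_error")
    }
    num
  }
  pull <- function(cols) {
    m <- matrix(NA_real_, nrow(df), length(cols),
                dimnames = list(NULL, cols))
    for (j in cols) m[, j] <- coerce_numeric(df[[j]], j)
    m
  }
  x <- pull(feat_cols)
  y <- pull(targets)
  log_msg("info", "read %s: %d rows, %d features, %d target(s)",
          path, nrow(df), ncol(x), ncol(y))
  as_dataset(x, y)
}

#' Write a dataset to a delimited file
#'
#' Writes the feature columns followed by the target columns, with a header.
#' The output round-trips losslessly (to full double precision) through
#' [read_dataset()].
#'
#' @param dataset an [as_dataset()] object.
#' @param path output file path; extension selects the delimiter as in
#'   [read_dataset()].
#' @param delimiter optional explicit delimiter.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, delimiter = NULL) {
  stopifnot(inherits(dataset, "ensembin_dataset"))
  sep <- guess_delimiter(path, delimiter)
  df <- cbind(as.data.frame(dataset$x), as.data.frame(dataset$y))
  ok <- tryCatch({
    utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                       path, sep = sep, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort(sprintf("cannot write %s", path), "ensembin_io_error")
  invisible(path)
}
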