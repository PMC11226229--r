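#' Construct a response matrix
#'
#' A `response_matrix` holds population activity as a conditions x features
#' matrix: one row per stimulus condition (an image, a movie frame, ...), one
#' column per unit, voxel, or model feature.  All downstream geometry metrics
#' adopt this orientation, so that "variance summed across all dimensions of
#' neural activity space" is the trace of the feature-space covariance.
#'
#' @param values numeric matrix, conditions x features; all entries finite.
#' @param condition_ids character vector of unique condition identifiers,
#'   one per row.  Defaults to existing rownames.
#' @param feature_ids optional character vector of feature names, one per
#'   column.
#' @return An object of class `response_matrix`: the numeric matrix with
#'   condition ids as rownames and feature ids as colnames.
#' @examples
#' rm <- response_matrix(matrix(rnorm(12), 4, 3),
#'                       condition_ids = paste0("c", 1:4))
#' n_conditions(rm)
#' @export
response_matrix <- function(values, condition_ids = rownames(values),
                            feature_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  assert_that(all(is.finite(values)), "response values must all be finite",
              "format_error")
  assert_that(nrow(values) >= 2, "a response matrix needs at least 2 conditions",
              "format_error")
  assert_that(!is.null(condition_ids), "condition_ids are required",
              "format_error")
  condition_ids <- as.character(condition_ids)
  assert_that(length(condition_ids) == nrow(values),
              "condition_ids must have one entry per row", "format_error")
  assert_that(!anyDuplicated(condition_ids),
              "condition_ids must be unique", "format_error")
  rownames(values) <- condition_ids
  if (!is.null(feature_ids)) {
    assert_that(length(feature_ids) == ncol(values),
                "feature_ids must have one entry per column", "format_error")
    colnames(values) <- as.character(feature_ids)
  }
  class(values) <- c("response_matrix", class(values))
  values
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix: %d conditions x %d features>\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Coerce to a response matrix
#' @param x matrix or data.frame with rownames as condition ids.
#' @return a `response_matrix`.
#' @export
as_response_matrix <- function(x) {
  if (inherits(x, "response_matrix")) return(x)
  response_matrix(as.matrix(x))
}

#' Number of conditions / features
#' @param x a `response_matrix`.
#' @export
n_conditions <- function(x) nrow(x)

#' @rdname n_conditions
#' @export
n_features <- function(x) ncol(x)

#' Condition identifiers of a response matrix
#' @param x a `response_matrix`.
#' @export
condition_ids <- function(x) rownames(x)

# strip the class so matrix algebra sees a plain double matrix
rm_values <- function(x) {
  y <- unclass(x)
  attr(y, "class") <- NULL
  y
}

#' Read a response matrix from disk
#'
#' CSV/TSV layout: first column `condition_id`, remaining columns numeric
#' features.  Row order in the file is preserved.
#'
#' @param path file path.
#' @param format `"csv"` or `"tsv"` (inferred from the extension by default).
#' @return a validated [response_matrix()].
#' @export
read_response_matrix <- function(path, format = c("auto", "csv", "tsv")) {
  format <- match.arg(format)
  if (identical(format, "hdf5"))
    fg_stop("hdf5 response matrices are not supported by this build; use csv/tsv",
            "format_error")
  assert_that(file.exists(path), sprintf("file not found: %s", path), "io_error")
  sep <- resolve_sep(path, format)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  assert_that(ncol(df) >= 2, "expected condition_id plus at least one feature column",
              "format_error")
  assert_that(identical(names(df)[1], "condition_id"),
              "first column must be named condition_id", "format_error")
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) fg_stop("non-numeric feature cells in response matrix",
                                 "parse_error")
  response_matrix(vals, condition_ids = ids, feature_ids = names(df)[-1])
}

#' Write a response matrix to disk
#' @param x a `response_matrix`.
#' @param path destination path.
#' @param format `"csv"` or `"tsv"` (inferred from the extension by default).
#' @export
write_response_matrix <- function(x, path, format = c("auto", "csv", "tsv")) {
  format <- match.arg(format)
  x <- as_response_matrix(x)
  sep <- resolve_sep(path, format)
  fids <- colnames(x)
  if (is.null(fids)) fids <- paste0("f", seq_len(ncol(x)))
  df <- data.frame(condition_id = condition_ids(x), rm_values(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("condition_id", fids)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

resolve_sep <- function(path, format) {
  if (format == "auto") {
    format <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  if (format == "tsv") "\t" else ","
}
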