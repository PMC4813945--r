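#' Feature tables
#'
#' A feature table is a tibble with one row per sample: a `sample_id`
#' column, one numeric column per sensor feature, a `label` column
#' (character; `NA` marks an unlabeled sample) and an optional
#' `concentration` column (ppm). Rows with a label form the labeled pool
#' L; rows with `NA` labels form the unlabeled pool U.
#'
#' @name feature_table
NULL

RESERVED_COLS <- c("sample_id", "label", "concentration")

# Names of the feature columns of a feature table, in column order.
#' Feature column names of a feature table
#'
#' @param data a feature table tibble.
#' @return character vector of feature column names.
#' @export
feature_cols <- function(data) {
  cols <- setdiff(names(data), RESERVED_COLS)
  cols[!startsWith(cols, ".")]  # dot columns (e.g. .agreement) are metadata
}

# Feature matrix (numeric) of a feature table.
feature_matrix <- function(data) {
  cols <- feature_cols(data)
  m <- as.matrix(data[cols])
  storage.mode(m) <- "double"
  m
}

validate_feature_table <- function(data, call = rlang::caller_env()) {
  if (!"sample_id" %in% names(data)) {
    abort("feature table must have a `sample_id` column", call = call)
  }
  cols <- feature_cols(data)
  if (length(cols) == 0) {
    abort("feature table has no feature columns", call = call)
  }
  for (cl in cols) {
    v <- data[[cl]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
      abort(sprintf(
        "feature column `%s` is not numeric (first offending row: %s)",
        cl, if (is.na(bad)) "?" else bad
      ), call = call)
    }
    if (any(!is.finite(v))) {
      abort(sprintf(
        "feature column `%s` contains non-finite values (row %d)",
        cl, which(!is.finite(v))[1]
      ), call = call)
    }
  }
  if (anyDuplicated(data$sample_id)) {
    abort("duplicated sample_id values in feature table", call = call)
  }
  invisible(data)
}

#' Read a feature table from CSV
#'
#' Reads a delimited feature table with header
#' `sample_id,<feature columns...>,label,concentration`. An empty label
#' field marks the row as unlabeled (`NA` in the returned tibble). Feature
#' columns are every column other than `sample_id`, `label` and
#' `concentration`, and must be numeric.
#'
#' @param path path to a CSV file.
#' @return a feature table tibble (see [feature_table]).
#' @seealso [write_feature_table()]
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  if (file.size(path) == 0) abort(sprintf("empty feature table file: %s", path))
  data <- suppressWarnings(readr::read_csv(
    path, col_types = readr::cols(.default = readr::col_character()),
    na = c("", "NA"), progress = FALSE, show_col_types = FALSE
  ))
  probs <- readr::problems(data)
  if (nrow(probs) > 0) {
    p <- probs[1, ]
    abort(sprintf(
      "malformed feature table %s: row %d, column %d (expected %s, got %s)",
      path, p$row, p$col, p$expected, p$actual
    ))
  }
  if (nrow(data) == 0) abort(sprintf("feature table %s has no rows", path))
  if (!"label" %in% names(data)) data$label <- NA_character_
  # plain tibble (drop readr's spec/problems bookkeeping)
  data <- tibble::as_tibble(as.data.frame(data, check.names = FALSE))
  # numeric conversion via strtod: correctly rounded, so values written
  # at 17 significant digits come back bit-exactly
  for (cl in setdiff(names(data), c("sample_id", "label"))) {
    v <- data[[cl]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad) > 0) {
      abort(sprintf(
        "non-numeric value %s in column `%s`, row %d of %s",
        dQuote(v[bad[1]]), cl, bad[1], path
      ))
    }
    data[[cl]] <- num
  }
  validate_feature_table(data)
  data
}

#' Write a feature table to CSV
#'
#' Writes one header plus one row per sample; unlabeled rows get an empty
#' label field. Numeric values are written with enough digits that
#' `read_feature_table()` reproduces them bit-exactly; labels containing
#' the delimiter are quoted.
#'
#' @param data a feature table tibble.
#' @param path output path.
#' @return `data`, invisibly.
#' @export
write_feature_table <- function(data, path) {
  validate_feature_table(data)
  out <- data
  num <- vapply(out, is.double, logical(1))
  # 17 significant digits: doubles survive the text round trip bit-exactly
  out[num] <- lapply(out[num], function(v) {
    ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
  })
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(data)
}

#' Labeled and unlabeled parts of a feature table
#'
#' @param data a feature table tibble.
#' @return the rows with (respectively without) a label.
#' @export
labeled_part <- function(data) dplyr::filter(data, !is.na(.data$label))

#' @rdname labeled_part
#' @export
unlabeled_part <- function(data) dplyr::filter(data, is.na(.data$label))
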