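#' Construct an expression table
#'
#' The core container of the package: a tibble whose first column,
#' `feature_id`, holds probe or gene identifiers and whose remaining columns
#' are numeric log2-ratio values, one column per sample. Missing measurements
#' are `NA` (never 0). The measurement level — `"probe"` before collapsing,
#' `"gene"` after — travels with the object as an attribute.
#'
#' @param x A data frame with a `feature_id` column (or feature ids as row
#'   names of a numeric matrix) and one numeric column per sample.
#' @param level Measurement level, `"probe"` or `"gene"`.
#' @return A tibble of class `serial_expr` with attribute `level`.
#' @examples
#' expression_table(
#'   data.frame(feature_id = c("AURKA", "PLK1"), s1 = c(1.5, -0.5), s2 = c(NA, 0)),
#'   level = "gene"
#' )
#' @export
expression_table <- function(x, level = c("gene", "probe")) {
  level <- match.arg(level)
  if (is.matrix(x)) {
    if (is.null(rownames(x))) abort("Matrix input needs feature ids as row names.")
    x <- tibble::rownames_to_column(as.data.frame(x), "feature_id")
  }
  check_no_duplicates(names(x), "sample ids") # header columns are sample ids
  x <- as_tibble(x)
  if (!"feature_id" %in% names(x)) abort("Expression input must have a `feature_id` column.")
  x <- dplyr::relocate(x, "feature_id")
  x$feature_id <- as.character(x$feature_id)
  check_no_duplicates(x$feature_id, "feature ids")
  check_no_duplicates(names(x)[-1], "sample ids")
  bad <- names(x)[-1][!vapply(x[-1], is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(sprintf("Non-numeric sample column(s): %s", paste(bad, collapse = ", ")))
  }
  structure(x, level = level, class = c("serial_expr", class(tibble())))
}

#' @rdname expression_table
#' @export
expr_level <- function(x) attr(x, "level") %||% "gene"

#' Expression values as a features-by-samples matrix
#'
#' @param x An expression table from [expression_table()].
#' @return Numeric matrix with feature ids as row names, sample ids as columns.
#' @export
expr_values <- function(x) {
  m <- as.matrix(as.data.frame(x[-1]))
  rownames(m) <- x$feature_id
  m
}

#' Read / write an expression table as TSV
#'
#' Plain UTF-8 tab-separated text, no quoting: header row of sample ids, first
#' column of feature ids, cells numeric or the missing token (`NA` or an empty
#' field). Round-trips are lossless to the printed precision.
#'
#' @param path File path.
#' @param level Measurement level of the stored values.
#' @return `read_expression()` returns a `serial_expr` tibble preserving file
#'   order; `write_expression()` returns `x` invisibly.
#' @export
read_expression <- function(path, level = c("gene", "probe")) {
  level <- match.arg(level)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE, name_repair = "minimal")
  if (ncol(raw) < 2) abort("Expression file needs a feature column plus >= 1 sample column.")
  names(raw)[1] <- "feature_id"
  for (j in seq(2, ncol(raw))) {
    cell <- raw[[j]]
    num <- suppressWarnings(as.numeric(ifelse(cell %in% c("NA", ""), NA, cell)))
    bad <- which(!is.na(cell) & !(cell %in% c("NA", "")) & is.na(num))
    if (length(bad) > 0) {
      abort(sprintf("Non-numeric value '%s' at row %d, column '%s'.",
                    cell[bad[1]], bad[1], names(raw)[j]))
    }
    raw[[j]] <- num
  }
  expression_table(raw, level = level)
}

#' @rdname read_expression
#' @param x Expression table to write.
#' @export
write_expression <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, na = "NA", quote = "none", progress = FALSE)
  invisible(x)
}
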