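#' Construct a subtype centroid panel
#'
#' Genes-by-subtypes matrix of reference expression centroids for
#' nearest-centroid molecular subtyping (the PAM50-style classifier uses a
#' 50-gene panel over the five intrinsic breast cancer subtypes). Centroid
#' values are user-supplied; the package ships no calibrated panel.
#'
#' @param x Data frame with a `gene_id` column and one numeric column per
#'   subtype, or a numeric matrix with gene row names and subtype column
#'   names.
#' @return A tibble of class `centroid_panel` (first column `gene_id`,
#'   upper-cased; one numeric column per subtype).
#' @export
centroid_panel <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) abort("Matrix input needs gene ids as row names.")
    x <- tibble::rownames_to_column(as.data.frame(x), "gene_id")
  }
  x <- as_tibble(x)
  if (!"gene_id" %in% names(x)) names(x)[1] <- "gene_id"
  x <- dplyr::relocate(x, "gene_id")
  x$gene_id <- toupper(as.character(x$gene_id))
  check_no_duplicates(x$gene_id, "panel genes")
  check_no_duplicates(names(x)[-1], "subtype labels")
  if (ncol(x) - 1 < 2) abort("Centroid panel needs >= 2 subtypes.")
  if (nrow(x) < 2) abort("Centroid panel needs >= 2 genes.")
  if (!all(vapply(x[-1], is.numeric, logical(1)))) {
    abort("Centroid columns must be numeric.")
  }
  structure(x, class = c("centroid_panel", class(tibble())))
}

#' Read / write a centroid panel as TSV
#'
#' Gene rows by subtype columns; first column gene symbols.
#'
#' @param path File path.
#' @return `read_centroids()` returns a `centroid_panel` tibble.
#' @export
read_centroids <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(readr::col_character(),
                                                       .default = readr::col_double()),
                         na = c("NA", ""), progress = FALSE, name_repair = "minimal")
  centroid_panel(raw)
}

#' @rdname read_centroids
#' @param x Panel to write.
#' @export
write_centroids <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, na = "NA", quote = "none", progress = FALSE)
  invisible(x)
}

centroid_matrix <- function(panel) {
  m <- as.matrix(as.data.frame(panel[-1]))
  rownames(m) <- panel$gene_id
  m
}
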