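#' Construct a gene-set collection
#'
#' Named lists of gene symbols used for overrepresentation testing. Gene
#' symbols are upper-cased on construction so that matching against
#' expression tables and centroid panels is case-insensitive.
#'
#' @param sets Named list of character vectors of gene symbols.
#' @param description Optional character vector of per-set descriptions
#'   (recycled from `""`).
#' @return A tibble of class `gene_sets` with columns `set`, `description`,
#'   `genes` (list column), `n_genes`.
#' @export
gene_sets <- function(sets, description = NULL) {
  if (length(sets) == 0) abort("Gene-set collection is empty.")
  nm <- names(sets)
  if (is.null(nm) || any(nm == "")) abort("Every gene set needs a name.")
  check_no_duplicates(nm, "gene-set names")
  description <- description %||% rep("", length(sets))
  genes <- purrr::imap(sets, function(g, set_name) {
    g <- toupper(as.character(g))
    if (length(g) == 0) abort(sprintf("Gene set '%s' is empty.", set_name))
    if (anyDuplicated(g)) {
      warn(sprintf("Gene set '%s' contains duplicate symbols; deduplicated.", set_name))
      g <- unique(g)
    }
    g
  })
  structure(
    tibble(set = nm, description = as.character(description),
           genes = unname(genes), n_genes = lengths(genes)),
    class = c("gene_sets", class(tibble()))
  )
}

#' Read gene sets from a GMT file
#'
#' Broad-dialect GMT: one set per line — name, description, then
#' tab-separated gene symbols.
#'
#' @param path File path.
#' @return A `gene_sets` tibble, preserving file order.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("GMT file is empty.")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    abort(sprintf("GMT line %d has no genes (needs name, description, >=1 gene).", short[1]))
  }
  sets <- purrr::map(fields, ~ .x[-(1:2)])
  names(sets) <- purrr::map_chr(fields, 1)
  gene_sets(sets, description = purrr::map_chr(fields, 2))
}

#' @rdname read_gmt
#' @param x A `gene_sets` tibble to write.
#' @export
write_gmt <- function(x, path) {
  lines <- purrr::pmap_chr(list(x$set, x$description, x$genes), function(s, d, g) {
    paste(c(s, d, g), collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(x)
}
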