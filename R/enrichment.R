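#' Overrepresentation of one gene set among significant genes
#'
#' Classic one-sided Fisher exact enrichment test: given a universe of
#' tested genes, a significant subset, and a gene set (intersected with the
#' universe first), the p-value is the hypergeometric upper-tail probability
#' of drawing at least the observed overlap when `n_significant` genes are
#' drawn from the universe without replacement. A two-sided Fisher test is
#' selectable.
#'
#' @param significant Character vector of significant gene symbols (must be
#'   a subset of `universe`).
#' @param universe Character vector of all tested gene symbols.
#' @param set Character vector: the gene set.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @return A one-row tibble: `n_universe`, `n_significant`, `n_set` (after
#'   intersection with the universe), `n_overlap`, `odds_ratio` (sample
#'   odds ratio of the 2x2 table), `expected` overlap, `p`.
#' @examples
#' overrepresentation_test(paste0("g", 1:5), paste0("g", 1:20),
#'                         paste0("g", c(1:4, 6, 7)))
#' @export
overrepresentation_test <- function(significant, universe, set,
                                    alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  universe <- unique(toupper(universe))
  significant <- unique(toupper(significant))
  set <- unique(toupper(set))
  if (length(universe) == 0) abort("Empty universe.")
  if (length(significant) == 0) abort("Empty significant gene list.")
  if (!all(significant %in% universe)) {
    abort("Significant genes must be a subset of the universe.")
  }
  set_u <- intersect(set, universe)
  k <- length(intersect(set_u, significant))
  m <- length(set_u)
  n_sig <- length(significant)
  n_uni <- length(universe)
  a <- k                       # in set & significant
  b <- n_sig - k               # not in set & significant
  cc <- m - k                  # in set & not significant
  d <- n_uni - m - b           # neither
  or <- (a * d) / (b * cc)     # sample OR; Inf/NaN possible at empty margins
  p <- if (m == 0) {
    1
  } else if (alternative == "greater") {
    phyper(k - 1, m, n_uni - m, n_sig, lower.tail = FALSE)
  } else {
    stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value
  }
  tibble(n_universe = n_uni, n_significant = n_sig, n_set = m, n_overlap = k,
         odds_ratio = or, expected = m * n_sig / n_uni, p = min(1, p))
}

#' Test every gene set of a collection against a result's significant genes
#'
#' The universe is the set of all features tested in the upstream result
#' (standard microarray practice), not the genome. Raw per-set p-values are
#' reported and thresholded at `alpha` (default 0.05) without multiplicity
#' correction, matching common overrepresentation usage; an optional BH
#' column can be added by the caller from `p`.
#'
#' @param result A `serial_de` / `serial_surv` result (or a character vector
#'   of significant genes plus `universe`).
#' @param sets A [gene_sets()] collection.
#' @param universe Required when `result` is a plain vector.
#' @param alpha Per-set significance threshold on the raw p.
#' @inheritParams overrepresentation_test
#' @return An `enrich_result` tibble ranked by `p`: per set `n_set`,
#'   `n_overlap`, `expected`, `odds_ratio`, `p`, `significant`,
#'   `overlap_genes` (list column).
#' @export
enrich_all <- function(result, sets, universe = NULL, alpha = 0.05,
                       alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (is.data.frame(result) && "significant" %in% names(result)) {
    universe <- result$feature_id
    significant <- significant_features(result)
  } else {
    significant <- as.character(result)
    if (is.null(universe)) abort("Supply `universe` when `result` is a plain vector.")
  }
  significant <- unique(toupper(significant))
  universe <- unique(toupper(universe))
  if (length(significant) == 0) {
    abort("Result has no significant features; nothing to enrich.")
  }
  rows <- purrr::map2(sets$set, sets$genes, function(nm, g) {
    r <- overrepresentation_test(significant, universe, g, alternative = alternative)
    r$set <- nm
    r$overlap_genes <- list(intersect(intersect(g, universe), significant))
    r
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$p, dplyr::desc(.data$n_overlap))
  out$significant <- out$p < alpha
  out <- dplyr::relocate(out, "set", "n_set", "n_overlap", "expected",
                         "odds_ratio", "p", "significant")
  structure(out, alpha = alpha, alternative = alternative,
            n_significant = length(significant), n_universe = length(universe),
            class = c("enrich_result", class(tibble())))
}

#' @method tidy enrich_result
#' @export
tidy.enrich_result <- function(x, ...) as_tibble(x)

#' @method glance enrich_result
#' @export
glance.enrich_result <- function(x, ...) {
  tibble(n_sets = nrow(x), n_enriched = sum(x$significant),
         n_significant_genes = attr(x, "n_significant"),
         n_universe = attr(x, "n_universe"), alpha = attr(x, "alpha"))
}
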