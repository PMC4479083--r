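#' Assign a molecular subtype by nearest centroid
#'
#' Correlates one sample's gene-level profile with each subtype centroid over
#' the genes shared between profile and panel (missing values excluded) and
#' assigns the subtype with the highest correlation. Spearman correlation is
#' the default, making the call invariant to any strictly monotone transform
#' of the profile; Pearson is selectable. Exact ties are broken by panel
#' column order and flagged.
#'
#' @param profile Named numeric vector of gene-level values (names = gene
#'   symbols, case-insensitive), or a one-column data frame with gene ids.
#' @param panel A [centroid_panel()].
#' @param metric `"spearman"` (default) or `"pearson"`.
#' @param min_genes Minimum shared non-missing genes required (default 30).
#' @return A one-row tibble: `label`, `tie`, `n_genes_used`, and one
#'   `cor_<subtype>` column per centroid.
#' @export
assign_subtype <- function(profile, panel, metric = c("spearman", "pearson"),
                           min_genes = 30) {
  metric <- match.arg(metric)
  if (is.data.frame(profile)) {
    profile <- setNames(profile[[2]], profile[[1]])
  }
  names(profile) <- toupper(names(profile))
  cm <- centroid_matrix(panel)
  shared <- intersect(rownames(cm), names(profile)[!is.na(profile)])
  if (length(shared) < min_genes) {
    abort(sprintf("Only %d shared non-missing panel genes (need >= %d).",
                  length(shared), min_genes))
  }
  r <- cor(profile[shared], cm[shared, , drop = FALSE], method = metric)[1, ]
  best <- which(r == max(r))
  out <- tibble(label = colnames(cm)[best[1]], tie = length(best) > 1,
                n_genes_used = length(shared))
  out[paste0("cor_", colnames(cm))] <- as.list(unname(r))
  out
}

#' Subtype every sample of an expression table
#'
#' @param expr Gene-level expression table.
#' @param panel A [centroid_panel()].
#' @inheritParams assign_subtype
#' @return A tibble of class `subtype_calls`: one row per sample with
#'   `sample_id`, `label`, `tie`, `n_genes_used` and the per-centroid
#'   correlations.
#' @export
assign_subtypes <- function(expr, panel, metric = c("spearman", "pearson"),
                            min_genes = 30) {
  metric <- match.arg(metric)
  vals <- expr_values(expr)
  rownames(vals) <- toupper(rownames(vals))
  calls <- purrr::map(colnames(vals), function(s) {
    assign_subtype(vals[, s], panel, metric = metric, min_genes = min_genes)
  })
  out <- dplyr::bind_cols(tibble(sample_id = colnames(vals)),
                          dplyr::bind_rows(calls))
  structure(out, metric = metric,
            subtypes = names(panel)[-1],
            class = c("subtype_calls", class(tibble())))
}

#' Concordance of paired subtype assignments between two time points
#'
#' Matches samples from two call sets by patient, counts pairs with
#' identical assignment, and reports the concordance rate as a whole
#' percentage (`100 * identical / pairs`, rounded half away from zero — the
#' convention that turns 24/39 into 62). Also tabulates every
#' label-to-label transition.
#'
#' @param calls_a,calls_b `subtype_calls` (or any tibble with `sample_id`
#'   and `label`) for the two time points.
#' @param meta Sample sheet used to map samples to patients.
#' @return A list of class `subtype_concordance`: `n_pairs`, `n_identical`,
#'   `n_changed`, `rate_percent`, `transitions` (tibble `from`, `to`, `n`),
#'   and the per-patient pair table.
#' @examples
#' # 36 pairs with 9 changed assignments -> concordance 75%
#' @export
concordance <- function(calls_a, calls_b, meta) {
  pa <- meta$patient_id[match(calls_a$sample_id, meta$sample_id)]
  pb <- meta$patient_id[match(calls_b$sample_id, meta$sample_id)]
  if (any(is.na(pa)) || any(is.na(pb))) {
    abort("Every call's sample must appear in the sample sheet.")
  }
  shared <- intersect(pa, pb)
  if (length(shared) == 0) abort("No matched pairs between the two call sets.")
  pairs <- tibble(
    patient_id = shared,
    from = calls_a$label[match(shared, pa)],
    to = calls_b$label[match(shared, pb)]
  )
  n_pairs <- nrow(pairs)
  n_identical <- sum(pairs$from == pairs$to)
  transitions <- dplyr::count(pairs, .data$from, .data$to, name = "n")
  structure(
    list(n_pairs = n_pairs, n_identical = n_identical,
         n_changed = n_pairs - n_identical,
         rate_percent = rate_percent(n_identical, n_pairs),
         transitions = transitions, pairs = pairs),
    class = "subtype_concordance"
  )
}

#' @method print subtype_concordance
#' @export
print.subtype_concordance <- function(x, ...) {
  cat(sprintf("Subtype concordance: %d of %d pairs identical (%d%%), %d changed\n",
              x$n_identical, x$n_pairs, x$rate_percent, x$n_changed))
  changed <- dplyr::filter(x$transitions, .data$from != .data$to)
  if (nrow(changed) > 0) {
    cat("Transitions:\n")
    print(as.data.frame(changed), row.names = FALSE)
  }
  invisible(x)
}

#' @method glance subtype_concordance
#' @export
glance.subtype_concordance <- function(x, ...) {
  tibble(n_pairs = x$n_pairs, n_identical = x$n_identical,
         n_changed = x$n_changed, rate_percent = x$rate_percent)
}

#' @method tidy subtype_concordance
#' @export
tidy.subtype_concordance <- function(x, ...) x$transitions
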