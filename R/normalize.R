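#' Collapse probe-level values to gene level
#'
#' Replicate probes mapping to the same gene symbol are combined by the
#' arithmetic mean of their non-missing values, per sample. Probes without a
#' gene annotation are dropped (a message reports how many). A gene whose
#' probes are all missing in a sample stays missing there.
#'
#' @param expr Probe-level expression table ([expression_table()]).
#' @param probe_to_gene Mapping from probe to gene symbol: a data frame with
#'   columns `probe_id` and `gene_id`, or a named character vector
#'   (`names` = probe ids, values = gene symbols). Each probe maps to at most
#'   one gene; `NA` marks an unannotated probe.
#' @return Gene-level expression table; gene symbols upper-cased, ordered by
#'   first appearance among the mapped probes.
#' @export
collapse_probes <- function(expr, probe_to_gene) {
  if (is.data.frame(probe_to_gene)) {
    if (!all(c("probe_id", "gene_id") %in% names(probe_to_gene))) {
      abort("probe_to_gene data frame needs columns `probe_id` and `gene_id`.")
    }
    map <- setNames(as.character(probe_to_gene$gene_id),
                    as.character(probe_to_gene$probe_id))
  } else {
    map <- probe_to_gene
  }
  if (length(map) == 0) abort("Empty probe-to-gene mapping.")
  check_no_duplicates(names(map), "probes in mapping")

  vals <- expr_values(expr)
  gene <- toupper(unname(map[rownames(vals)]))
  gene[gene %in% c("", "NA")] <- NA
  n_drop <- sum(is.na(gene))
  if (n_drop > 0) {
    inform(sprintf("Dropping %d unmapped probe(s) of %d.", n_drop, nrow(vals)))
  }
  keep <- !is.na(gene)
  if (!any(keep)) abort("No probe maps to a gene symbol.")
  vals <- vals[keep, , drop = FALSE]
  gene <- gene[keep]

  f <- factor(gene, levels = unique(gene))
  obs <- !is.na(vals)
  sums <- rowsum(ifelse(obs, vals, 0), f)
  ns <- rowsum(obs + 0, f)
  out <- sums / ns
  out[ns == 0] <- NA
  expression_table(out, level = "gene")
}

#' Remove print-batch effects by linear-model residualization
#'
#' Per feature, fits the one-way linear model `value ~ batch` (batch as a
#' categorical explanatory variable) on the non-missing entries and keeps the
#' residuals — equivalently, subtracts each batch's own mean. A feature seen
#' in a single batch is simply mean-centered; a batch with no observed value
#' for a feature leaves those entries missing. The operation is idempotent.
#'
#' @param expr Expression table.
#' @param meta Sample sheet ([sample_meta()]) covering every sample column of
#'   `expr`; supplies the `batch` label per sample.
#' @return Expression table of residuals, same dimensions and level.
#' @export
residualize_batch <- function(expr, meta) {
  m <- meta_for_expr(expr, meta)
  if (any(is.na(m$batch))) {
    abort(sprintf("Sample(s) missing a batch label: %s",
                  paste(head(m$sample_id[is.na(m$batch)], 5), collapse = ", ")))
  }
  vals <- expr_values(expr)
  batch <- droplevels(m$batch)
  out <- vals
  for (b in levels(batch)) {
    idx <- which(batch == b)
    sub <- vals[, idx, drop = FALSE]
    mu <- rowMeans(sub, na.rm = TRUE) # NaN where all-missing; NA cells stay NA
    out[, idx] <- sub - mu
  }
  res <- expression_table(out, level = expr_level(expr))
  names(res)[-1] <- names(expr)[-1]
  res
}
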