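CONTRASTS <- c("t1_vs_t2", "t1_vs_ts",
               "rcb_t1", "rcb_t2", "rcb_ts", "rcb_delta_t2", "rcb_delta_ts")

# features x patients matrix of one timepoint's values, restricted to
# patients present at every timepoint in `tps`; columns named by patient
timepoint_matrix <- function(expr, meta, tp, patients) {
  m <- meta_for_expr(expr, meta)
  sel <- m$timepoint == tp & m$patient_id %in% patients
  vals <- expr_values(expr)[, which(sel), drop = FALSE]
  colnames(vals) <- m$patient_id[sel]
  vals[, match(patients, colnames(vals)), drop = FALSE]
}

patients_with <- function(meta, tps) {
  tab <- table(meta$patient_id, factor(meta$timepoint, levels = TIMEPOINTS))
  rownames(tab)[rowSums(tab[, tps, drop = FALSE] > 0) == length(tps)]
}

#' Run one differential-expression contrast
#'
#' Applies the study's per-gene tests across a whole expression table:
#'
#' * `"t1_vs_t2"`, `"t1_vs_ts"` — paired permutation t-test of the later
#'   time point against pretreatment, per gene, over patients with both
#'   samples. P-values are Benjamini-Hochberg adjusted and called
#'   significant at adjusted p < `alpha` (default 0.05).
#' * `"rcb_t1"`, `"rcb_t2"`, `"rcb_ts"` — two-group (responder RCB 0/I vs
#'   nonresponder RCB II/III) Welch permutation t-test on the static values
#'   at one time point.
#' * `"rcb_delta_t2"`, `"rcb_delta_ts"` — the same two-group test on the
#'   within-patient change (T2 - T1 or TS - T1).
#'
#' Outcome (RCB) contrasts use the relaxed threshold raw p <
#' `outcome_alpha` (default 0.005) with *no* multiple-testing correction,
#' reflecting their small group sizes; no adjusted p is reported for them.
#' Patients with undetermined RCB are excluded from outcome contrasts.
#' Pairs with a missing value are dropped per gene, and the per-gene sample
#' sizes are recorded.
#'
#' @param expr Expression table (typically batch-residualized).
#' @param meta Sample sheet covering the expression columns.
#' @param contrast One of the contrast names above.
#' @param n_perm Permutation budget per gene (default 10000; exhaustive
#'   enumeration is used automatically when cheaper).
#' @param seed Integer seed; all permutation draws derive from it.
#' @param alpha Adjusted-p threshold for time-point contrasts.
#' @param outcome_alpha Raw-p threshold for outcome contrasts.
#' @return A `serial_de` tibble: per feature `t`, `p`, `p_adj` (time-point
#'   contrasts only), `mean_diff`, `direction` (`"up"`/`"down"` for the
#'   later time point or the second group), `significant`, sample sizes,
#'   `exhaustive`. Metadata (contrast, thresholds, n_perm, seed, group
#'   definition) is attached as attributes and shown by [glance()].
#' @export
run_contrast <- function(expr, meta, contrast, n_perm = 10000, seed,
                         alpha = 0.05, outcome_alpha = 0.005) {
  contrast <- match.arg(contrast, CONTRASTS)
  meta <- meta_for_expr(expr, meta)

  paired <- contrast %in% c("t1_vs_t2", "t1_vs_ts")
  if (paired) {
    tp_b <- if (contrast == "t1_vs_t2") "T2" else "TS"
    pts <- patients_with(meta, c("T1", tp_b))
    if (length(pts) < 3) {
      abort(sprintf("Contrast %s needs >= 3 complete pairs; %d patient(s) have both samples.",
                    contrast, length(pts)))
    }
    D <- timepoint_matrix(expr, meta, tp_b, pts) -
      timepoint_matrix(expr, meta, "T1", pts)
    res <- perm_paired_matrix(D, n_perm, derive_seed(seed, contrast))
    res$p_adj <- bh_adjust(res$p)
    res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
    rule <- sprintf("BH-adjusted p < %g", alpha)
    n_pairs <- length(pts)
    groups <- NULL
  } else {
    tp <- switch(contrast, rcb_t1 = "T1", rcb_t2 = "T2", rcb_ts = "TS",
                 rcb_delta_t2 = "T2", rcb_delta_ts = "TS")
    delta <- contrast %in% c("rcb_delta_t2", "rcb_delta_ts")
    need <- if (delta) c("T1", tp) else tp
    pts <- patients_with(meta, need)
    grp <- meta$rcb_group[match(pts, meta$patient_id)]
    keep <- !is.na(grp)
    pts <- pts[keep]; grp <- droplevels_keep2(grp[keep])
    if (sum(grp == "responder") < 2 || sum(grp == "nonresponder") < 2) {
      abort(sprintf(
        "Contrast %s needs >= 2 patients per RCB group; have %d responder(s), %d nonresponder(s).",
        contrast, sum(grp == "responder"), sum(grp == "nonresponder")))
    }
    X <- timepoint_matrix(expr, meta, tp, pts)
    if (delta) X <- X - timepoint_matrix(expr, meta, "T1", pts)
    res <- perm_group_matrix(X, grp == "responder", n_perm,
                             derive_seed(seed, contrast))
    res$p_adj <- NA_real_
    res$significant <- !is.na(res$p) & res$p < outcome_alpha
    rule <- sprintf("raw p < %g, no multiple-testing correction", outcome_alpha)
    n_pairs <- length(pts)
    groups <- table(grp)
  }
  res$direction <- dplyr::if_else(res$mean_diff >= 0, "up", "down", missing = NA_character_)
  res <- dplyr::relocate(res, "feature_id", "t", "p", "p_adj", "mean_diff",
                         "direction", "significant")
  structure(res,
            contrast = contrast, threshold_rule = rule, n_perm = n_perm,
            seed = seed,
            reference = if (paired) "T1" else "responder (RCB 0/I)",
            n_units = n_pairs, group_sizes = groups,
            class = c("serial_de", class(tibble())))
}

# two-group factor keeping both levels even if one empties after filtering
droplevels_keep2 <- function(f) factor(as.character(f), levels = c("responder", "nonresponder"))

#' @method tidy serial_de
#' @export
tidy.serial_de <- function(x, ...) {
  as_tibble(x)
}

#' @method glance serial_de
#' @export
glance.serial_de <- function(x, ...) {
  tibble(
    contrast = attr(x, "contrast"),
    n_features = nrow(x),
    n_tested = sum(!is.na(x$p)),
    n_significant = sum(x$significant, na.rm = TRUE),
    n_up = sum(x$significant & x$direction == "up", na.rm = TRUE),
    n_down = sum(x$significant & x$direction == "down", na.rm = TRUE),
    threshold_rule = attr(x, "threshold_rule"),
    n_perm = attr(x, "n_perm"),
    n_units = attr(x, "n_units"),
    reference = attr(x, "reference")
  )
}

#' Significant feature ids of a result
#'
#' @param x A `serial_de`, `serial_surv` or similar result with
#'   `feature_id` and `significant` columns.
#' @return Character vector of significant feature ids.
#' @export
significant_features <- function(x) {
  x$feature_id[!is.na(x$significant) & x$significant]
}
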