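#' Run the full serial-expression analysis workflow
#'
#' Orchestrates every stage of the study design on one cohort: optional
#' probe collapsing, print-batch residualization, paired time-point
#' differential expression (T1 vs T2; T1 vs TS), response-group contrasts
#' (RCB 0/I vs II/III at T1, T2 and on the early change T2 - T1), molecular
#' subtype calls with paired concordance for both pairings, per-gene Cox
#' screens of recurrence-free survival (T1, TS, TS - T1; surgical-sample
#' screens restricted to residual-disease patients), overlap reports between
#' significant sets, and gene-set overrepresentation for every contrast with
#' significant genes. Every number in the summary is recomputable by calling
#' the stage functions directly; the pipeline adds no computation of its own.
#'
#' If `out_dir` is given, per-stage TSVs and a JSON `summary.json` are
#' written as stages complete, plus a `manifest.json` marking which stages
#' finished — so a failed stage leaves the completed outputs behind. A stage
#' failure aborts with the stage name.
#'
#' @param expr Expression table (probe level if `probe_map` is supplied).
#' @param meta Sample sheet.
#' @param centroids Optional [centroid_panel()] for subtype calls.
#' @param sets Optional [gene_sets()] for enrichment.
#' @param probe_map Optional probe-to-gene mapping (see [collapse_probes()]).
#' @param n_perm Permutation budget per gene.
#' @param seed Integer seed; every stage derives its stream from it.
#' @param alpha Adjusted-p threshold for time-point contrasts (default 0.05).
#' @param outcome_alpha Raw-p threshold for outcome contrasts and survival
#'   screens (default 0.005).
#' @param enrich_alpha Per-set enrichment threshold (default 0.05).
#' @param metric Correlation metric for subtype calls.
#' @param adjust_hr Adjust survival screens for hormone-receptor status.
#' @param min_genes Minimum shared panel genes for a subtype call.
#' @param out_dir Optional output directory.
#' @return A list of class `serial_report`: `expr` (normalized), `de`
#'   (named list of `serial_de`), `subtypes`, `concordance` (named list),
#'   `rfs` (named list of `serial_surv`), `enrichment` (named list),
#'   `overlaps`, `summary` (the JSON-ready summary), `manifest`.
#' @export
run_all <- function(expr, meta, centroids = NULL, sets = NULL,
                    probe_map = NULL, n_perm = 10000, seed,
                    alpha = 0.05, outcome_alpha = 0.005, enrich_alpha = 0.05,
                    metric = c("spearman", "pearson"), adjust_hr = FALSE,
                    min_genes = 30, out_dir = NULL) {
  metric <- match.arg(metric)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  manifest <- list()
  note_stage <- function(name) {
    manifest[[name]] <<- TRUE
    if (!is.null(out_dir)) {
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE)
    }
  }
  run_stage <- function(name, code) {
    res <- tryCatch(force(code), error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
    })
    note_stage(name)
    res
  }
  save_tsv <- function(x, file) {
    if (!is.null(out_dir)) {
      flat <- as_tibble(x)
      for (j in names(flat)) {
        if (is.list(flat[[j]])) {
          flat[[j]] <- purrr::map_chr(flat[[j]], paste, collapse = ",")
        }
      }
      readr::write_tsv(flat, file.path(out_dir, file), na = "NA", progress = FALSE)
    }
    invisible(x)
  }

  expr <- run_stage("normalize", {
    if (!is.null(probe_map)) expr <- collapse_probes(expr, probe_map)
    residualize_batch(expr, meta)
  })
  save_tsv(as_tibble(expr), "expression_normalized.tsv")

  de_names <- c("t1_vs_t2", "t1_vs_ts", "rcb_t1", "rcb_t2", "rcb_delta_t2")
  de <- purrr::map(setNames(de_names, de_names), function(ct) {
    r <- run_stage(paste0("de_", ct), {
      run_contrast(expr, meta, ct, n_perm = n_perm, seed = seed,
                   alpha = alpha, outcome_alpha = outcome_alpha)
    })
    save_tsv(r, paste0("de_", ct, ".tsv"))
    r
  })

  subtypes <- NULL
  conc <- list()
  if (!is.null(centroids)) {
    subtypes <- run_stage("subtype_calls", {
      assign_subtypes(expr, centroids, metric = metric, min_genes = min_genes)
    })
    save_tsv(subtypes, "subtype_calls.tsv")
    m <- meta_for_expr(expr, meta)
    calls_at <- function(tp) {
      subtypes[subtypes$sample_id %in% m$sample_id[m$timepoint == tp], , drop = FALSE]
    }
    conc <- purrr::map(
      setNames(c("T2", "TS"), c("t1_t2", "t1_ts")),
      function(tp) {
        cc <- run_stage(paste0("concordance_t1_", tolower(tp)), {
          concordance(calls_at("T1"), calls_at(tp), meta)
        })
        save_tsv(cc$transitions, paste0("transitions_t1_", tolower(tp), ".tsv"))
        cc
      })
  }

  rfs_names <- c("t1", "ts", "delta_ts")
  rfs <- purrr::map(setNames(rfs_names, rfs_names), function(md) {
    r <- run_stage(paste0("rfs_", md), {
      screen_rfs(expr, meta, mode = md, adjust_hr = adjust_hr,
                 p_threshold = outcome_alpha)
    })
    save_tsv(r, paste0("rfs_", md, ".tsv"))
    r
  })

  sig_sets <- c(purrr::map(de, significant_features),
                purrr::map(setNames(rfs, paste0("rfs_", rfs_names)),
                           significant_features))
  overlap_family <- function(nms) {
    prs <- utils::combn(nms, 2, simplify = FALSE)
    purrr::map_dfr(prs, function(pr) {
      tibble(contrast_a = pr[1], contrast_b = pr[2],
             n_a = length(sig_sets[[pr[1]]]), n_b = length(sig_sets[[pr[2]]]),
             n_overlap = length(intersect(sig_sets[[pr[1]]], sig_sets[[pr[2]]])),
             overlap_genes = paste(intersect(sig_sets[[pr[1]]], sig_sets[[pr[2]]]),
                                   collapse = ","))
    })
  }
  overlaps <- run_stage("overlaps", {
    dplyr::bind_rows(
      overlap_family(c("rcb_t1", "rcb_t2", "rcb_delta_t2")),
      overlap_family(paste0("rfs_", rfs_names))
    )
  })
  save_tsv(overlaps, "overlaps.tsv")

  enrichment <- list()
  if (!is.null(sets)) {
    enrich_targets <- names(sig_sets)[lengths(sig_sets) > 0]
    enrichment <- purrr::map(setNames(enrich_targets, enrich_targets), function(nm) {
      r <- run_stage(paste0("enrich_", nm), {
        src <- if (startsWith(nm, "rfs_")) rfs[[sub("^rfs_", "", nm)]] else de[[nm]]
        enrich_all(src, sets, alpha = enrich_alpha)
      })
      save_tsv(r, paste0("enrich_", nm, ".tsv"))
      r
    })
  }

  summary <- list(
    thresholds = list(timepoint_adjusted_alpha = alpha,
                      outcome_raw_alpha = outcome_alpha,
                      enrichment_alpha = enrich_alpha),
    n_perm = n_perm, seed = seed,
    contrasts = c(
      purrr::map(de, ~ as.list(glance(.x))),
      purrr::map(setNames(rfs, paste0("rfs_", rfs_names)), ~ as.list(glance(.x)))
    ),
    concordance = purrr::map(conc, ~ as.list(glance(.x))),
    overlaps = purrr::map(seq_len(nrow(overlaps)),
                          ~ as.list(overlaps[.x, , drop = FALSE])),
    enrichment = purrr::map(enrichment, function(e) {
      list(n_enriched = sum(e$significant),
           top_set = e$set[1], top_p = e$p[1])
    })
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  note_stage("summary")

  structure(list(expr = expr, de = de, subtypes = subtypes, concordance = conc,
                 rfs = rfs, enrichment = enrichment, overlaps = overlaps,
                 summary = summary, manifest = manifest),
            class = "serial_report")
}

#' @export
print.serial_report <- function(x, ...) {
  cat("Serial expression analysis report\n")
  cat(sprintf("  features: %d, samples: %d\n", nrow(x$expr), ncol(x$expr) - 1))
  for (nm in names(x$de)) {
    g <- glance(x$de[[nm]])
    cat(sprintf("  %-14s %4d significant (%d up / %d down) [%s]\n",
                nm, g$n_significant, g$n_up, g$n_down, g$threshold_rule))
  }
  for (nm in names(x$rfs)) {
    g <- glance(x$rfs[[nm]])
    cat(sprintf("  rfs_%-10s %4d significant (%d reduced RFS)\n",
                nm, g$n_significant, g$n_reduced_rfs))
  }
  for (nm in names(x$concordance)) {
    cc <- x$concordance[[nm]]
    cat(sprintf("  concordance %-6s %d%% (%d of %d pairs identical)\n",
                nm, cc$rate_percent, cc$n_identical, cc$n_pairs))
  }
  invisible(x)
}
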