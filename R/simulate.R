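#' Configuration of the synthetic serial-biopsy cohort
#'
#' Defines a generative stand-in for a neoadjuvant serial-expression cohort
#' with three biopsy time points (T1 pretreatment, T2 early on-treatment, TS
#' at surgery), print-batch structure, molecular-subtype structure, planted
#' treatment / response / hazard signals and recurrence-free survival.
#' Defaults mirror the study conditions the analysis targets: 48 patients of
#' whom 36 retain a T2 pair, 6 print batches, an RCB class distribution
#' matching a neoadjuvant anthracycline/taxane cohort (about a fifth
#' responders among evaluable patients), and a clear on-treatment
#' downregulation of proliferation/immune genes.
#'
#' @param n_patients Number of patients (default 48).
#' @param n_genes Number of genes (default 2000).
#' @param n_batches Number of print batches with additive per-(batch, gene)
#'   offsets (default 6).
#' @param subtype_proportions Named probabilities of the generating subtypes
#'   (default LumA/LumB/Her2/Basal/Normal = .30/.20/.15/.25/.10).
#' @param n_panel_genes Genes carrying subtype-centroid signal; the first
#'   `n_panel_genes` gene indices form the classifier panel (default 50).
#' @param centroid_effect_size Multiplier on the centroid profile in T1
#'   expression (default 1).
#' @param sigma_noise Residual sd of log2-ratio expression (default 0.5).
#' @param batch_sd Sd of the per-(batch, gene) additive offsets (default 0.5).
#' @param sigma_shift Sd of the within-patient T2 and TS shifts around their
#'   means (default 0.35).
#' @param frac_t2_missing,frac_ts_missing Fraction of eligible T2 / TS
#'   arrays dropped to emulate incomplete pairing (defaults 0.25, 0.10).
#' @param prolif_genes,immune_genes,response_genes,hazard_genes Integer gene
#'   indices of the planted sets (defaults: disjoint blocks after the panel
#'   genes: 51-150, 151-250, 251-300, 301-350).
#' @param allow_overlap Allow planted sets (and the panel) to overlap
#'   (default FALSE; overlapping sets otherwise error).
#' @param t2_downshift Mean decrease at T2 for proliferation/immune genes,
#'   in log2 units (default 0.5).
#' @param response_delta_gap Difference in the T2 - T1 shift of
#'   `response_genes` between responders and nonresponders (default 1).
#'   Group offsets are weighted by the complementary group's expected
#'   frequency so the cohort-mean shift of response genes is zero: only the
#'   between-group contrast is planted.
#' @param rcb_probs Named probabilities of RCB classes
#'   (RCB0/I/II/III/undetermined; default .17/.03/.44/.28/.08, the matched-
#'   pair distribution of a neoadjuvant cohort).
#' @param hazard_beta Log hazard per unit of mean TS expression of
#'   `hazard_genes` (default 0.8).
#' @param hazard_frailty_sd Sd of the patient-level frailty added to every
#'   hazard gene at TS (default 4); this shared component is what makes
#'   single-gene screens recover `hazard_beta` with little attenuation.
#' @param baseline_hazard Baseline exponential hazard per month (default 0.02).
#' @param censor_time_max Administrative censoring horizon in months
#'   (default 60); censoring times are uniform on (0, `censor_time_max`].
#' @param probes_per_gene If > 1, emit a probe-level matrix with this many
#'   probes per gene (probe-level noise sd `probe_noise_sd`) to exercise
#'   probe collapsing (default 1 = gene level).
#' @param probe_noise_sd Probe-level measurement noise sd (default 0.2).
#' @param seed Integer seed; with the seed fixed the cohort is bit-identical.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 48,
                       n_genes = 2000,
                       n_batches = 6,
                       subtype_proportions = c(LumA = 0.30, LumB = 0.20,
                                               Her2 = 0.15, Basal = 0.25,
                                               Normal = 0.10),
                       n_panel_genes = 50,
                       centroid_effect_size = 1,
                       sigma_noise = 0.5,
                       batch_sd = 0.5,
                       sigma_shift = 0.35,
                       frac_t2_missing = 0.25,
                       frac_ts_missing = 0.10,
                       prolif_genes = 51:150,
                       immune_genes = 151:250,
                       response_genes = 251:300,
                       hazard_genes = 301:350,
                       allow_overlap = FALSE,
                       t2_downshift = 0.5,
                       response_delta_gap = 1,
                       rcb_probs = c(RCB0 = 0.17, RCB_I = 0.03, RCB_II = 0.44,
                                     RCB_III = 0.28, undetermined = 0.08),
                       hazard_beta = 0.8,
                       hazard_frailty_sd = 4,
                       baseline_hazard = 0.02,
                       censor_time_max = 60,
                       probes_per_gene = 1,
                       probe_noise_sd = 0.2,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_patients >= 3, n_genes >= 1, n_batches >= 1,
            sigma_noise >= 0, batch_sd >= 0, sigma_shift >= 0,
            hazard_frailty_sd >= 0, probe_noise_sd >= 0,
            frac_t2_missing >= 0, frac_t2_missing < 1,
            frac_ts_missing >= 0, frac_ts_missing < 1,
            baseline_hazard > 0, censor_time_max > 0, probes_per_gene >= 1)
  if (abs(sum(subtype_proportions) - 1) > 1e-8) abort("subtype_proportions must sum to 1.")
  if (abs(sum(rcb_probs) - 1) > 1e-8) abort("rcb_probs must sum to 1.")
  if (!setequal(names(rcb_probs), RCB_LEVELS)) {
    abort("rcb_probs needs exactly the names RCB0, RCB_I, RCB_II, RCB_III, undetermined.")
  }
  planted <- list(panel = seq_len(min(n_panel_genes, n_genes)),
                  prolif = prolif_genes, immune = immune_genes,
                  response = response_genes, hazard = hazard_genes)
  for (nm in names(planted)) {
    idx <- planted[[nm]]
    if (length(idx) > 0 && (min(idx) < 1 || max(idx) > n_genes)) {
      abort(sprintf("Planted gene indices for '%s' fall outside 1..%d.", nm, n_genes))
    }
  }
  if (!allow_overlap) {
    all_idx <- unlist(planted)
    if (anyDuplicated(all_idx)) {
      abort("Planted gene sets (and the panel) overlap; set allow_overlap = TRUE to permit this.")
    }
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a serial-biopsy cohort
#'
#' Generative model (all draws from one stream keyed to `config$seed`, with
#' per-stage substreams so each stage is reproducible independently of
#' evaluation order):
#'
#' 1. Each patient draws a subtype from `subtype_proportions`; each array a
#'    print batch (uniform over `n_batches`).
#' 2. T1 expression of gene g in patient i:
#'    `x = centroid_effect_size * c(subtype_i, g) + batch_offset(batch, g) +
#'    N(0, sigma_noise^2)`, with `c` a centroid profile (standard-normal
#'    entries on the panel genes, 0 elsewhere) and
#'    `batch_offset ~ N(0, batch_sd^2)` per (batch, gene).
#' 3. T2 = T1 + shift, `shift ~ N(mu, sigma_shift^2)`, where `mu` is
#'    `-t2_downshift` for proliferation/immune genes; for response genes
#'    responders add `+response_delta_gap * (1 - pr)` and nonresponders
#'    `-response_delta_gap * pr` (pr = expected responder fraction among
#'    determinate RCB), so the groups differ by the full gap while the
#'    cohort mean stays zero; 0 otherwise. The RCB class (hence responder
#'    label, RCB 0/I vs II/III) is drawn per patient from `rcb_probs` first.
#' 4. TS exists only for residual-disease patients (RCB != 0):
#'    TS = T1 + drift, `drift ~ N(0, sigma_shift^2)`, plus a patient
#'    frailty `u_i ~ N(0, hazard_frailty_sd^2)` added to every hazard gene.
#' 5. RFS: for residual-disease patients, time-to-recurrence is exponential
#'    with `log hazard = log(baseline_hazard) + hazard_beta * mean(TS
#'    expression of hazard genes)`, censored by an independent
#'    Uniform(0, censor_time_max] time; pCR patients are censored at
#'    `censor_time_max`.
#' 6. A fraction of T2 arrays (all patients) and TS arrays (residual-disease
#'    patients) is dropped per the configured missingness; HR status is
#'    positive with probability 0.6 for luminal subtypes, 0.15 otherwise.
#'
#' @param config A [sim_config()].
#' @return A list: `expr` (expression table; probe level if
#'   `probes_per_gene > 1`), `meta` ([sample_meta()] sheet), `centroids`
#'   (the generating [centroid_panel()] over the panel genes), `truth`
#'   (planted memberships: gene ids per planted set, per-patient subtype,
#'   responder label, frailty, and the full config), and `probe_map`
#'   (probe-to-gene tibble when probes are emitted).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  subtypes <- names(cfg$subtype_proportions)

  centro <- with_local_seed(derive_seed(cfg$seed, "centroids"), {
    m <- matrix(0, cfg$n_genes, length(subtypes),
                dimnames = list(genes, subtypes))
    m[seq_len(min(cfg$n_panel_genes, cfg$n_genes)), ] <-
      rnorm(min(cfg$n_panel_genes, cfg$n_genes) * length(subtypes))
    m
  })

  pts <- with_local_seed(derive_seed(cfg$seed, "patients"), {
    subtype <- sample(subtypes, cfg$n_patients, replace = TRUE,
                      prob = cfg$subtype_proportions)
    rcb <- sample(names(cfg$rcb_probs), cfg$n_patients, replace = TRUE,
                  prob = cfg$rcb_probs)
    hr_prob <- ifelse(subtype %in% c("LumA", "LumB"), 0.6, 0.15)
    hr <- ifelse(runif(cfg$n_patients) < hr_prob, "positive", "negative")
    tibble(patient_id = sprintf("P%03d", seq_len(cfg$n_patients)),
           subtype = subtype, rcb = rcb, hr_status = hr)
  })
  pts$responder <- rcb_to_group(pts$rcb) == "responder"
  pts$residual <- pts$rcb != "RCB0" # TS exists only with residual disease

  t1 <- with_local_seed(derive_seed(cfg$seed, "t1"), {
    base <- cfg$centroid_effect_size *
      centro[, match(pts$subtype, subtypes), drop = FALSE]
    base + matrix(rnorm(cfg$n_genes * cfg$n_patients, sd = cfg$sigma_noise),
                  cfg$n_genes)
  })
  colnames(t1) <- pts$patient_id

  mu_shift <- matrix(0, cfg$n_genes, cfg$n_patients)
  mu_shift[cfg$prolif_genes, ] <- -cfg$t2_downshift
  mu_shift[cfg$immune_genes, ] <- -cfg$t2_downshift
  # response genes: responders and nonresponders differ by the full gap, but
  # the weights keep the expected cohort-mean shift at zero so the planted
  # response signal does not masquerade as a marginal time-point change
  pr <- sum(cfg$rcb_probs[c("RCB0", "RCB_I")]) /
    sum(cfg$rcb_probs[c("RCB0", "RCB_I", "RCB_II", "RCB_III")])
  resp_w <- ifelse(pts$responder %in% TRUE, 1 - pr, -pr)
  mu_shift[cfg$response_genes, ] <-
    mu_shift[cfg$response_genes, ] +
    matrix(rep(cfg$response_delta_gap * resp_w, each = length(cfg$response_genes)),
           nrow = length(cfg$response_genes))
  t2 <- t1 + mu_shift + with_local_seed(derive_seed(cfg$seed, "t2"), {
    matrix(rnorm(cfg$n_genes * cfg$n_patients, sd = cfg$sigma_shift), cfg$n_genes)
  })

  ts_all <- with_local_seed(derive_seed(cfg$seed, "ts"), {
    frailty <- rnorm(cfg$n_patients, sd = cfg$hazard_frailty_sd)
    drift <- matrix(rnorm(cfg$n_genes * cfg$n_patients, sd = cfg$sigma_shift),
                    cfg$n_genes)
    m <- t1 + drift
    m[cfg$hazard_genes, ] <- m[cfg$hazard_genes, ] +
      matrix(rep(frailty, each = length(cfg$hazard_genes)),
             nrow = length(cfg$hazard_genes))
    list(m = m, frailty = frailty)
  })

  surv <- with_local_seed(derive_seed(cfg$seed, "survival"), {
    mean_hz <- if (length(cfg$hazard_genes) > 0) {
      colMeans(ts_all$m[cfg$hazard_genes, , drop = FALSE])
    } else rep(0, cfg$n_patients)
    loghaz <- log(cfg$baseline_hazard) + cfg$hazard_beta * mean_hz
    t_event <- rexp(cfg$n_patients, rate = exp(loghaz))
    t_cens <- runif(cfg$n_patients, 0, cfg$censor_time_max)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    time[!pts$residual] <- cfg$censor_time_max # pCR: censored at horizon
    event[!pts$residual] <- 0L
    tibble(rfs_time = time, rfs_event = event)
  })

  drop_idx <- function(n_eligible, frac, stage) {
    with_local_seed(derive_seed(cfg$seed, stage),
                    sample.int(n_eligible, floor(frac * n_eligible)))
  }
  has_t2 <- rep(TRUE, cfg$n_patients)
  has_t2[drop_idx(cfg$n_patients, cfg$frac_t2_missing, "t2drop")] <- FALSE
  ts_eligible <- which(pts$residual)
  has_ts <- rep(FALSE, cfg$n_patients)
  has_ts[ts_eligible] <- TRUE
  has_ts[ts_eligible[drop_idx(length(ts_eligible), cfg$frac_ts_missing, "tsdrop")]] <- FALSE

  samples <- dplyr::bind_rows(
    tibble(patient_id = pts$patient_id, timepoint = "T1"),
    tibble(patient_id = pts$patient_id[has_t2], timepoint = "T2"),
    tibble(patient_id = pts$patient_id[has_ts], timepoint = "TS")
  )
  samples$sample_id <- paste0(samples$patient_id, "_", samples$timepoint)
  samples$batch <- with_local_seed(derive_seed(cfg$seed, "batches"), {
    paste0("B", sample.int(cfg$n_batches, nrow(samples), replace = TRUE))
  })

  batch_off <- with_local_seed(derive_seed(cfg$seed, "batch_offsets"), {
    matrix(rnorm(cfg$n_genes * cfg$n_batches, sd = cfg$batch_sd), cfg$n_genes,
           dimnames = list(genes, paste0("B", seq_len(cfg$n_batches))))
  })

  mats <- list(T1 = t1, T2 = t2, TS = ts_all$m)
  expr_vals <- vapply(seq_len(nrow(samples)), function(i) {
    mats[[samples$timepoint[i]]][, samples$patient_id[i]] +
      batch_off[, samples$batch[i]]
  }, numeric(cfg$n_genes))
  rownames(expr_vals) <- genes
  colnames(expr_vals) <- samples$sample_id

  probe_map <- NULL
  if (cfg$probes_per_gene > 1) {
    k <- cfg$probes_per_gene
    probe_ids <- paste0(rep(genes, each = k), "_pr", seq_len(k))
    probe_map <- tibble(probe_id = probe_ids, gene_id = rep(genes, each = k))
    expr_vals <- expr_vals[rep(seq_len(cfg$n_genes), each = k), , drop = FALSE] +
      with_local_seed(derive_seed(cfg$seed, "probes"), {
        matrix(rnorm(length(probe_ids) * nrow(samples), sd = cfg$probe_noise_sd),
               length(probe_ids))
      })
    rownames(expr_vals) <- probe_ids
  }

  meta <- sample_meta(dplyr::left_join(
    samples,
    dplyr::bind_cols(pts[c("patient_id", "rcb", "hr_status")], surv),
    by = "patient_id"
  ))

  panel_idx <- seq_len(min(cfg$n_panel_genes, cfg$n_genes))
  truth <- list(
    prolif_genes = genes[cfg$prolif_genes],
    immune_genes = genes[cfg$immune_genes],
    response_genes = genes[cfg$response_genes],
    hazard_genes = genes[cfg$hazard_genes],
    panel_genes = genes[panel_idx],
    patients = dplyr::bind_cols(pts, surv,
                                tibble(frailty = ts_all$frailty,
                                       has_t2 = has_t2, has_ts = has_ts)),
    config = cfg
  )
  list(
    expr = expression_table(expr_vals,
                            level = if (cfg$probes_per_gene > 1) "probe" else "gene"),
    meta = meta,
    centroids = centroid_panel(centro[panel_idx, , drop = FALSE]),
    truth = truth,
    probe_map = probe_map
  )
}

#' Compare calls against planted truth
#'
#' @param result A result with `feature_id` and `significant` columns (e.g.
#'   from [run_contrast()] or [screen_rfs()]), or a character vector of
#'   called feature ids plus `universe`.
#' @param planted Character vector of planted (true) feature ids.
#' @param universe Character vector of all tested feature ids (taken from
#'   `result` when it is a result table).
#' @return A one-row tibble: `n_planted`, `n_called`, `n_true_positive`,
#'   `sensitivity` (called planted / planted) and `fdr` (called non-planted
#'   / called; 0 when nothing is called).
#' @export
truth_eval <- function(result, planted, universe = NULL) {
  if (is.data.frame(result)) {
    universe <- result$feature_id
    called <- significant_features(result)
  } else {
    called <- as.character(result)
    if (is.null(universe)) abort("Supply `universe` when `result` is a plain vector.")
  }
  if (!all(planted %in% universe)) {
    abort("Planted features are not all in the tested universe; mismatched cohorts?")
  }
  if (!all(called %in% universe)) abort("Called features outside the universe.")
  tp <- length(intersect(called, planted))
  tibble(
    n_planted = length(planted), n_called = length(called),
    n_true_positive = tp,
    sensitivity = if (length(planted) > 0) tp / length(planted) else NA_real_,
    fdr = if (length(called) > 0) (length(called) - tp) / length(called) else 0
  )
}
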