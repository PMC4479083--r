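test_that("cohorts are bit-identical under a fixed seed and differ across seeds", {
  cfg <- sim_config(n_patients = 12, n_genes = 60, n_panel_genes = 20,
                    hazard_genes = 41:50, prolif_genes = 51:55,
                    immune_genes = 56:58, response_genes = 59:60, seed = 5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(expr_values(a$expr), expr_values(b$expr))
  expect_identical(as.data.frame(a$meta), as.data.frame(b$meta))
  expect_identical(a$truth$patients$frailty, b$truth$patients$frailty)
  cfg2 <- sim_config(n_patients = 12, n_genes = 60, n_panel_genes = 20,
                     hazard_genes = 41:50, prolif_genes = 51:55,
                     immune_genes = 56:58, response_genes = 59:60, seed = 6)
  expect_false(identical(expr_values(a$expr),
                         expr_values(simulate_cohort(cfg2)$expr)))
})

test_that("config validation rejects bad planted sets and proportions", {
  expect_error(sim_config(n_genes = 100, hazard_genes = 90:110), "outside")
  expect_error(sim_config(n_genes = 400, prolif_genes = 51:150,
                          immune_genes = 100:120), "overlap")
  cfg <- sim_config(n_genes = 400, prolif_genes = 51:150,
                    immune_genes = 100:120, allow_overlap = TRUE)
  expect_s3_class(cfg, "sim_config")
  expect_error(sim_config(subtype_proportions = c(A = 0.5, B = 0.4)), "sum to 1")
})

test_that("missingness and sampling structure match the configuration", {
  sim <- simulate_cohort(sim_config(seed = 3))
  m <- sim$meta
  expect_equal(sum(m$timepoint == "T1"), 48)
  # frac_t2_missing = 0.25 drops floor(0.25 * 48) = 12 patients' T2 arrays
  expect_equal(sum(m$timepoint == "T2"), 36)
  # TS exists only for residual-disease (non-RCB0) patients
  ts_pat <- m$patient_id[m$timepoint == "TS"]
  expect_true(all(m$rcb[match(ts_pat, m$patient_id)] != "RCB0"))
  # pCR patients are event-free at the horizon
  pcr <- m$timepoint == "T1" & m$rcb == "RCB0"
  expect_true(all(m$rfs_event[pcr] == 0))
})

test_that("planted T2 downshift appears in the marginal mean of T2 - T1", {
  cfg <- sim_config(n_patients = 60, n_genes = 300, frac_t2_missing = 0,
                    seed = 11, prolif_genes = 51:120, immune_genes = 121:180,
                    response_genes = 181:220, hazard_genes = 221:260)
  sim <- simulate_cohort(cfg)
  v <- expr_values(sim$expr)
  m <- sim$meta
  pts <- m$patient_id[m$timepoint == "T1"]
  D <- v[, paste0(pts, "_T2")] - v[, paste0(pts, "_T1")]
  dbar <- mean(D[cfg$prolif_genes, ])
  se <- stats::sd(D[cfg$prolif_genes, ]) / sqrt(length(D[cfg$prolif_genes, ]))
  expect_lt(abs(dbar - (-cfg$t2_downshift)), 3 * se + 1e-12)
  # response genes carry no marginal shift by construction
  dresp <- mean(D[cfg$response_genes, ])
  se_r <- stats::sd(D[cfg$response_genes, ]) / sqrt(length(D[cfg$response_genes, ]))
  expect_lt(abs(dresp), 4 * se_r)
})

test_that("probe-level emission exercises probe collapsing", {
  cfg <- sim_config(n_patients = 8, n_genes = 40, probes_per_gene = 3,
                    prolif_genes = 31:34, immune_genes = 35:36,
                    response_genes = 37:38, hazard_genes = 39:40,
                    n_panel_genes = 10, seed = 2)
  sim <- simulate_cohort(cfg)
  expect_equal(expr_level(sim$expr), "probe")
  expect_equal(nrow(sim$expr), 120)
  g <- collapse_probes(sim$expr, sim$probe_map)
  expect_equal(expr_level(g), "gene")
  expect_equal(nrow(g), 40)
  # collapsed values average out probe noise around the gene-level signal
  expect_lt(mean(abs(expr_values(g))) - 0, 10) # finite sanity
  expect_equal(dim(expr_values(g)), c(40, ncol(expr_values(sim$expr))))
})

test_that("truth_eval implements the stated sensitivity/FDR conventions", {
  uni <- paste0("g", 1:10)
  planted <- paste0("g", 1:4)
  expect_equal(truth_eval(planted, planted, uni)$sensitivity, 1)
  expect_equal(truth_eval(planted, planted, uni)$fdr, 0)
  none <- truth_eval(character(0), planted, uni)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$fdr, 0) # convention: empty call set has FDR 0
  all_called <- truth_eval(uni, planted, uni)
  expect_equal(all_called$fdr, 1 - length(planted) / length(uni))
  expect_error(truth_eval(planted, c(planted, "not_here"), uni), "universe")
})

test_that("null-configuration cohorts yield uniform raw permutation p-values", {
  ns <- simulate_cohort(sim_config(t2_downshift = 0, response_delta_gap = 0,
                                   hazard_beta = 0, seed = 1))
  nd <- run_contrast(residualize_batch(ns$expr, ns$meta), ns$meta, "t1_vs_t2",
                     n_perm = 10000, seed = 1)
  # Kolmogorov-Smirnov against U(0,1) over 2000 genes; the permutation
  # granularity (multiples of 1/10001) is far below the KS resolution
  ks <- suppressWarnings(stats::ks.test(nd$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})
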