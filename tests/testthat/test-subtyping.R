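make_panel <- function(n_genes = 40, subtypes = c("LumA", "LumB", "Basal"),
                       seed = 5) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * length(subtypes)), n_genes,
              dimnames = list(paste0("G", seq_len(n_genes)), subtypes))
  centroid_panel(m)
}

test_that("nearest-centroid assignment satisfies the argmax contract", {
  panel <- make_panel()
  cm <- serialdex:::centroid_matrix(panel)
  prof <- setNames(cm[, "LumB"], rownames(cm))
  call <- assign_subtype(prof, panel)
  expect_equal(call$label, "LumB")
  expect_equal(call$cor_LumB, 1)
  expect_false(call$tie)

  # the anti-profile of a centroid goes to whichever centroid correlates
  # best with its negation, never to the centroid itself
  anti <- assign_subtype(-prof, panel)
  expect_true(anti$label != "LumB")
  expect_equal(anti$label, names(which.max(cor(-prof, cm, method = "spearman")[1, ])))
})

test_that("Spearman calls are invariant under strictly monotone transforms", {
  panel <- make_panel()
  cm <- serialdex:::centroid_matrix(panel)
  set.seed(10)
  for (i in 1:5) {
    prof <- setNames(cm[, sample(colnames(cm), 1)] + rnorm(nrow(cm), sd = 0.5),
                     rownames(cm))
    a <- assign_subtype(prof, panel, metric = "spearman")
    b <- assign_subtype(exp(2 * prof) + 3, panel, metric = "spearman")
    expect_equal(b$label, a$label)
    expect_equal(b$cor_LumA, a$cor_LumA)
  }
})

test_that("insufficient shared genes and ties are reported", {
  panel <- make_panel()
  prof <- setNames(rnorm(40), paste0("G", 1:40))
  expect_error(assign_subtype(prof[1:10], panel), "10 shared")
  # duplicated centroid column forces an exact tie, broken by column order
  cm <- serialdex:::centroid_matrix(panel)
  dup <- centroid_panel(cbind(A = cm[, 1], B = cm[, 1]))
  call <- assign_subtype(setNames(cm[, 1], rownames(cm)), dup)
  expect_true(call$tie)
  expect_equal(call$label, "A")
})

test_that("concordance reproduces whole-percentage rates with away-from-zero rounding", {
  # 36 pairs with 9 changed -> 75 %; 39 pairs with 15 changed -> 62 %
  # (24/39 = 61.54 rounds to 62, not 61)
  mk <- function(n_pairs, n_changed) {
    pts <- sprintf("P%02d", seq_len(n_pairs))
    meta <- make_meta(setNames(rep(list(c("T1", "T2")), n_pairs), pts))
    from <- rep("LumA", n_pairs)
    to <- c(rep("Basal", n_changed), rep("LumA", n_pairs - n_changed))
    a <- tibble::tibble(sample_id = paste0(pts, "_T1"), label = from)
    b <- tibble::tibble(sample_id = paste0(pts, "_T2"), label = to)
    concordance(a, b, meta)
  }
  c36 <- mk(36, 9)
  expect_equal(c36$rate_percent, 75)
  expect_equal(c36$n_identical, 27)
  c39 <- mk(39, 15)
  expect_equal(c39$rate_percent, 62)
  c39b <- mk(39, 24)
  expect_equal(c39b$rate_percent, 38) # 15/39, the complementary rate

  ident <- mk(10, 0)
  expect_equal(ident$rate_percent, 100)
  expect_equal(nrow(dplyr::filter(ident$transitions, from != to)), 0)
})

test_that("concordance is symmetric and its transition table transposes", {
  pts <- sprintf("P%02d", 1:12)
  meta <- make_meta(setNames(rep(list(c("T1", "T2")), 12), pts))
  set.seed(3)
  a <- tibble::tibble(sample_id = paste0(pts, "_T1"),
                      label = sample(c("LumA", "LumB", "Basal"), 12, TRUE))
  b <- tibble::tibble(sample_id = paste0(pts, "_T2"),
                      label = sample(c("LumA", "LumB", "Basal"), 12, TRUE))
  ab <- concordance(a, b, meta)
  ba <- concordance(b, a, meta)
  expect_equal(ab$rate_percent, ba$rate_percent)
  rev_tab <- dplyr::arrange(tibble::tibble(from = ba$transitions$to,
                                           to = ba$transitions$from,
                                           n = ba$transitions$n), from, to)
  expect_equal(dplyr::arrange(ab$transitions, from, to), rev_tab)

  expect_error(concordance(a[0, ], b, meta), "matched pairs|sample sheet")
})

test_that("generated subtypes are recovered from low-noise cohorts", {
  sim <- simulate_cohort(sim_config(n_patients = 40, n_genes = 300,
                                    sigma_noise = 0.15,
                                    prolif_genes = 51:100, immune_genes = 101:150,
                                    response_genes = 151:200, hazard_genes = 201:250,
                                    seed = 9))
  expr <- residualize_batch(sim$expr, sim$meta)
  calls <- assign_subtypes(expr, sim$centroids)
  m <- sim$meta
  t1 <- calls[calls$sample_id %in% m$sample_id[m$timepoint == "T1"], ]
  truth <- sim$truth$patients$subtype[match(sub("_T1$", "", t1$sample_id),
                                            sim$truth$patients$patient_id)]
  expect_gte(mean(t1$label == truth), 0.95)
})
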