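test_that("cox_fit honors degenerate contracts", {
  time <- c(5, 8, 12, 3, 9, 15, 7, 11, 4, 10)
  event <- c(1, 0, 1, 1, 0, 0, 1, 0, 1, 0)
  const <- cox_fit(rep(2, 10), time, event)
  expect_equal(const$beta, 0)
  expect_equal(const$lr_statistic, 0)
  expect_equal(const$lr_p, 1)
  expect_true(const$degenerate)

  none <- cox_fit(rnorm(10), time, rep(0, 10), min_events = 0)
  expect_equal(none$beta, 0)
  expect_true(none$degenerate)

  expect_error(cox_fit(rnorm(5), time[1:5], event[1:5], min_n = 10), ">= 10")
})

test_that("cox_fit agrees with a grid-search partial-likelihood maximizer", {
  set.seed(4)
  for (i in 1:4) {
    n <- 8
    x <- rnorm(n)
    time <- rexp(n, exp(0.5 * x))
    event <- rep(1, n)
    fit <- cox_fit(x, time, event, min_n = 5, min_events = 1)
    grid <- seq(-4, 4, by = 5e-4)
    ll <- vapply(grid, breslow_loglik, numeric(1), x = x, time = time,
                 event = event)
    expect_lt(abs(fit$beta - grid[which.max(ll)]), 1e-3)
    # LR statistic recomputed from the oracle log-likelihood
    lr_oracle <- 2 * (max(ll) - breslow_loglik(0, x, time, event))
    expect_equal(fit$lr_statistic, lr_oracle, tolerance = 1e-4)
  }
})

test_that("Kaplan-Meier estimate equals 1 - ECDF without censoring", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$n_risk, 4:1)

  set.seed(12)
  tt <- sort(runif(15))
  km2 <- km_estimate(tt, rep(1, 15))
  expect_equal(km2$surv, 1 - stats::ecdf(tt)(km2$time))
})

test_that("log-rank test matches a hand-computed 2x2-table oracle", {
  ident <- logrank_test(rep(c(1, 3, 5), 2), rep(c(1, 1, 0), 2),
                        rep(c("a", "b"), each = 3))
  expect_equal(ident$chi2, 0)
  expect_equal(ident$p, 1)

  # 6-subject fixture: group A times 2, 4, 6 (all events),
  # group B times 3, 5, 7 (events at 3 and 5, censored at 7)
  time <- c(2, 4, 6, 3, 5, 7)
  event <- c(1, 1, 1, 1, 1, 0)
  grp <- rep(c("A", "B"), each = 3)
  # hand computation over the risk sets at each distinct event time
  o_minus_e <- 0; v <- 0
  for (t in sort(time[event == 1])) {
    at_risk <- time >= t
    d <- sum(time == t & event == 1)
    n <- sum(at_risk)
    n_a <- sum(at_risk & grp == "A")
    d_a <- sum(time == t & event == 1 & grp == "A")
    o_minus_e <- o_minus_e + d_a - d * n_a / n
    v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / max(n - 1, 1)
  }
  oracle_chi2 <- o_minus_e^2 / v
  lr <- logrank_test(time, event, grp)
  expect_equal(lr$chi2, oracle_chi2, tolerance = 1e-12)
  expect_equal(lr$p, pchisq(oracle_chi2, 1, lower.tail = FALSE))

  expect_error(logrank_test(c(1, 2), c(0, 0), c("a", "b")), "event")
})

test_that("Wilcoxon signed-rank is exact for small n and symmetric", {
  expect_equal(wilcoxon_signed_rank(1:6, 1:6)$p, 1)
  r <- wilcoxon_signed_rank(rep(0, 5), 1:5)
  expect_equal(r$p, 2 / 32)
  expect_equal(r$statistic, 15)
  expect_true(r$exact)

  set.seed(6)
  a <- rnorm(12); b <- rnorm(12)
  expect_equal(wilcoxon_signed_rank(a, b)$p, wilcoxon_signed_rank(b, a)$p)
  # tie-free exact p agrees with the classical implementation
  expect_equal(wilcoxon_signed_rank(a, b)$p,
               stats::wilcox.test(b, a, paired = TRUE, exact = TRUE)$p.value)
  # beyond the enumeration limit the normal approximation is close
  a2 <- rnorm(40); b2 <- a2 + rnorm(40, 0.4)
  approx <- wilcoxon_signed_rank(a2, b2)
  expect_false(approx$exact)
  ref <- stats::wilcox.test(b2, a2, paired = TRUE, exact = FALSE,
                            correct = TRUE)$p.value
  expect_equal(approx$p, ref, tolerance = 1e-10)
})

test_that("tertile dichotomization is deterministic and documented", {
  top <- dichotomize_tertile(1:9, "top_vs_rest")
  expect_equal(which(top == "high"), 7:9)
  bottom <- dichotomize_tertile(1:9, "bottom_vs_rest")
  expect_equal(which(bottom == "low"), 1:3)
  # ties straddling the cut all fall to the "rest" side of the interpolated
  # quantile; sizes are deterministic
  ties <- dichotomize_tertile(c(1, 2, 2, 2, 3, 4), "top_vs_rest")
  expect_equal(as.vector(table(ties)), c(4, 2))
  expect_equal(which(ties == "high"), 5:6)
  expect_error(dichotomize_tertile(rep(3, 6)), "distinct")
})

test_that("RFS screens restrict surgical-sample analyses to residual disease", {
  # P1 is pCR (RCB 0) but has a TS sample on file: it must not enter the
  # TS screen; P7 has undetermined RCB and is excluded from outcome screens
  specs <- setNames(rep(list(c("T1", "TS")), 12), paste0("P", 1:12))
  rcb <- setNames(c("0", rep(c("II", "III"), 5), "undetermined"),
                  paste0("P", 1:12))
  rfs_time <- setNames(seq(2, 24, by = 2), paste0("P", 1:12))
  rfs_event <- setNames(rep(c(1, 0), 6), paste0("P", 1:12))
  meta <- make_meta(specs, rcb = rcb, rfs_time = rfs_time,
                    rfs_event = rfs_event)
  set.seed(2)
  v <- matrix(rnorm(3 * 24), 3, 24, dimnames = list(NULL, meta$sample_id))
  sr <- screen_rfs(make_expr(v), meta, mode = "ts", p_threshold = 0.005)
  expect_equal(attr(sr, "n_patients"), 10)

  # identical features yield identical results
  v2 <- v; v2[2, ] <- v2[1, ]; v2[3, ] <- v2[1, ]
  sr2 <- screen_rfs(make_expr(v2), meta, mode = "ts")
  expect_equal(sr2$beta[2], sr2$beta[1])
  expect_equal(sr2$lr_p[3], sr2$lr_p[1])

  # the T1 screen uses everyone with RFS data, including pCR and undetermined
  sr_t1 <- screen_rfs(make_expr(v), meta, mode = "t1")
  expect_equal(attr(sr_t1, "n_patients"), 12)
})
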