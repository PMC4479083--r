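test_that("paired permutation test matches the exhaustive enumeration oracle", {
  # classic small case: d = (1, 2, 3); only the two global sign patterns
  # reach |t_obs| among the 8 assignments
  r <- paired_permutation_test(c(0, 0, 0), c(1, 2, 3), n_perm = 1000, seed = 1)
  expect_equal(r$p, 2 / 8)
  expect_true(r$exhaustive)
  expect_equal(r$n_total, 8)
  expect_equal(r$p, oracle_paired_p(c(1, 2, 3)))

  set.seed(21)
  for (n in c(4, 6, 9, 11)) {
    d <- rnorm(n)
    r <- paired_permutation_test(rep(0, n), d, n_perm = 2^n, seed = 1)
    expect_true(r$exhaustive)
    expect_equal(r$p, oracle_paired_p(d))
  }
})

test_that("paired test honors its degenerate and precondition contracts", {
  r <- paired_permutation_test(c(1, 2, 3, 4), c(1, 2, 3, 4), seed = 1)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_error(paired_permutation_test(1:2, 2:3, seed = 1), ">= 3")
  # pairs with missing members are dropped before the n >= 3 check
  expect_error(paired_permutation_test(c(1, 2, NA, NA), c(2, 3, 4, 5), seed = 1),
               ">= 3")
})

test_that("Monte-Carlo and exhaustive p-values agree on the same data", {
  set.seed(9)
  d <- rnorm(10, mean = 0.4)
  ex <- paired_permutation_test(rep(0, 10), d, n_perm = 2000, seed = 1) # 2^10 enumerated
  mc <- paired_permutation_test(rep(0, 10), d, n_perm = 900, seed = 4)  # sampled
  expect_true(ex$exhaustive)
  expect_false(mc$exhaustive)
  expect_lt(abs(ex$p - mc$p), 2 / sqrt(900))
})

test_that("permutation p-values are granular and sign-symmetric", {
  set.seed(33)
  for (i in 1:10) {
    d <- rnorm(sample(5:14, 1), mean = runif(1, -1, 1))
    r <- paired_permutation_test(rep(0, length(d)), d, n_perm = 500, seed = i)
    k <- r$p * r$n_total
    expect_equal(k, round(k))
    expect_gte(k, 1)
    rneg <- paired_permutation_test(d, rep(0, length(d)), n_perm = 500, seed = i)
    expect_equal(rneg$t, -r$t)
    expect_equal(rneg$p, r$p)
  }
})

test_that("two-group test matches the label-permutation oracle", {
  r <- two_group_permutation_test(c(0, 0, 5, 5), c("A", "A", "B", "B"),
                                  n_perm = 100, seed = 1)
  expect_equal(r$p, 2 / 6)
  expect_true(r$exhaustive)
  expect_equal(r$mean_diff, 5)

  set.seed(14)
  for (i in 1:5) {
    x <- rnorm(9)
    g <- rep(c("A", "B"), c(4, 5))
    r <- two_group_permutation_test(x, g, n_perm = choose(9, 4), seed = 1)
    expect_equal(r$p, oracle_group_p(x, 1:4))
  }

  tie <- two_group_permutation_test(c(1, 2, 1, 2), c("A", "A", "B", "B"),
                                    n_perm = 100, seed = 1)
  expect_equal(tie$t, 0)
  expect_equal(tie$p, 1)
  expect_error(two_group_permutation_test(1:4, rep("A", 4), seed = 1),
               "two groups")
})

test_that("BH adjustment matches the step-up oracle and its invariants", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")

  # missing entries pass through and are excluded from m
  expect_equal(bh_adjust(c(0.02, NA, 0.04)), c(0.04, NA, 0.04))

  set.seed(8)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj > 0 & adj <= 1))
    # monotone nondecreasing in raw-p rank order
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
    # order-equivariance
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm])
  }
})

test_that("matrix engines agree with the single-feature tests", {
  set.seed(77)
  D <- matrix(rnorm(6 * 8, mean = 0.3), 6, 8)
  D[2, c(1, 5)] <- NA
  D[5, ] <- 0
  rownames(D) <- paste0("g", 1:6)
  res <- serialdex:::perm_paired_matrix(D, n_perm = 2^8, seed = 3)
  for (i in 1:6) {
    d <- D[i, !is.na(D[i, ])]
    single <- paired_permutation_test(rep(0, length(d)), d, n_perm = 2^8, seed = 3)
    expect_equal(res$t[i], single$t, tolerance = 1e-12)
    expect_equal(res$p[i], single$p)
  }

  X <- matrix(rnorm(5 * 10), 5, 10)
  X[3, 2] <- NA
  rownames(X) <- paste0("g", 1:5)
  g1 <- rep(c(TRUE, FALSE), each = 5)
  resg <- serialdex:::perm_group_matrix(X, g1, n_perm = choose(10, 5), seed = 2)
  for (i in c(1, 2, 4, 5)) {
    single <- two_group_permutation_test(X[i, ], ifelse(g1, "A", "B"),
                                         n_perm = choose(10, 5), seed = 2)
    expect_equal(resg$t[i], single$t, tolerance = 1e-12)
    expect_equal(resg$p[i], single$p)
  }
})

test_that("run_contrast applies pairing, thresholds and degenerate contracts", {
  # 6 patients, T1 + T2; identical delta everywhere -> nothing significant
  specs <- setNames(as.list(rep(list(c("T1", "T2")), 6)), paste0("P", 1:6))
  rcb <- setNames(c("0", "0", "II", "II", "III", "I"), paste0("P", 1:6))
  meta <- make_meta(specs, rcb = rcb)
  v <- matrix(rnorm(5 * 12), 5, 12, dimnames = list(NULL, meta$sample_id))
  t2cols <- grepl("_T2$", colnames(v))
  v[, t2cols] <- v[, !t2cols] + 1 # constant shift for every patient
  de <- run_contrast(make_expr(v), meta, "rcb_delta_t2", n_perm = 200, seed = 1)
  expect_equal(sum(de$significant), 0)
  expect_true(all(de$p == 1))

  # the paired contrast sees the constant +1 shift as maximally significant
  # at permutation granularity
  dep <- run_contrast(make_expr(v), meta, "t1_vs_t2", n_perm = 200, seed = 1)
  expect_true(all(dep$p == 2 / 64)) # exhaustive over 2^6 sign flips
  expect_true(all(dep$direction == "up"))

  expect_error(run_contrast(make_expr(v[, 1:2]), meta[1:2, ], "t1_vs_t2",
                            seed = 1), "pairs")
})
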