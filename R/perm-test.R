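# ---- RNG scoping -----------------------------------------------------------

# run code under a local RNG stream without disturbing the caller's stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# ---- null-assignment matrices ----------------------------------------------

# all 2^n sign vectors, rows = assignments; row 1 is the identity (+1...+1)
all_sign_vectors <- function(n) {
  g <- expand.grid(rep(list(c(1, -1)), n))
  as.matrix(g[order(rowSums(g == -1)), , drop = FALSE])[, , drop = FALSE]
}

sampled_sign_vectors <- function(n, n_perm, seed) {
  with_local_seed(seed, {
    rbind(rep(1, n),
          matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), nrow = n_perm))
  })
}

# sign matrix for a paired test on n pairs; identity row always present
sign_matrix <- function(n, n_perm, seed) {
  if (2^n <= n_perm) {
    list(S = all_sign_vectors(n), exhaustive = TRUE)
  } else {
    list(S = sampled_sign_vectors(n, n_perm, seed), exhaustive = FALSE)
  }
}

# group-1 membership indicators (n x P) for a two-group test; column 1 is the
# observed assignment
group_indicator_matrix <- function(n, idx1, n_perm, seed) {
  n1 <- length(idx1)
  n_total <- choose(n, n1)
  if (n_total <= n_perm) {
    combos <- combn(n, n1)
    Z <- matrix(0, n, ncol(combos))
    Z[cbind(as.vector(combos), rep(seq_len(ncol(combos)), each = n1))] <- 1
    obs <- which(colSums(Z[idx1, , drop = FALSE]) == n1)[1]
    Z <- cbind(Z[, obs], Z[, -obs, drop = FALSE])
    list(Z = Z, exhaustive = TRUE)
  } else {
    Z <- with_local_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        z <- numeric(n); z[sample.int(n, n1)] <- 1; z
      }, numeric(n))
    })
    z0 <- numeric(n); z0[idx1] <- 1
    list(Z = cbind(z0, Z), exhaustive = FALSE)
  }
}

# ---- t statistics ----------------------------------------------------------

# one-sample t on differences; sample sd (n-1); degenerate contracts:
# all-zero -> 0, zero-variance nonzero mean -> signed Inf
paired_t_stat <- function(d) {
  n <- length(d)
  m <- mean(d)
  v <- sum((d - m)^2) / (n - 1)
  if (v <= 0) {
    if (m == 0) 0 else sign(m) * Inf
  } else {
    m / sqrt(v / n)
  }
}

# Welch t for group2 - group1 (so the sign matches `mean_difference`)
welch_t_stat <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  m1 <- mean(x1); m2 <- mean(x2)
  se2 <- var_or_zero(x1) / n1 + var_or_zero(x2) / n2
  if (se2 <= 0) {
    if (m2 == m1) 0 else sign(m2 - m1) * Inf
  } else {
    (m2 - m1) / sqrt(se2)
  }
}

var_or_zero <- function(x) if (length(x) < 2) 0 else sum((x - mean(x))^2) / (length(x) - 1)

# count permutations with |t_perm| >= |t_obs| under a small relative
# tolerance (ties at exactly |t_obs|, e.g. the global sign flip, must count)
perm_tail_p <- function(t_perm_abs, t_obs) {
  thr <- abs(t_obs) * (1 - 1e-12) - 1e-12
  sum(t_perm_abs >= thr) / length(t_perm_abs)
}

# ---- user-facing single tests ----------------------------------------------

#' Paired-sample permutation test based on the t-statistic
#'
#' Tests whether paired measurements differ between two conditions. The
#' statistic is the one-sample t of the differences `d = b - a`,
#' `t = mean(d) / (sd(d) / sqrt(n))` with the (n-1)-denominator sd. The null
#' distribution flips the sign of each difference independently: all `2^n`
#' sign vectors when `2^n <= n_perm` (exhaustive), otherwise `n_perm` random
#' sign vectors plus the identity. The two-sided p-value is the fraction of
#' assignments with `|t| >= |t_obs|`; the identity is always counted, so
#' `p >= 1/total`.
#'
#' @param a,b Paired numeric vectors (condition A, condition B). Pairs with a
#'   missing member are dropped; at least 3 complete pairs are required.
#' @param n_perm Permutation budget (default 10000).
#' @param seed Integer seed for the Monte-Carlo sign draws (required; ignored
#'   in the exhaustive case).
#' @return A one-row tibble: `t`, `p`, `mean_diff` (mean of `b - a`), `n`
#'   (complete pairs), `n_total` (assignments evaluated), `exhaustive`.
#' @examples
#' paired_permutation_test(c(0, 0, 0), c(1, 2, 3), seed = 1) # p = 2/8
#' @export
paired_permutation_test <- function(a, b, n_perm = 10000, seed) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  d <- (b - a)[ok]
  n <- length(d)
  if (n < 3) abort(sprintf("Need >= 3 complete pairs; have %d.", n))
  if (all(d == 0)) {
    return(tibble(t = 0, p = 1, mean_diff = 0, n = n,
                  n_total = NA_integer_, exhaustive = NA))
  }
  sm <- sign_matrix(n, n_perm, seed)
  t_perm <- apply(sm$S, 1, function(s) paired_t_stat(s * d))
  t_obs <- paired_t_stat(d)
  tibble(t = t_obs, p = perm_tail_p(abs(t_perm), t_obs), mean_diff = mean(d),
         n = n, n_total = nrow(sm$S), exhaustive = sm$exhaustive)
}

#' Two-group permutation test based on the Welch t-statistic
#'
#' Compares a numeric value between two groups using the unequal-variance
#' (Welch) t-statistic, oriented as `mean(group 2) - mean(group 1)` where
#' group order is the factor-level order of `groups`. The null distribution
#' reassigns group labels preserving group sizes: exhaustive enumeration when
#' `choose(n, n1) <= n_perm`, otherwise `n_perm` random reassignments plus
#' the observed one. Two-sided p as in [paired_permutation_test()].
#'
#' @param values Numeric vector; missing values are dropped (with their label).
#' @param groups Factor (or coercible) with exactly two levels; each group
#'   needs >= 2 non-missing values.
#' @inheritParams paired_permutation_test
#' @return A one-row tibble: `t`, `p`, `mean_diff`, `n1`, `n2`, `n_total`,
#'   `exhaustive`.
#' @examples
#' two_group_permutation_test(c(0, 0, 5, 5), c("A", "A", "B", "B"), seed = 1) # p = 2/6
#' @export
two_group_permutation_test <- function(values, groups, n_perm = 10000, seed) {
  groups <- droplevels(as.factor(groups))
  stopifnot(length(values) == length(groups))
  ok <- !is.na(values) & !is.na(groups)
  x <- values[ok]; g <- groups[ok]
  if (nlevels(g) != 2) abort("Need exactly two groups with data.")
  lv <- levels(g)
  n1 <- sum(g == lv[1]); n2 <- sum(g == lv[2])
  if (n1 < 2 || n2 < 2) {
    abort(sprintf("Each group needs >= 2 values (have %d and %d).", n1, n2))
  }
  t_obs <- welch_t_stat(x[g == lv[1]], x[g == lv[2]])
  if (t_obs == 0 && var_or_zero(x) == 0) {
    return(tibble(t = 0, p = 1, mean_diff = 0, n1 = n1, n2 = n2,
                  n_total = NA_integer_, exhaustive = NA))
  }
  gm <- group_indicator_matrix(length(x), which(g == lv[1]), n_perm, seed)
  t_perm <- apply(gm$Z, 2, function(z) {
    welch_t_stat(x[z == 1], x[z == 0])
  })
  tibble(t = t_obs, p = perm_tail_p(abs(t_perm), t_obs),
         mean_diff = mean(x[g == lv[2]]) - mean(x[g == lv[1]]),
         n1 = n1, n2 = n2, n_total = ncol(gm$Z), exhaustive = gm$exhaustive)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment: with `m` non-missing p-values sorted ascending,
#' `q_i = p_(i) * m / i` and the adjusted value at rank `i` is
#' `min(1, min_{j >= i} q_j)`, returned in the original order. Missing
#' entries pass through as missing and do not count toward `m`.
#'
#' @param p Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_adjust <- function(p) {
  out <- as.numeric(p)
  ok <- !is.na(out)
  if (any(out[ok] <= 0 | out[ok] > 1)) abort("p-values must lie in (0, 1].")
  out[ok] <- p.adjust(out[ok], method = "BH")
  out
}

# ---- vectorized per-feature engines (shared null assignments) --------------

# paired permutation test for every row of a differences matrix D
# (features x pairs). Features sharing a missingness pattern share one null
# sign matrix, keyed deterministically to `seed` and the pattern.
perm_paired_matrix <- function(D, n_perm, seed) {
  nfeat <- nrow(D)
  res <- tibble(feature_id = rownames(D) %||% as.character(seq_len(nfeat)),
                t = NA_real_, p = NA_real_, mean_diff = NA_real_,
                n = NA_integer_, exhaustive = NA)
  pat <- do.call(paste0, as.data.frame((!is.na(D)) * 1L))
  for (pk in unique(pat)) {
    rows <- which(pat == pk)
    use <- which(strsplit(pk, "")[[1]] == "1")
    n <- length(use)
    res$n[rows] <- n
    if (n < 3) next # too few complete pairs for this feature; left NA
    sm <- sign_matrix(n, n_perm, derive_seed(seed, paste0("pairs", pk)))
    # chunk features so the features x assignments block stays ~128 MB
    chunk <- max(1L, floor(2^24 / nrow(sm$S)))
    for (rows_i in split(rows, ceiling(seq_along(rows) / chunk))) {
      Dk <- D[rows_i, use, drop = FALSE]
      ss <- rowSums(Dk^2)
      t_all <- perm_paired_block(Dk, sm$S, ss, n)
      t_obs <- t_all[, 1]
      p <- vapply(seq_along(rows_i), function(i) {
        perm_tail_p(abs(t_all[i, ]), t_obs[i])
      }, numeric(1))
      allzero <- ss == 0
      t_obs[allzero] <- 0; p[allzero] <- 1
      res$t[rows_i] <- t_obs
      res$p[rows_i] <- p
      res$mean_diff[rows_i] <- rowMeans(Dk)
      res$exhaustive[rows_i] <- sm$exhaustive
    }
  }
  res
}

# t statistics for all features x all sign assignments (S rows); identity
# must be row 1 of S so column 1 holds the observed t
perm_paired_block <- function(Dk, S, ss, n) {
  M <- Dk %*% t(S) / n
  V <- (ss - n * M^2) / (n - 1)
  V[V < 0] <- 0
  T <- M / sqrt(V / n)
  T[V == 0 & M != 0] <- sign(M[V == 0 & M != 0]) * Inf
  T[V == 0 & M == 0] <- 0
  T
}

# Welch two-group permutation test for every row of X (features x samples);
# g1 indicates group-1 membership. Missingness patterns share indicators.
perm_group_matrix <- function(X, g1, n_perm, seed) {
  nfeat <- nrow(X)
  res <- tibble(feature_id = rownames(X) %||% as.character(seq_len(nfeat)),
                t = NA_real_, p = NA_real_, mean_diff = NA_real_,
                n1 = NA_integer_, n2 = NA_integer_, exhaustive = NA)
  pat <- do.call(paste0, as.data.frame((!is.na(X)) * 1L))
  for (pk in unique(pat)) {
    rows <- which(pat == pk)
    use <- which(strsplit(pk, "")[[1]] == "1")
    idx1 <- which(g1[use]); n1 <- length(idx1)
    n <- length(use); n2 <- n - n1
    res$n1[rows] <- n1; res$n2[rows] <- n2
    if (n1 < 2 || n2 < 2) next
    gm <- group_indicator_matrix(n, idx1, n_perm,
                                 derive_seed(seed, paste0("groups", pk)))
    Z <- gm$Z
    chunk <- max(1L, floor(2^24 / ncol(Z)))
    for (rows_i in split(rows, ceiling(seq_along(rows) / chunk))) {
    Xk <- X[rows_i, use, drop = FALSE]
    S1 <- Xk %*% Z
    Q1 <- (Xk^2) %*% Z
    st <- rowSums(Xk); qt <- rowSums(Xk^2)
    M1 <- S1 / n1
    M2 <- (st - S1) / n2
    V1 <- (Q1 - n1 * M1^2) / max(n1 - 1, 1)
    V2 <- ((qt - Q1) - n2 * M2^2) / max(n2 - 1, 1)
    V1[V1 < 0] <- 0; V2[V2 < 0] <- 0
    SE2 <- V1 / n1 + V2 / n2
    T <- (M2 - M1) / sqrt(SE2)
    deg <- SE2 == 0
    T[deg & M2 == M1] <- 0
    T[deg & M2 != M1] <- sign((M2 - M1)[deg & M2 != M1]) * Inf
    t_obs <- T[, 1]
    p <- vapply(seq_along(rows_i), function(i) {
      perm_tail_p(abs(T[i, ]), t_obs[i])
    }, numeric(1))
    res$t[rows_i] <- t_obs
    res$p[rows_i] <- p
    res$mean_diff[rows_i] <- M2[, 1] - M1[, 1]
    res$exhaustive[rows_i] <- gm$exhaustive
    }
  }
  res
}
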