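# small in-code fixtures shared across test files

# minimal sample sheet: one row per (patient, timepoint) given as
# "P1:T1,T2" style specs; batches round-robin
make_meta <- function(specs, rcb = NULL, rfs_time = NULL, rfs_event = NULL,
                      n_batches = 2) {
  rows <- purrr::imap_dfr(specs, function(tps, pid) {
    tibble::tibble(patient_id = pid, timepoint = tps,
                   sample_id = paste0(pid, "_", tps))
  })
  rows$batch <- paste0("B", (seq_len(nrow(rows)) - 1) %% n_batches + 1)
  if (!is.null(rcb)) rows$rcb <- rcb[rows$patient_id]
  if (!is.null(rfs_time)) rows$rfs_time <- rfs_time[rows$patient_id]
  if (!is.null(rfs_event)) rows$rfs_event <- rfs_event[rows$patient_id]
  sample_meta(rows)
}

# expression table from a plain matrix (features x samples)
make_expr <- function(m, level = "gene") {
  if (is.null(rownames(m))) rownames(m) <- paste0("G", seq_len(nrow(m)))
  expression_table(m, level = level)
}

# independent enumeration oracle for the paired sign-flip test
oracle_paired_p <- function(d) {
  n <- length(d)
  tstat <- function(x) {
    s <- stats::sd(x)
    if (s == 0) return(if (mean(x) == 0) 0 else sign(mean(x)) * Inf)
    mean(x) / (s / sqrt(n))
  }
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  ts <- apply(signs, 1, function(s) tstat(s * d))
  t_obs <- tstat(d)
  mean(abs(ts) >= abs(t_obs) - 1e-9)
}

# independent enumeration oracle for the two-group label permutation test
oracle_group_p <- function(x, g1_idx) {
  n <- length(x)
  n1 <- length(g1_idx)
  welch <- function(i1) {
    a <- x[i1]; b <- x[-i1]
    se2 <- stats::var(a) / length(a) + stats::var(b) / length(b)
    if (se2 == 0) return(if (mean(b) == mean(a)) 0 else Inf)
    (mean(b) - mean(a)) / sqrt(se2)
  }
  combos <- utils::combn(n, n1, simplify = FALSE)
  ts <- vapply(combos, welch, numeric(1))
  mean(abs(ts) >= abs(welch(g1_idx)) - 1e-9)
}

# direct BH step-up oracle
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# Breslow log partial likelihood for a single covariate (no ties assumed
# beyond Breslow's handling); used as a grid-search oracle for cox_fit
breslow_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# the default-condition cohort used by recovery checks, built once
acceptance_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_cohort(sim_config(seed = 20150529))
      expr <- residualize_batch(sim$expr, sim$meta)
      de <- run_contrast(expr, sim$meta, "t1_vs_t2", n_perm = 10000, seed = 20150529)
      cache <<- list(sim = sim, expr = expr, de = de)
    }
    cache
  }
})
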