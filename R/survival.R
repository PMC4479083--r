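#' Cox proportional-hazards fit for one covariate
#'
#' Fits the Cox model for recurrence-free survival on a single continuous
#' covariate (optionally adjusted for additional covariates such as hormone
#' receptor status) and reports the likelihood-ratio test against the model
#' without the covariate of interest — the adjustment covariates are
#' retained in both models. Breslow tie handling by default (switchable to
#' Efron). Fitting is by the partial-likelihood Newton-Raphson of
#' [survival::coxph()].
#'
#' @param x Numeric covariate (e.g., one gene's expression).
#' @param time,event Follow-up time and event indicator (1 = recurrence).
#' @param adjust Optional data frame of adjustment covariates.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param min_n,min_events Minimum usable subjects / events (defaults 10, 3).
#' @return A one-row tibble: `beta`, `se`, `hr` (hazard ratio `exp(beta)`),
#'   `lr_statistic`, `lr_p`, `n`, `n_events`, `degenerate` flag, `adjusted`.
#' @export
cox_fit <- function(x, time, event, adjust = NULL, ties = c("breslow", "efron"),
                    min_n = 10, min_events = 3) {
  ties <- match.arg(ties)
  df <- tibble(x = as.numeric(x), time = as.numeric(time),
               event = as.integer(event))
  if (!is.null(adjust)) df <- dplyr::bind_cols(df, as_tibble(adjust))
  df <- df[complete.cases(df), , drop = FALSE]
  n <- nrow(df); n_events <- sum(df$event)
  if (n < min_n) abort(sprintf("Need >= %d subjects with complete data; have %d.", min_n, n))
  if (n_events < min_events) abort(sprintf("Need >= %d events; have %d.", min_events, n_events))

  base <- tibble(beta = NA_real_, se = NA_real_, hr = NA_real_,
                 lr_statistic = 0, lr_p = 1, n = n, n_events = n_events,
                 degenerate = TRUE, adjusted = !is.null(adjust))
  if (var_or_zero(df$x) == 0 || n_events == 0) {
    base$beta <- 0
    return(base)
  }
  adj_terms <- setdiff(names(df), c("x", "time", "event"))
  rhs0 <- if (length(adj_terms) > 0) paste(adj_terms, collapse = " + ") else "1"
  f1 <- stats::as.formula(paste("survival::Surv(time, event) ~ x +", rhs0))
  f0 <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs0))
  fit1 <- tryCatch(
    suppressWarnings(survival::coxph(f1, data = df, ties = ties,
                                     control = survival::coxph.control(iter.max = 100))),
    error = function(e) NULL)
  if (is.null(fit1) || is.na(stats::coef(fit1)["x"])) return(base)
  loglik0 <- if (rhs0 == "1") {
    fit1$loglik[1] # unadjusted: the null partial likelihood needs no refit
  } else {
    fit0 <- suppressWarnings(
      survival::coxph(f0, data = df, ties = ties,
                      control = survival::coxph.control(iter.max = 100)))
    fit0$loglik[2]
  }
  lr <- max(0, 2 * (fit1$loglik[2] - loglik0))
  b <- unname(stats::coef(fit1)["x"])
  degen <- n_events == 0 || !is.finite(b) || abs(b) > 15
  tibble(beta = if (degen) NA_real_ else b,
         se = if (degen) NA_real_ else sqrt(diag(stats::vcov(fit1))[["x"]]),
         hr = if (degen) NA_real_ else exp(b),
         lr_statistic = lr, lr_p = pchisq(lr, df = 1, lower.tail = FALSE),
         n = n, n_events = n_events, degenerate = degen,
         adjusted = !is.null(adjust))
}

# per-patient covariate rows for survival screens: value at `tp` (or change
# tp - T1), joined to patient-level RFS / HR-status. TS-based screens are
# restricted to residual-disease patients with known RCB (RCB I/II/III).
patient_covariates <- function(expr, meta, tp, delta = FALSE) {
  m <- meta_for_expr(expr, meta)
  need <- if (delta) c("T1", tp) else tp
  pts <- patients_with(m, need)
  if (tp == "TS") {
    keep_rcb <- m$patient_id[m$rcb %in% c("RCB_I", "RCB_II", "RCB_III")]
    pts <- intersect(pts, unique(keep_rcb))
  }
  X <- timepoint_matrix(expr, m, tp, pts)
  if (delta) X <- X - timepoint_matrix(expr, m, "T1", pts)
  info <- m[match(pts, m$patient_id), c("patient_id", "hr_status", "rfs_time", "rfs_event")]
  list(X = X, info = info)
}

#' Per-gene Cox screen against recurrence-free survival
#'
#' Runs [cox_fit()] on every feature, with the covariate taken as the static
#' expression at one time point (`mode = "t1"` or `"ts"`) or the
#' within-patient change (`mode = "delta_ts"`, TS - T1). Screens based on
#' the surgical sample include only residual-disease patients with a
#' determinate RCB class (RCB I/II/III); pretreatment screens use all
#' patients with RFS data. Significance uses the relaxed raw threshold
#' `lr_p < p_threshold` (default 0.005) with no multiple-testing correction.
#'
#' @param expr Gene-level expression table.
#' @param meta Sample sheet with `rfs_time` / `rfs_event` (and `hr_status`
#'   when `adjust_hr = TRUE`).
#' @param mode `"t1"`, `"ts"` or `"delta_ts"`.
#' @param adjust_hr Adjust for hormone-receptor status (retained in both the
#'   full and the null model of the likelihood-ratio test).
#' @param p_threshold Raw likelihood-ratio p threshold.
#' @inheritParams cox_fit
#' @return A `serial_surv` tibble: per feature `beta`, `se`, `hr`,
#'   `lr_statistic`, `lr_p`, `significant`, `direction`
#'   (`"reduced_rfs"` when high expression raises the recurrence hazard,
#'   i.e. `beta > 0`, else `"increased_rfs"`), `n`, `n_events`.
#' @export
screen_rfs <- function(expr, meta, mode = c("t1", "ts", "delta_ts"),
                       adjust_hr = FALSE, p_threshold = 0.005,
                       ties = c("breslow", "efron")) {
  mode <- match.arg(mode)
  ties <- match.arg(ties)
  pc <- switch(mode,
               t1 = patient_covariates(expr, meta, "T1"),
               ts = patient_covariates(expr, meta, "TS"),
               delta_ts = patient_covariates(expr, meta, "TS", delta = TRUE))
  info <- pc$info
  usable <- !is.na(info$rfs_time) & !is.na(info$rfs_event)
  if (adjust_hr) usable <- usable & !is.na(info$hr_status)
  X <- pc$X[, usable, drop = FALSE]
  info <- info[usable, , drop = FALSE]
  adjust <- if (adjust_hr) tibble(hr_status = info$hr_status) else NULL

  rows <- purrr::map(rownames(X), function(g) {
    r <- tryCatch(
      cox_fit(X[g, ], info$rfs_time, info$rfs_event, adjust = adjust, ties = ties),
      error = function(e) tibble(beta = NA_real_, se = NA_real_, hr = NA_real_,
                                 lr_statistic = NA_real_, lr_p = NA_real_,
                                 n = NA_integer_, n_events = NA_integer_,
                                 degenerate = TRUE, adjusted = adjust_hr))
    dplyr::bind_cols(tibble(feature_id = g), r)
  })
  out <- dplyr::bind_rows(rows)
  out$significant <- !is.na(out$lr_p) & out$lr_p < p_threshold
  out$direction <- dplyr::if_else(out$beta > 0, "reduced_rfs", "increased_rfs",
                                  missing = NA_character_)
  out <- dplyr::relocate(out, "feature_id", "beta", "se", "hr",
                         "lr_statistic", "lr_p", "significant", "direction")
  structure(out, mode = mode, p_threshold = p_threshold,
            adjust_hr = adjust_hr, ties = ties,
            n_patients = nrow(info), n_events = sum(info$rfs_event),
            class = c("serial_surv", class(tibble())))
}

#' @method tidy serial_surv
#' @export
tidy.serial_surv <- function(x, ...) as_tibble(x)

#' @method glance serial_surv
#' @export
glance.serial_surv <- function(x, ...) {
  tibble(
    mode = attr(x, "mode"),
    n_features = nrow(x),
    n_significant = sum(x$significant, na.rm = TRUE),
    n_reduced_rfs = sum(x$significant & x$direction == "reduced_rfs", na.rm = TRUE),
    n_increased_rfs = sum(x$significant & x$direction == "increased_rfs", na.rm = TRUE),
    p_threshold = attr(x, "p_threshold"),
    adjust_hr = attr(x, "adjust_hr"),
    n_patients = attr(x, "n_patients"),
    n_events = attr(x, "n_events")
  )
}

#' Dichotomize a continuous marker at a tertile
#'
#' Splits values at the empirical tertile for Kaplan-Meier illustration:
#' `"top_vs_rest"` labels values strictly above the 2/3 quantile `"high"`;
#' `"bottom_vs_rest"` labels values strictly below the 1/3 quantile `"low"`;
#' everything else is `"rest"`. Quantiles use the linear-interpolation
#' definition (type 7), so the cut point is deterministic; ties at the cut
#' all fall on the `"rest"` side.
#'
#' @param values Numeric vector with >= 3 distinct values.
#' @param direction `"top_vs_rest"` or `"bottom_vs_rest"`.
#' @return Factor of labels, `"rest"` first (reference level).
#' @examples
#' dichotomize_tertile(1:9, "top_vs_rest") # 7,8,9 are "high"
#' @export
dichotomize_tertile <- function(values, direction = c("top_vs_rest", "bottom_vs_rest")) {
  direction <- match.arg(direction)
  v <- values[!is.na(values)]
  if (length(unique(v)) < 3) abort("Need >= 3 distinct values to form tertiles.")
  if (direction == "top_vs_rest") {
    cut <- quantile(v, 2 / 3, type = 7, names = FALSE)
    lab <- ifelse(values > cut, "high", "rest")
    factor(lab, levels = c("rest", "high"))
  } else {
    cut <- quantile(v, 1 / 3, type = 7, names = FALSE)
    lab <- ifelse(values < cut, "low", "rest")
    factor(lab, levels = c("rest", "low"))
  }
}

#' Kaplan-Meier estimate and two-group log-rank test
#'
#' `km_estimate()` computes the product-limit estimator (via
#' [survival::survfit()]), optionally per group; `logrank_test()` compares
#' groups with the standard log-rank statistic (hypergeometric variance,
#' [survival::survdiff()] with `rho = 0`).
#'
#' @param time,event Follow-up times and event indicators.
#' @param group Optional grouping factor.
#' @return `km_estimate()`: a `serial_km` tibble with `group`, `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`. `logrank_test()`: a one-row
#'   tibble `chi2`, `df`, `p`.
#' @export
km_estimate <- function(time, event, group = NULL) {
  df <- tibble(time = as.numeric(time), event = as.integer(event),
               group = if (is.null(group)) factor("all") else as.factor(group))
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) == 0 || any(table(df$group) == 0)) abort("Empty group in survival data.")
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  strata <- if (is.null(fit$strata)) {
    rep(levels(df$group)[1], length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  out <- tibble(group = strata, time = fit$time, n_risk = fit$n.risk,
                n_event = fit$n.event, n_censor = fit$n.censor, surv = fit$surv)
  structure(out, class = c("serial_km", class(tibble())))
}

#' @rdname km_estimate
#' @export
logrank_test <- function(time, event, group) {
  df <- tibble(time = as.numeric(time), event = as.integer(event),
               group = droplevels(as.factor(group)))
  df <- df[complete.cases(df), , drop = FALSE]
  if (nlevels(df$group) < 2 || any(table(df$group) == 0)) {
    abort("log-rank test needs >= 2 non-empty groups.")
  }
  if (sum(df$event) < 1) abort("log-rank test needs >= 1 event.")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df, rho = 0)
  df_test <- length(sd$n) - 1
  tibble(chi2 = unname(sd$chisq), df = df_test,
         p = pchisq(sd$chisq, df_test, lower.tail = FALSE))
}

#' Exact Wilcoxon signed-rank test for paired measurements
#'
#' Two-sided paired test (used, e.g., for pre- vs on-treatment Ki-67
#' scores). Zero differences are dropped; ranks of the absolute differences
#' use midranks for ties. For up to 20 nonzero differences the null
#' distribution of the positive-rank sum is enumerated exactly over all
#' `2^n` sign assignments (so ties are handled exactly); beyond that a
#' normal approximation with tie-corrected variance and continuity
#' correction is used.
#'
#' @param a,b Paired numeric vectors.
#' @param exact_max Largest n for exact enumeration (default 20).
#' @return A one-row tibble: `statistic` (positive-rank sum `V`), `p`,
#'   `n_nonzero`, `exact`.
#' @examples
#' wilcoxon_signed_rank(rep(0, 5), 1:5) # p = 2/32
#' @export
wilcoxon_signed_rank <- function(a, b, exact_max = 20) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  d <- (b - a)[ok]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(tibble(statistic = 0, p = 1, n_nonzero = 0L, exact = TRUE))
  }
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  if (n <= exact_max) {
    # distribution of the positive-rank sum over all 2^n sign assignments
    sums <- 0
    for (ri in r) sums <- c(sums, sums + ri)
    mu <- sum(r) / 2
    tail_count <- sum(abs(sums - mu) >= abs(v_obs - mu) - 1e-9)
    p <- min(1, tail_count / length(sums))
    tibble(statistic = v_obs, p = p, n_nonzero = as.integer(n), exact = TRUE)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (abs(v_obs - mu) - 0.5) / sqrt(sigma2)
    tibble(statistic = v_obs, p = min(1, 2 * pnorm(-max(z, 0))),
           n_nonzero = as.integer(n), exact = FALSE)
  }
}
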