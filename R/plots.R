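#' Volcano plot of a differential-expression contrast
#'
#' @param object A `serial_de` result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot serial_de
#' @export
autoplot.serial_de <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), !is.na(.data$p))
  pcol <- if (all(is.na(df$p_adj))) "p" else "p_adj"
  ggplot2::ggplot(df, ggplot2::aes(.data$mean_diff, -log10(.data[[pcol]]),
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Mean difference (log2 ratio)",
                  y = sprintf("-log10 %s", if (pcol == "p_adj") "adjusted p" else "p"),
                  title = attr(object, "contrast"),
                  subtitle = attr(object, "threshold_rule")) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves
#'
#' Step curves of the product-limit estimate, one per group.
#'
#' @param object A `serial_km` tibble from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot serial_km
#' @export
autoplot.serial_km <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::distinct(tibble(group = object$group, time = 0, surv = 1)),
    as_tibble(object)[c("group", "time", "surv")]
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$surv, colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Recurrence-free survival") +
    ggplot2::theme_minimal()
}

#' Subtype transition plot
#'
#' Tile plot of paired label-to-label transitions; the diagonal counts
#' concordant pairs.
#'
#' @param object A `subtype_concordance` from [concordance()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot subtype_concordance
#' @export
autoplot.subtype_concordance <- function(object, ...) {
  ggplot2::ggplot(object$transitions,
                  ggplot2::aes(.data$to, .data$from, fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "Later time point", y = "T1",
                  title = sprintf("Concordance %d%% (%d/%d pairs)",
                                  object$rate_percent, object$n_identical,
                                  object$n_pairs)) +
    ggplot2::theme_minimal()
}

#' Enrichment bar plot
#'
#' @param object An `enrich_result` from [enrich_all()].
#' @param top Number of top-ranked sets to show (default 15).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot enrich_result
#' @export
autoplot.enrich_result <- function(object, top = 15, ...) {
  df <- head(as_tibble(object), top)
  df$set <- factor(df$set, levels = rev(df$set))
  ggplot2::ggplot(df, ggplot2::aes(-log10(.data$p), .data$set,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "steelblue")) +
    ggplot2::labs(x = "-log10 p (Fisher exact, enrichment)", y = NULL) +
    ggplot2::theme_minimal()
}
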