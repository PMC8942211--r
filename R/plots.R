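# ggplot2 convenience views of the result tables. Display clipping of odds
# ratios to [0.05, 10] is presentation-only; stored results are never
# clipped.

#' Forest plot of a feature enrichment scan
#'
#' @param object An `idr_enrichment` tibble ([enrichment_scan()]).
#' @param or_limits Display clipping range for ORs and CIs on the log axis.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot idr_enrichment
autoplot.idr_enrichment <- function(object, or_limits = c(0.05, 10), ...) {
  labels <- attr(object, "labels") %||% c("class A", "class B")
  df <- object %>%
    filter(!.data$degenerate) %>%
    mutate(across(c("odds_ratio", "ci_low", "ci_high"),
                  ~ pmin(pmax(.x, or_limits[1]), or_limits[2])),
           call = factor(.data$call,
                         levels = c("class_a_enriched", "class_b_enriched",
                                    "none"),
                         labels = c(paste(labels[1], "feature"),
                                    paste(labels[2], "feature"),
                                    "not significant")),
           feature_class = stats::reorder(.data$feature_class,
                                          .data$odds_ratio))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$odds_ratio,
                                   y = .data$feature_class,
                                   colour = .data$call)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.3) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10(limits = or_limits) +
    ggplot2::scale_colour_manual(values = c("#E69F00", "#009E73", "grey60"),
                                 drop = FALSE) +
    ggplot2::labs(x = "odds ratio (95% CI)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar plot of permutation feature importance
#'
#' @param object An `idr_importance` tibble ([permutation_importance()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot idr_importance
autoplot.idr_importance <- function(object, ...) {
  df <- mutate(object,
               feature_class = stats::reorder(.data$feature_class,
                                              .data$mean_drop))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature_class,
                                   y = .data$mean_drop,
                                   fill = .data$important)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_drop - .data$sd_drop,
                                        ymax = .data$mean_drop + .data$sd_drop),
                           width = 0.3) +
    ggplot2::geom_hline(yintercept = 5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#CC3399",
                                          `FALSE` = "grey60")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "drop in average precision (pct points)",
                  fill = "important\n(>= 5 pts)") +
    ggplot2::theme_minimal()
}

#' Missense/synonymous ratio distributions by length stratum
#'
#' @param counts An `idr_burden` tibble ([region_variant_counts()]).
#' @return A ggplot (regions with undefined ratios are omitted).
#' @export
plot_burden_ratios <- function(counts) {
  df <- bind_rows(mutate(counts, stratum = factor("all")),
                  mutate(counts, stratum = .data$stratum)) %>%
    filter(!is.na(.data$mis_syn_ratio))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum,
                                   y = .data$mis_syn_ratio)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3, fill = "grey85") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "IDR length stratum",
                  y = expression(n[mis] / n[syn])) +
    ggplot2::theme_minimal()
}

#' Pathogenic vs population counts per region, with median thresholds
#'
#' The scatter behind the intolerance rule: for one mutation type, each
#' region's population count against its pathogenic count, the cohort median
#' thresholds, and the diagonal. Intolerant regions sit left of the vertical
#' median, above both the horizontal median and the diagonal.
#'
#' @param counts An `idr_burden` tibble.
#' @param thresholds Threshold tibble ([compute_thresholds()] or
#'   [reference_thresholds()]).
#' @param vtype Mutation type to plot.
#' @return A ggplot.
#' @export
plot_intolerance_scatter <- function(counts, thresholds,
                                     vtype = c("missense", "nonsense",
                                               "frameshift", "inframe")) {
  vtype <- match.arg(vtype)
  df <- tibble(n_pop = counts[[paste0("n_pop_", vtype)]],
               n_path = counts[[paste0("n_path_", vtype)]])
  th <- thresholds[thresholds$vtype == vtype, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_pop, y = .data$n_path)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = th$median_population,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = th$median_pathogenic,
                        linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = paste("population", vtype, "count"),
                  y = paste("pathogenic", vtype, "count")) +
    ggplot2::theme_minimal()
}
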