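#' Plot a gene-body metagene methylation profile
#'
#' @param profile tibble from [gene_body_profile()], optionally with an
#'   extra grouping column (e.g. `gene_set`) mapped to color.
#' @param color optional name of a grouping column.
#' @return A ggplot object.
#' @export
plot_gene_body_profile <- function(profile, color = NULL) {
  aes <- if (is.null(color)) {
    ggplot2::aes(x = .data$bin, y = .data$mean_meth)
  } else {
    ggplot2::aes(x = .data$bin, y = .data$mean_meth,
                 color = .data[[color]], group = .data[[color]])
  }
  ggplot2::ggplot(profile, aes) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "position in gene body (TSS → end, binned)",
                  y = "mean methylation") +
    ggplot2::theme_minimal()
}

#' Plot methylation change against expression change
#'
#' @param delta_table tibble with `delta_meth` and `lfc` columns (see
#'   [gene_region_delta()]); an optional `gene_set` column is mapped to
#'   color.
#' @return A ggplot object.
#' @export
plot_delta_correlation <- function(delta_table) {
  aes <- if ("gene_set" %in% names(delta_table)) {
    ggplot2::aes(x = .data$delta_meth, y = .data$lfc, color = .data$gene_set)
  } else {
    ggplot2::aes(x = .data$delta_meth, y = .data$lfc)
  }
  ggplot2::ggplot(delta_table, aes) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(x = "methylation change (tumor - normal)",
                  y = "expression log2 fold change") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a GRS fit
#'
#' Score distribution with the top-`k` genes highlighted and labelled.
#'
#' @param object a `grs_fit`.
#' @param k number of top genes to highlight (default 15).
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.grs_fit <- function(object, k = 15, ...) {
  scores <- arrange(object$scores, .data$rank)
  scores$top <- scores$rank <= k
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$rank, y = .data$grs,
                                       color = .data$top)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#d95f02", `FALSE` = "grey60")) +
    ggplot2::labs(x = "rank", y = "gene risk score") +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves of an activity stratification
#'
#' @param object an `activity_result` from [stratify_activity()].
#' @param ... unused.
#' @return A ggplot object with one step curve per activity group.
#' @exportS3Method ggplot2::autoplot
autoplot.activity_result <- function(object, ...) {
  curves <- object$activity %>%
    group_by(.data$group) %>%
    group_modify(~ {
      km <- km_estimate(.x)
      bind_rows(tibble(time = 0, n_risk = nrow(.x), n_event = 0L,
                       n_censor = 0L, survival = 1), km)
    }) %>%
    ungroup()
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$survival,
                                       color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "time (months)", y = "survival probability",
      subtitle = sprintf("log-rank p = %.3g", object$logrank$p_value)
    ) +
    ggplot2::theme_minimal()
}
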