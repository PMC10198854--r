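#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_point geom_hline
#'   geom_vline geom_tile geom_boxplot scale_fill_gradient2 labs theme_minimal
#' @export
ggplot2::autoplot

#' Kaplan-Meier curves
#'
#' @param object A `km_estimate`.
#' @param ... Unused.
#' @return A ggplot of the step survival curves per group.
#' @export
autoplot.km_estimate <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::summarise(object, time = 0, survival = 1, .by = "group"),
    object[, c("group", "time", "survival")]
  )
  ggplot(df, aes(x = .data$time, y = .data$survival, colour = .data$group)) +
    geom_step() +
    labs(x = "Time", y = "Survival probability", colour = NULL) +
    theme_minimal()
}

#' Interaction-screen overview
#'
#' Interaction coefficient d against -log10 p, coloured by class; genes left
#' of zero strengthen the protective TLS association, genes right of zero
#' weaken it.
#'
#' @param object A `tls_screen`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tls_screen <- function(object, ...) {
  df <- object[!is.na(object$class), , drop = FALSE]
  ggplot(df, aes(x = .data$d, y = -log10(.data$p_d), colour = .data$class)) +
    geom_point(alpha = 0.6) +
    geom_vline(xintercept = 0, linetype = "dashed") +
    labs(x = "interaction coefficient d", y = expression(-log[10]~p[d]),
         colour = NULL) +
    theme_minimal()
}

#' Cluster-profile heatmap
#'
#' Mean z-score of every TME parameter per cluster.
#'
#' @param object A `tme_profile` ([characterize_clusters()]).
#' @param ... Unused.
#' @return A ggplot tile map.
#' @export
autoplot.tme_profile <- function(object, ...) {
  ggplot(object$profile,
         aes(x = factor(.data$cluster), y = .data$parameter, fill = .data$mean_z)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B") +
    labs(x = "TME class", y = NULL, fill = "mean z") +
    theme_minimal()
}

#' Score distribution across groups
#'
#' Boxplots of a signature score per group, e.g. the TLS score across
#' CR/PR/SD/PD immunotherapy response groups.
#'
#' @param scores Score tibble (`sample_id`, `score`).
#' @param group_labels Tibble `sample_id`, `group`.
#' @return A ggplot.
#' @export
plot_score_by_group <- function(scores, group_labels) {
  df <- dplyr::inner_join(scores, group_labels, by = "sample_id")
  df <- df[!is.na(df$group), , drop = FALSE]
  ggplot(df, aes(x = .data$group, y = .data$score)) +
    geom_boxplot() +
    labs(x = NULL, y = "signature score") +
    theme_minimal()
}
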