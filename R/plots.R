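#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_col geom_point
#'   geom_hline scale_fill_gradient labs theme_minimal coord_fixed
#' @export
ggplot2::autoplot

#' Heatmap of a pairwise mutual-information matrix
#'
#' @param object An `mi_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mi_matrix <- function(object, ...) {
  long <- tidy(object)
  long2 <- dplyr::bind_rows(
    long,
    dplyr::rename(long, var_a = "var_b", var_b = "var_a")
  )
  ggplot(long2, aes(x = .data$var_a, y = .data$var_b, fill = .data$mi_bits)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "#08306b", name = "MI (bits)") +
    coord_fixed() +
    labs(x = NULL, y = NULL,
         title = "Pairwise mutual information",
         subtitle = "what a pairwise association network sees") +
    theme_minimal()
}

#' Intervention effect plot
#'
#' Change in log-odds per node after a soft (nudge) intervention.
#'
#' @param object An `effect_report` from [population_effect()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.effect_report <- function(object, ...) {
  iv <- attr(object, "intervention")
  ggplot(object, aes(x = .data$node, y = .data$delta_log_odds)) +
    geom_col(fill = "#2171b5") +
    geom_hline(yintercept = 0, linewidth = 0.3) +
    labs(x = NULL, y = expression(Delta ~ "log-odds"),
         title = paste0("Nudge on ", iv$node, " (delta = ", iv$delta, ")")) +
    theme_minimal()
}

#' Synergy-scan overview plot
#'
#' O-information against permutation significance for every candidate
#' triplet; synergistic discoveries sit in the lower-left (negative
#' O-information, small q).
#'
#' @param object A `synergy_scan` from [scan_synergy()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.synergy_scan <- function(object, ...) {
  cfg <- attr(object, "config")
  ggplot(object, aes(x = .data$o_information_bits,
                     y = -log10(.data$q_value),
                     colour = .data$significant)) +
    geom_point(alpha = 0.7) +
    geom_hline(yintercept = -log10(cfg$fdr_q %||% 0.15), linetype = 2) +
    labs(x = "O-information (bits)", y = expression(-log[10](q)),
         colour = "significant",
         title = "Candidate triplets: synergy vs. significance") +
    theme_minimal()
}
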