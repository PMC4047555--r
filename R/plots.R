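# ggplot2 views of evaluation results.

#' Plot the pooled ROC curve of an evaluation
#'
#' @param object A `som_eval` from [evaluate_som()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.som_eval <- function(object, ...) {
  m <- object$metrics
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv", colour = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("%s, depth %d, q = %d, j = %d", toupper(m$base),
                      m$depth, m$q, m$j),
      subtitle = sprintf("AUC %.3f | MCC %.3f | top-2 %.0f%%", m$auc, m$mcc, m$top2),
      x = "False positive rate", y = "True positive rate")
}

#' Plot a subsample-length scan
#'
#' MCC (and AUC) against the subsample length q; the RASCAL collapse towards
#' MCC 0 at large q is the signature to look for.
#'
#' @param object A `som_scan` from [scan_q()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.som_scan <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("mcc", "auc"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$q, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = "subsample length q", y = NULL,
                  title = sprintf("%s, depth %d, j = %d", toupper(object$base[1]),
                                  object$depth[1], object$j[1]))
}

#' Plot per-molecule ranked site probabilities
#'
#' @param ranked Output of [rank_sites()].
#' @param annotations Annotation tibble (to colour true SoMs).
#' @return A ggplot.
#' @export
plot_ranked_sites <- function(ranked, annotations) {
  flag <- map2(ranked$mol_id, ranked$members, function(id, mem) {
    som <- annotations$som_atoms[match(id, annotations$mol_id)][[1]]
    length(intersect(mem, som)) > 0L
  })
  df <- dplyr::mutate(ranked, is_som = unlist(flag))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$prob_som,
                                   colour = .data$is_som)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~mol_id) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "grey40"),
                                 name = "true SoM") +
    ggplot2::labs(x = "rank (1 = most likely SoM)", y = "SoM vote fraction")
}
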