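# ggplot2 displays for rankings and evaluation reports.

#' Plot an LWC ranking
#'
#' CCDF of the ranking scores on a log-scaled score axis: the flatter and
#' longer the staircase, the more distinct ranks the method assigns.
#'
#' @param object An `lwc_ranking` from [lwc()] or [centrality_ranking()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lwc_ranking <- function(object, ...) {
  curve <- ccdf_curve(object)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$score, y = .data$fraction)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "score threshold", y = "fraction of nodes with score ≥ s",
                  title = "CCDF of ranking scores") +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report
#'
#' @param object An `lwc_evaluation` from [evaluate_methods()].
#' @param type Which panel to draw: `"ccdf"` (per-method score CCDFs,
#'   scores rescaled to ranks so methods are comparable),
#'   `"imprecision"` (eps(p) against p), or `"jaccard"` (top-k Jaccard
#'   against k).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lwc_evaluation <- function(object, type = c("ccdf", "imprecision",
                                                     "jaccard"), ...) {
  type <- match.arg(type)
  th <- ggplot2::theme_minimal()
  switch(type,
    ccdf = {
      d <- dplyr::mutate(
        dplyr::group_by(object$ccdf, .data$method),
        rank_fraction = dplyr::row_number() / dplyr::n()
      )
      ggplot2::ggplot(d, ggplot2::aes(x = .data$rank_fraction,
                                      y = .data$fraction,
                                      colour = .data$method)) +
        ggplot2::geom_step() +
        ggplot2::labs(x = "distinct-score quantile", y = "CCDF",
                      title = "Rank discrimination per method") + th
    },
    imprecision = ggplot2::ggplot(object$imprecision,
                                  ggplot2::aes(x = .data$p,
                                               y = .data$imprecision,
                                               colour = .data$method)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "p (fraction of top nodes)", y = "imprecision ε(p)",
                    title = "Imprecision of top-p node sets") + th,
    jaccard = ggplot2::ggplot(object$jaccard,
                              ggplot2::aes(x = .data$top_t,
                                           y = .data$jaccard,
                                           colour = .data$method)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "T (top-set size)", y = "Jaccard J(T)",
                    title = "Top-T overlap with SIR ground truth") + th
  )
}
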