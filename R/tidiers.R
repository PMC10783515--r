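# Plot methods for result objects.

#' Plot a multilink profile
#'
#' Tile map of z-scores by multilink type `(S, R)`, with significantly
#' over-represented types outlined.
#'
#' @param object A `mux_profile` from [profile_subset()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mux_profile <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  dat$z_plot <- ifelse(is.finite(dat$z), dat$z, NA_real_)
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$S),
                                    y = factor(.data$R))) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$z_plot)) +
    ggplot2::geom_tile(
      data = dat[dat$significant, , drop = FALSE],
      fill = NA, colour = "black", linewidth = 0.8
    ) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", na.value = "grey85") +
    ggplot2::labs(x = "signaling component S", y = "regulatory component R",
                  fill = "z", title = unique(dat$subset_id)) +
    ggplot2::theme_minimal()
}

#' Plot crosstalk scores of ranked pathway pairs
#'
#' @param object A `mux_crosstalk` from [infer_crosstalk()].
#' @param top_n Show at most this many top-ranked pairs.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mux_crosstalk <- function(object, top_n = 20, ...) {
  dat <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$rank),
                       .data$rank <= top_n)
  dat$pair <- stats::reorder(paste0(dat$pathway_a, " → ", dat$pathway_b),
                             -dat$rank)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$score, y = .data$pair,
                                    fill = factor(.data$n_sig))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "crosstalk score", y = NULL,
                  fill = "significant\nmultilink types") +
    ggplot2::theme_minimal()
}

#' Precision-rank curve plot
#'
#' @param precision Tibble from [precision_at_rank()].
#' @return A ggplot object.
#' @export
plot_precision_rank <- function(precision) {
  ggplot2::ggplot(precision, ggplot2::aes(x = .data$k,
                                          y = .data$precision)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "rank", y = "precision among top k") +
    ggplot2::theme_minimal()
}
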