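#' Plot a sample of protein trajectories
#'
#' Protein level against time for up to `n_cells` cells, log-scaled y axis.
#'
#' @param trajectories Long-format tibble (`cell_id, time, value`).
#' @param n_cells Maximum number of cells shown (default 20).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(trajectories, n_cells = 20) {
  ids <- unique(trajectories$cell_id)
  sel <- trajectories[trajectories$cell_id %in% head(ids, n_cells), ]
  ggplot2::ggplot(sel, ggplot2::aes(.data$time, .data$value,
                                    group = .data$cell_id)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (time units)", y = "protein level (a.u.)")
}

#' @method autoplot prc1_corr
#' @export
autoplot.prc1_corr <- function(object, ...) {
  d <- tidy(object)
  d$var1 <- factor(d$var1, levels = rev(corr_variables))
  d$var2 <- factor(d$var2, levels = corr_variables)
  ggplot2::ggplot(d, ggplot2::aes(.data$var2, .data$var1, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r")
}

#' @method autoplot prc1_timepoint
#' @export
autoplot.prc1_timepoint <- function(object, ...) {
  relation <- attr(object, "relation")
  d <- as_tibble(unclass(object), .name_repair = "minimal")
  d$p <- as.numeric(rownames(object))
  d <- tidyr::pivot_longer(d, -"p", names_to = "q", values_to = "r")
  d$q <- as.numeric(d$q)
  lab <- if (identical(relation, "sib-sib")) c("sibling 1 cycle %", "sibling 2 cycle %")
         else c("parent cycle %", "progeny cycle %")
  ggplot2::ggplot(d, ggplot2::aes(.data$p, .data$q, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = lab[1], y = lab[2], fill = "r")
}

#' @method autoplot prc1_curves
#' @export
autoplot.prc1_curves <- function(object, ...) {
  d <- tidyr::pivot_longer(
    dplyr::select(as_tibble(object), "X0", "X1", "X2", "T1", "T2"),
    -"X0", names_to = "variable", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$X0, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "X0 (a.u.)", y = NULL)
}

#' @method autoplot prc1_iteration
#' @export
autoplot.prc1_iteration <- function(object, ...) {
  d <- tidyr::pivot_longer(as_tibble(object), c("X0", "X2"),
                           names_to = "variable", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$step, .data$value,
                                  linetype = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "protein level (a.u.)", linetype = NULL)
}

#' @method autoplot prc1_pedigree
#' @export
autoplot.prc1_pedigree <- function(object, ...) {
  d <- as_tibble(object)
  d$generation <- factor(d$generation)
  ggplot2::ggplot(d, ggplot2::aes(.data$generation, .data$T1 + .data$T2)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "generation", y = "cycle duration T1 + T2 (time units)")
}
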