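#' Plot methods
#'
#' `autoplot()` methods give the standard views of each result type:
#' wild-type vs depleted current for a screen, ratio vs initiation rate for
#' an alpha scan, per-codon density profiles for a simulation or a density
#' comparison.
#'
#' @param object a result object.
#' @param ... unused.
#' @return A ggplot object.
#' @name codonqueue-plots
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname codonqueue-plots
#' @export
autoplot.tasep_screen <- function(object, ...) {
  thr <- attr(object, "threshold")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$J_wt, y = .data$J_dep,
                               colour = .data$sensitive)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_abline(slope = thr, intercept = 0, linetype = 3, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "J wild-type (proteins/s)", y = "J depleted (proteins/s)",
                  colour = sprintf("ratio < %g", thr))
}

#' @rdname codonqueue-plots
#' @export
autoplot.alpha_scan <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$alpha, y = .data$ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ratio - .data$ratio_se,
                                        ymax = .data$ratio + .data$ratio_se),
                           width = 0) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "initiation rate alpha (1/s)",
                  y = "J depleted / J wild-type")
}

#' @rdname codonqueue-plots
#' @export
autoplot.density_compare <- function(object, ...) {
  ggplot2::ggplot(object$profiles,
                  ggplot2::aes(x = .data$codon_index, y = .data$rho,
                               colour = .data$condition)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~alpha_level,
                        labeller = ggplot2::label_both, ncol = 1) +
    ggplot2::labs(x = "codon", y = "A-site density rho")
}

#' @rdname codonqueue-plots
#' @export
autoplot.tasep_sim <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$codon_index, y = .data$rho)) +
    ggplot2::geom_col(width = 1, fill = "steelblue") +
    ggplot2::labs(x = "codon", y = "A-site density rho")
}
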