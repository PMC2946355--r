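#' Plot a CES surface
#'
#' Effective size against the last-class contribution `p5`, one line (or
#' tile fill) per death fraction `c5`. Infeasible grid points are omitted
#' from the drawing (they stay in the table).
#'
#' @param object A [ces_surface()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot salmon_ces_surface
#' @export
autoplot.salmon_ces_surface <- function(object, ...) {
  dat <- dplyr::filter(object, .data$feasible)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$p5, y = .data$Ne,
                                    colour = factor(.data$c5))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "contribution of last age class (p5)",
                  y = "coalescent effective size Ne",
                  colour = "c5") +
    ggplot2::theme_minimal()
}

#' Plot a coalescence-time sample
#'
#' Histogram of replicate pair coalescence times with the theoretical mean
#' marked.
#'
#' @param object A [simulate_pair_backward()] /
#'   [simulate_fluctuating_pair()] result.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coalescence_sample
#' @export
autoplot.coalescence_sample <- function(object, bins = 60, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$time_years)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = object$theory_years,
                        linetype = "dashed") +
    ggplot2::labs(x = "pair coalescence time (years)", y = "replicates") +
    ggplot2::theme_minimal()
}

#' Plot a per-block estimate comparison
#'
#' The classic three-estimator picture for a fluctuating series: arithmetic
#' (A) and harmonic (H) breeder estimators and the coalescent estimate (C)
#' per generation block.
#'
#' @param object A [compare_estimates()] table.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot salmon_estimates
#' @export
autoplot.salmon_estimates <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "block", "estimate_A",
                  "estimate_H", "estimate_C"),
    cols = dplyr::starts_with("estimate_"),
    names_to = "method", values_to = "Ne")
  long$method <- sub("estimate_", "", long$method)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$block, y = .data$Ne,
                                     colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "generation block", y = "effective size estimate",
                  colour = "method") +
    ggplot2::theme_minimal()
}
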