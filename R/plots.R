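#' Plot the potential at selected noise levels
#'
#' Curves of `V(m, xi)` for a set of noise values — the standard picture of a
#' symmetric well deepening into a double (or asymmetric) well as the
#' intrinsic noise drops through its critical values.
#'
#' @param model A [landau_model()].
#' @param xi Noise levels to draw.
#' @param m_range Range of `m` (default `c(-1.5, 1.5)`).
#' @param n Points per curve.
#' @return A ggplot object.
#' @export
plot_potential <- function(model, xi = c(0.8, 1, 1.2),
                           m_range = c(-1.5, 1.5), n = 400) {
  check_model(model)
  grid <- tidyr::expand_grid(
    xi = xi,
    m = seq(m_range[1], m_range[2], length.out = n)
  )
  grid$V <- potential(grid$m, grid$xi, model)
  ggplot2::ggplot(grid, ggplot2::aes(.data$m, .data$V,
                                     colour = factor(.data$xi))) +
    ggplot2::geom_line() +
    ggplot2::labs(colour = expression(xi), y = expression(V(m, xi))) +
    ggplot2::theme_minimal()
}

#' @describeIn equilibrium_branches Bifurcation diagram: branch curves over
#'   `xi`, solid for stable and dashed for unstable segments.
#' @param object A `landau_branches` tibble.
#' @param ... Unused.
#' @export
autoplot.landau_branches <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$xi, .data$m, group = .data$branch,
                               linetype = .data$stable)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::scale_linetype_manual(
      values = c(`TRUE` = "solid", `FALSE` = "dashed"),
      na.translate = FALSE, name = "stable"
    ) +
    ggplot2::labs(x = expression(xi), y = "m") +
    ggplot2::theme_minimal()
}

#' @describeIn simulate_path Trajectory plot: phase portrait in the
#'   `(m, xi)` plane (`type = "phase"`) or time series (`type = "time"`).
#' @param object A `landau_trajectory`.
#' @param type `"phase"` or `"time"`.
#' @param ... Unused.
#' @export
autoplot.landau_trajectory <- function(object, type = c("phase", "time"),
                                       ...) {
  type <- match.arg(type)
  df <- tibble::as_tibble(object)
  if (type == "phase") {
    ggplot2::ggplot(df, ggplot2::aes(.data$m, .data$xi)) +
      ggplot2::geom_path(alpha = 0.8) +
      ggplot2::labs(x = "m", y = expression(xi)) +
      ggplot2::theme_minimal()
  } else {
    long <- tidyr::pivot_longer(df, c("m", "xi"), names_to = "variable")
    ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y") +
      ggplot2::theme_minimal()
  }
}

#' @describeIn pdf_over_time Heatmap of `P(m, t)` over time.
#' @param object A `landau_density`.
#' @param ... Unused.
#' @export
autoplot.landau_density <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$t, .data$m,
                                       fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "t", y = "m", fill = "P(m, t)") +
    ggplot2::theme_minimal()
}

#' @describeIn quasi_potential Heatmap of the quasi-potential
#'   `Phi(m, t) = -ln P`; masked (never-visited) bins are blank.
#' @param object A `landau_quasipotential`.
#' @param ... Unused.
#' @export
autoplot.landau_quasipotential <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$t, .data$m, fill = .data$phi)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(direction = -1, na.value = "white") +
    ggplot2::labs(x = "t", y = "m", fill = expression(Phi)) +
    ggplot2::theme_minimal()
}
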