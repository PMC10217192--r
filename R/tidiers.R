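#' Tidy a critical-noise analysis
#'
#' @param x A `landau_critical` from [critical_noise()].
#' @param ... Unused.
#' @return A one-row tibble with `model`, `xi_c`, `xi_transition`,
#'   `xi_saddle`, `transition_order`.
#' @export
tidy.landau_critical <- function(x, ...) {
  tibble::tibble(
    model = x$model_name,
    xi_c = x$xi_c,
    xi_transition = x$xi_transition,
    xi_saddle = x$xi_saddle,
    transition_order = x$transition_order
  )
}

#' Tidy a Hopf-point result
#'
#' @param x A `landau_hopf` from [hopf_point()].
#' @param ... Unused.
#' @return A one-row tibble with `exists`, `Mc`, `branch`, `character`,
#'   `det_at_Mc`, `G`.
#' @export
tidy.landau_hopf <- function(x, ...) {
  tibble::tibble(
    exists = x$exists, Mc = x$Mc, branch = x$branch,
    character = x$character, det_at_Mc = x$det_at_Mc, G = x$G
  )
}

#' Tidy a Jacobian report
#'
#' @param x A `landau_jacobian` from [jacobian()].
#' @param ... Unused.
#' @return A one-row tibble with the state, trace, determinant, discriminant,
#'   eigenvalue components and the stability label.
#' @export
tidy.landau_jacobian <- function(x, ...) {
  tibble::tibble(
    m = x$m, xi = x$xi, trace = x$trace, det = x$det,
    discriminant = x$discriminant,
    re_lambda1 = Re(x$eigenvalues[1]), im_lambda1 = Im(x$eigenvalues[1]),
    re_lambda2 = Re(x$eigenvalues[2]), im_lambda2 = Im(x$eigenvalues[2]),
    label = classify_stability(x)
  )
}

#' Tidy a limit-cycle summary
#'
#' @param x A `landau_cycle` from [limit_cycle_summary()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.landau_cycle <- function(x, ...) {
  tibble::tibble(
    is_cycle = x$is_cycle, undetermined = x$undetermined,
    period = x$period, m_amplitude = x$m_amplitude,
    orientation = x$orientation %||% NA_character_,
    mean_m = x$mean_m, mean_xi = x$mean_xi, n_peaks = x$n_peaks
  )
}

#' Tidy a switching report
#'
#' @param x A `landau_switching` from [switching_report()].
#' @param ... Unused.
#' @return The dwell table: one row per basin visit (`label`, `enter`,
#'   `duration`).
#' @export
tidy.landau_switching <- function(x, ...) {
  x$dwell
}

#' @rdname tidy.landau_switching
#' @export
glance.landau_switching <- function(x, ...) {
  tibble::tibble(
    transitions = x$transitions,
    n_visits = nrow(x$dwell),
    n_basins_visited = length(unique(x$dwell$label))
  )
}

#' Tidy a stability report
#'
#' @param x A `landau_stability_report` from [run_stability()].
#' @param ... Unused.
#' @return The per-equilibrium classification table.
#' @export
tidy.landau_stability_report <- function(x, ...) {
  x$equilibria
}

#' @rdname tidy.landau_stability_report
#' @export
glance.landau_stability_report <- function(x, ...) {
  tibble::tibble(
    model = x$params$model$name,
    G = x$params$G, M = x$params$M,
    M_max = x$M_max,
    hopf_exists = x$hopf$exists,
    Mc = x$hopf$Mc
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
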