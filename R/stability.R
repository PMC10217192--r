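#' Jacobian of the coupled system at a state
#'
#' Linearization of the coupled dynamics
#' \eqn{\dot m = (1-\xi)m - \alpha m^2 - \beta m^3 - \gamma m^5},
#' \eqn{\dot\xi = G(m^2 - M^2)} at a state `(m, xi)`:
#' \deqn{J = \begin{pmatrix} (1-\xi) - 2\alpha m - 3\beta m^2 - 5\gamma m^4 &
#'   -m \\ 2 G m & 0 \end{pmatrix}.}
#' For the presets at the equilibria \eqn{E_\pm} this reproduces the
#' closed-form traces \eqn{-2M^2} (model 1), \eqn{2M^2 - 4M^4} (model 2) and
#' \eqn{\pm M - 2M^2} (model 3), with determinant \eqn{2 G M^2} in all cases.
#'
#' @param model A [landau_model()].
#' @param G,M Feedback parameters (`G >= 0`).
#' @param m,xi State at which to linearize.
#' @return An object of class `landau_jacobian`: list with the 2x2 `matrix`,
#'   `trace`, `det`, `discriminant` (`trace^2 - 4 det`) and the complex
#'   `eigenvalues`.
#' @examples
#' jacobian(landau_model("model1"), G = 0.6, M = 0.2, m = 0.2, xi = 0.96)
#' @export
jacobian <- function(model, G, M, m, xi) {
  check_model(model)
  check_feedback(G, M)
  check_scalar_finite(m, "m")
  check_scalar_finite(xi, "xi")
  J <- matrix(c(drift_dm(m, xi, model), 2 * G * m,
                -m, 0), nrow = 2)
  tr <- J[1, 1] + J[2, 2]
  dt <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  structure(
    list(matrix = J, trace = tr, det = dt,
         discriminant = tr^2 - 4 * dt,
         eigenvalues = trace_det_eigenvalues(tr, dt),
         m = m, xi = xi, G = G, M = M),
    class = "landau_jacobian"
  )
}

#' @export
print.landau_jacobian <- function(x, ...) {
  cat(sprintf("<landau_jacobian at (m = %g, xi = %g)>\n", x$m, x$xi))
  print(x$matrix)
  cat(sprintf("trace = %g, det = %g, eigenvalues = %s, %s\n",
              x$trace, x$det,
              format(x$eigenvalues[1]), format(x$eigenvalues[2])))
  invisible(x)
}

#' Eigenvalues of a 2x2 matrix from its trace and determinant
#'
#' \eqn{\lambda_{1,2} = [T \pm \sqrt{T^2 - 4\Delta}]/2}, returned as a complex
#' pair whose sum is the trace and product the determinant.
#'
#' @param trace,det Trace and determinant.
#' @return Complex vector of length 2 (largest real part first).
#' @export
trace_det_eigenvalues <- function(trace, det) {
  check_scalar_finite(trace, "trace")
  check_scalar_finite(det, "det")
  disc <- as.complex(trace^2 - 4 * det)
  s <- sqrt(disc)
  c((trace + s) / 2, (trace - s) / 2)
}

#' Classify a fixed point on the trace-determinant (Poincare) diagram
#'
#' Labels a 2-D linearization by the signs of the trace, determinant and
#' discriminant \eqn{T^2 - 4\Delta}, with a tolerance for the boundary cases:
#' `det < 0` is a saddle; `trace < 0, det > 0` is a stable node
#' (`disc > 0`), stable spiral (`disc < 0`) or stable degenerate node
#' (`disc = 0`); mirrored labels for `trace > 0`; `trace = 0, det > 0` is a
#' center candidate (non-hyperbolic linearization, Hopf suspect); `det = 0`
#' is non-hyperbolic.
#'
#' @param x A `landau_jacobian` (from [jacobian()]) or a numeric trace.
#' @param det Determinant (when `x` is numeric).
#' @param tol Sign tolerance for the boundary tests.
#' @return A single classification string.
#' @examples
#' classify_stability(jacobian(landau_model("model1"), 0.6, 0.2, 0.2, 0.96))
#' @export
classify_stability <- function(x, det = NULL, tol = 1e-10) {
  if (inherits(x, "landau_jacobian")) {
    tr <- x$trace
    dt <- x$det
  } else {
    check_scalar_finite(x, "trace")
    check_scalar_finite(det, "det")
    tr <- x
    dt <- det
  }
  if (dt < -tol) return("saddle")
  if (abs(dt) <= tol) return("nonhyperbolic")
  if (abs(tr) <= tol) return("center_candidate")
  disc <- tr^2 - 4 * dt
  side <- if (tr < 0) "stable" else "unstable"
  shape <- if (abs(disc) <= tol) {
    "degenerate_node"
  } else if (disc > 0) {
    "node"
  } else {
    "spiral"
  }
  paste(side, shape, sep = "_")
}

#' Stability report for the equilibria of the coupled system
#'
#' Evaluates the Jacobian at each equilibrium \eqn{E_\pm} and classifies it.
#'
#' @inheritParams equilibria
#' @param tol Sign tolerance passed to [classify_stability()].
#' @return A tibble with one row per equilibrium: `branch`, `m`, `xi`,
#'   `trace`, `det`, `discriminant`, `re_lambda1`, `im_lambda1`, `label`.
#' @export
equilibrium_report <- function(model, G, M, tol = 1e-10) {
  eq <- equilibria(model, G, M)
  purrr::pmap_dfr(eq, function(branch, m, xi) {
    J <- jacobian(model, G, M, m, xi)
    tibble::tibble(
      branch = branch, m = m, xi = xi,
      trace = J$trace, det = J$det, discriminant = J$discriminant,
      re_lambda1 = Re(J$eigenvalues[1]), im_lambda1 = Im(J$eigenvalues[1]),
      label = classify_stability(J, tol = tol)
    )
  })
}

# trace at the equilibrium on a branch, as a function of M:
# J11(E) = -alpha m - 2 beta m^2 - 4 gamma m^4 with m = +M (E_plus) or -M
equilibrium_trace <- function(M, model, branch = c("E_plus", "E_minus")) {
  branch <- match.arg(branch)
  m <- if (branch == "E_plus") M else -M
  -model$alpha * m - 2 * model$beta * m^2 - 4 * model$gamma * m^4
}

#' Locate a Hopf point of the feedback-coupled system
#'
#' Searches each equilibrium branch for a set-point value `Mc` in the
#' admissible range at which the Jacobian trace vanishes while the
#' determinant \eqn{2 G M^2} stays positive — the non-hyperbolicity condition
#' for a Hopf bifurcation, at which the equilibrium trades stability with a
#' limit cycle. Model 2 has \eqn{M_c = \sqrt 2/2} (root of
#' \eqn{2M^2 - 4M^4}), model 3 has \eqn{M_c = 1/2} on the \eqn{E_+} branch,
#' and model 1 (trace \eqn{-2M^2 < 0}) has none.
#'
#' The sub/supercritical character is not derived from a normal form; with
#' `detect_character = TRUE` it is determined empirically by deterministic
#' simulation on both sides of `Mc`: a small bounded orbit just below `Mc`
#' together with convergence to the equilibrium just above it is reported as
#' `"supercritical"`.
#'
#' @param model A [landau_model()].
#' @param G Feedback gain, `> 0`.
#' @param detect_character Run the two-sided simulation probe (adds a few
#'   seconds of compute).
#' @param delta Offset from `Mc` used by the probe.
#' @return An object of class `landau_hopf`: list with `exists`, `Mc`,
#'   `branch`, `character` (`"supercritical"`, `"subcritical"` or
#'   `"undetermined"`), `det_at_Mc`, `G`.
#' @examples
#' hopf_point(landau_model("model3"), G = 0.2)
#' @export
hopf_point <- function(model, G, detect_character = FALSE, delta = 0.02) {
  check_model(model)
  check_feedback(G, M = 0, require_positive_G = TRUE)
  M_hi <- min(admissible_M_max(model), 10)
  hits <- purrr::map_dfr(c("E_plus", "E_minus"), function(br) {
    Mc <- trace_zero_on_branch(model, br, M_hi)
    if (is.na(Mc)) return(tibble::tibble())
    tibble::tibble(branch = br, Mc = Mc)
  })
  if (nrow(hits) == 0) {
    return(structure(
      list(exists = FALSE, Mc = NA_real_, branch = NA_character_,
           character = "undetermined", det_at_Mc = NA_real_, G = G),
      class = "landau_hopf"
    ))
  }
  hits <- dplyr::arrange(hits, .data$Mc)
  Mc <- hits$Mc[1]
  branch <- hits$branch[1]
  if (nrow(hits) == 2 && abs(diff(hits$Mc)) < 1e-9) branch <- "E_both"
  det_at_Mc <- 2 * G * Mc^2
  stopifnot(det_at_Mc > 0)
  character <- "undetermined"
  if (detect_character) {
    character <- hopf_character(model, G, Mc,
                                branch = if (branch == "E_both") "E_plus" else branch,
                                delta = delta)
  }
  structure(
    list(exists = TRUE, Mc = Mc, branch = branch, character = character,
         det_at_Mc = det_at_Mc, G = G),
    class = "landau_hopf"
  )
}

#' @export
print.landau_hopf <- function(x, ...) {
  if (!x$exists) {
    cat("<landau_hopf> no Hopf point: equilibrium trace has no admissible zero\n")
  } else {
    cat(sprintf("<landau_hopf> Mc = %.8g on branch %s (det = %g > 0), character: %s\n",
                x$Mc, x$branch, x$det_at_Mc, x$character))
  }
  invisible(x)
}

# smallest positive zero of the equilibrium trace on (0, M_hi); NA if none
trace_zero_on_branch <- function(model, branch, M_hi, n_grid = 2048) {
  f <- function(M) equilibrium_trace(M, model, branch)
  grid <- seq(1e-6, M_hi - 1e-9, length.out = n_grid)
  vals <- f(grid)
  sgn <- sign(vals)
  flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  exact <- which(abs(vals) < 1e-14 & grid > 1e-5)
  roots <- grid[exact]
  for (i in flip) {
    r <- stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-13)$root
    roots <- c(roots, r)
  }
  roots <- roots[roots > 1e-5]
  if (length(roots) == 0) NA_real_ else min(roots)
}

# simulation probe for the Hopf character: small stable orbit below Mc and
# spiral convergence above Mc is the supercritical signature
hopf_character <- function(model, G, Mc, branch, delta = 0.02,
                           t_final = 800, dt = 1e-3) {
  probe <- function(M) {
    eq <- equilibria(model, G, M)
    eq <- eq[eq$branch == branch, ]
    traj <- simulate_path(model, G = G, M = M, sigma = 0,
                          m0 = eq$m + 0.05, xi0 = eq$xi,
                          t_final = t_final, dt = dt, record_stride = 20L)
    limit_cycle_summary(traj, transient_fraction = 0.6)
  }
  below <- probe(Mc - delta)
  above <- probe(Mc + delta)
  small_orbit_below <- isTRUE(below$is_cycle) && below$m_amplitude < 0.5
  converged_above <- !isTRUE(above$is_cycle) && above$m_amplitude < 1e-2
  if (small_orbit_below && converged_above) "supercritical"
  else if (!small_orbit_below && isTRUE(above$is_cycle)) "subcritical"
  else "undetermined"
}
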