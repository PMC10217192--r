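#' Equilibrium branches of the fixed-noise system
#'
#' With the feedback off and the intrinsic noise `xi` held fixed, the order
#' parameter relaxes on the potential alone: the equilibria are the real
#' roots of the drift polynomial
#' \eqn{m[(1-\xi) - \alpha m - \beta m^2 - \gamma m^4] = 0}, with stability
#' given by the sign of \eqn{\partial \dot m/\partial m}. For the presets the
#' non-trivial branches have the closed forms
#' \eqn{m_\pm = \pm\sqrt{1-\xi}} (model 1),
#' \eqn{m_\pm = \pm\sqrt{0.5 + \sqrt{1.25-\xi}}},
#' \eqn{\mu_\pm = \pm\sqrt{0.5 - \sqrt{1.25-\xi}}} (model 2) and
#' \eqn{m_\pm = 0.5 \pm \sqrt{1.25-\xi}} (model 3); roots found numerically
#' are labelled by matching against these.
#'
#' @param model A [landau_model()].
#' @param xi_grid Non-negative noise values at which to solve.
#' @param root_tol Tolerance for merging numerically coincident (double)
#'   roots and for marginal-stability detection.
#' @return A tibble of class `landau_branches` with columns `xi`, `branch`
#'   (`m0`, `m_plus`, `m_minus`, `mu_plus`, `mu_minus`, or `root_k` for
#'   custom coefficient sets), `m`, `stable` (logical; `NA` at a marginal
#'   double root).
#' @examples
#' equilibrium_branches(landau_model("model1"), xi_grid = c(0.75, 1.5))
#' @export
equilibrium_branches <- function(model, xi_grid, root_tol = 1e-7) {
  check_model(model)
  check_finite_vec(xi_grid, "xi_grid")
  if (length(xi_grid) == 0) rlang::abort("`xi_grid` must be non-empty")
  if (any(xi_grid < 0)) rlang::abort("`xi_grid` values must be >= 0")
  out <- purrr::map_dfr(xi_grid, function(xi) branch_rows(model, xi, root_tol))
  class(out) <- c("landau_branches", class(out))
  out
}

branch_rows <- function(model, xi, root_tol) {
  # non-trivial factor q(m) = (1-xi) - alpha m - beta m^2 - gamma m^4
  roots <- real_poly_roots(c(1 - xi, -model$alpha, -model$beta, 0, -model$gamma))
  roots <- roots[abs(roots) > root_tol]
  roots <- merge_close(sort(roots), tol = root_tol)
  ddm <- drift_dm(roots, xi, model)
  stable_nz <- ifelse(abs(ddm) < 1e-8, NA, ddm < 0)
  branch <- c("m0", label_branches(model, xi, roots, stable_nz))
  m <- c(0, roots)
  stable <- c(1 - xi < 0, stable_nz)
  tibble::tibble(xi = xi, branch = branch, m = m, stable = stable)
}

merge_close <- function(x, tol) {
  if (length(x) <= 1) return(x)
  keep <- c(TRUE, diff(x) > tol)
  x[keep]
}

# closed-form labels for the presets; generic root_k labels otherwise
label_branches <- function(model, xi, roots, stable) {
  if (length(roots) == 0) return(character(0))
  forms <- switch(model$name,
    model1 = if (xi <= 1) {
      c(m_plus = sqrt(1 - xi), m_minus = -sqrt(1 - xi))
    },
    model2 = {
      f <- NULL
      if (xi <= 1.25) {
        s <- sqrt(1.25 - xi)
        if (0.5 + s >= 0) f <- c(f, m_plus = sqrt(0.5 + s), m_minus = -sqrt(0.5 + s))
        if (0.5 - s >= 0) f <- c(f, mu_plus = sqrt(0.5 - s), mu_minus = -sqrt(0.5 - s))
      }
      f
    },
    model3 = if (xi <= 1.25) {
      c(m_plus = 0.5 + sqrt(1.25 - xi), m_minus = 0.5 - sqrt(1.25 - xi))
    },
    NULL
  )
  if (is.null(forms)) {
    return(sprintf("%s_%d", ifelse(is.na(stable), "fold",
                                   ifelse(stable, "m", "mu")),
                   seq_along(roots)))
  }
  vapply(roots, function(r) names(forms)[which.min(abs(forms - r))], "")
}

#' Critical noise values of the fixed-noise system
#'
#' Computes the bifurcation/phase-transition skeleton of the potential as the
#' intrinsic noise `xi` varies:
#' \describe{
#'   \item{`xi_c`}{loss of linear stability of the pluripotent state `m = 0`,
#'     the zero of \eqn{\partial \dot m/\partial m(0, \xi) = 1 - \xi}
#'     (so `xi_c = 1` for every coefficient set).}
#'   \item{`xi_saddle`}{saddle-node location: the `xi` at which a non-zero
#'     double root of the drift appears (`1.25` for models 2 and 3; absent
#'     for model 1).}
#'   \item{`xi_transition`}{phase-transition point: the `xi` at which a
#'     non-zero minimum of `V` becomes degenerate with `V(0) = 0`, obtained
#'     by eliminating the stationarity condition from `V = 0`. Evaluates to
#'     `19/16 = 1.1875` for model 2 and `11/9 = 1.2222...` for model 3; for
#'     model 1 the ground state moves continuously and the transition sits at
#'     `xi_c` itself.}
#'   \item{`transition_order`}{`"second"` when the ground-state branch leaves
#'     `m = 0` continuously (transition at `xi_c`), `"first"` when it jumps.}
#' }
#'
#' @param model A [landau_model()].
#' @return An object of class `landau_critical`: list with `xi_c`,
#'   `xi_transition`, `xi_saddle` (`NA` when absent), `transition_order`.
#' @examples
#' critical_noise(landau_model("model2"))
#' @export
critical_noise <- function(model) {
  check_model(model)
  xi_c <- stats::uniroot(function(x) drift_dm(0, x, model),
                         interval = c(-10, 10), tol = 1e-13)$root

  # saddle-node: drift and its m-derivative share a non-zero root, i.e.
  # q(m) = 0 and q'(m) = 0 with q the non-trivial drift factor
  m_cand <- real_poly_roots(c(-model$alpha, -2 * model$beta, 0, -4 * model$gamma))
  m_cand <- m_cand[abs(m_cand) > 1e-10]
  xi_saddle <- NA_real_
  if (length(m_cand) > 0) {
    xs <- xi_star(m_cand, model)
    xs <- xs[xs > xi_c + 1e-12]
    if (length(xs) > 0) xi_saddle <- max(xs)
  }

  # first-order transition: eliminate (1-xi) = alpha m + beta m^2 + gamma m^4
  # from V(m, xi) = 0, leaving -alpha/6 - beta/4 m - gamma/3 m^3 = 0
  m_tr <- real_poly_roots(c(-model$alpha / 6, -model$beta / 4, 0, -model$gamma / 3))
  m_tr <- m_tr[abs(m_tr) > 1e-10]
  xi_transition <- xi_c
  transition_order <- "second"
  if (length(m_tr) > 0) {
    cand <- tibble::tibble(m = m_tr, xi = xi_star(m_tr, model))
    # keep genuine degenerate minima above xi_c
    cand <- cand[cand$xi > xi_c + 1e-9 &
                   drift_dm(cand$m, cand$xi, model) < -1e-12 &
                   abs(potential(cand$m, cand$xi, model)) < 1e-9, ]
    if (nrow(cand) > 0) {
      xi_transition <- max(cand$xi)
      transition_order <- "first"
    }
  }
  structure(
    list(model_name = model$name, xi_c = xi_c,
         xi_transition = xi_transition, xi_saddle = xi_saddle,
         transition_order = transition_order),
    class = "landau_critical"
  )
}

#' @export
print.landau_critical <- function(x, ...) {
  cat(sprintf(
    "<landau_critical '%s'> xi_c = %g, xi_transition = %g (%s order), xi_saddle = %s\n",
    x$model_name, x$xi_c, x$xi_transition, x$transition_order,
    ifelse(is.na(x$xi_saddle), "none", format(x$xi_saddle))
  ))
  invisible(x)
}

#' Ground state(s) of the potential at fixed noise
#'
#' Argmin of `V(., xi)` over all stationary points; degenerate minima (ties
#' to within `tie_tol`) are all returned — at the first-order transition
#' point the pluripotent and differentiated states coexist.
#'
#' @param model A [landau_model()].
#' @param xi Noise level, `>= 0`.
#' @param tie_tol Energy tolerance for reporting ties.
#' @return Numeric vector of global-minimizer `m` values.
#' @examples
#' ground_state(landau_model("model2"), xi = 1.1)
#' @export
ground_state <- function(model, xi, tie_tol = 1e-9) {
  check_model(model)
  check_scalar_finite(xi, "xi")
  if (xi < 0) rlang::abort("`xi` must be >= 0")
  stat <- c(0, real_poly_roots(c(1 - xi, -model$alpha, -model$beta, 0,
                                 -model$gamma)))
  stat <- unique(stat)
  v <- potential(stat, xi, model)
  sort(stat[v <= min(v) + tie_tol])
}

#' Hysteresis sweep of the fixed-noise system
#'
#' Follows the occupied branch along a noise schedule: at each `xi` the order
#' parameter is relaxed to a stable equilibrium by damped gradient flow
#' started from the previously settled value (nudged by `eps` to either side
#' so that a branch that has just lost stability is actually left; a
#' symmetric tie at `m = 0` breaks toward `+`). Discontinuous jumps mark
#' branch terminations — the hysteresis loop interpreted as phenotypic
#' memory.
#'
#' @param model A [landau_model()].
#' @param xi_schedule Monotone (or piecewise monotone) vector of noise values.
#' @param m_init Starting order parameter.
#' @param eps Symmetry-breaking nudge applied before each relaxation. Must
#'   be large enough that the drift it induces on a freshly destabilized
#'   branch exceeds the relaxation tolerance, else departure is delayed past
#'   the true branch termination.
#' @param jump_tol Minimum `|dm|` between consecutive settled values reported
#'   as a jump; the default clears the steep square-root branch growth just
#'   below a pitchfork at the default schedule step.
#' @return A tibble with columns `xi`, `m` (settled value) and `jump`
#'   (logical: discontinuity relative to the previous schedule point).
#' @examples
#' hysteresis_sweep(landau_model("model1"), seq(1.2, 0.8, by = -0.05), 0)
#' @export
hysteresis_sweep <- function(model, xi_schedule, m_init,
                             eps = 1e-3, jump_tol = 0.1) {
  check_model(model)
  check_finite_vec(xi_schedule, "xi_schedule")
  if (length(xi_schedule) == 0) rlang::abort("`xi_schedule` must be non-empty")
  if (any(xi_schedule < 0)) rlang::abort("`xi_schedule` values must be >= 0")
  check_scalar_finite(m_init, "m_init")
  m_prev <- m_init
  settled <- numeric(length(xi_schedule))
  for (i in seq_along(xi_schedule)) {
    xi <- xi_schedule[i]
    up <- relax_fixed_xi(model, xi, m_prev + eps)
    dn <- relax_fixed_xi(model, xi, m_prev - eps)
    # nearest stable branch; symmetric tie broken toward +
    m_prev <- if (abs(up - m_prev) <= abs(dn - m_prev) + 1e-12) up else dn
    settled[i] <- m_prev
  }
  tibble::tibble(
    xi = xi_schedule,
    m = settled,
    jump = c(FALSE, abs(diff(settled)) > jump_tol)
  )
}

#' Relax the order parameter at fixed noise
#'
#' Damped gradient flow \eqn{\dot m = -\partial V/\partial m} integrated to a
#' steady state (`|drift| < tol`).
#'
#' @param model A [landau_model()].
#' @param xi Fixed noise level.
#' @param m0 Starting value.
#' @param dt Flow step.
#' @param tol Residual tolerance on the drift.
#' @param max_steps Iteration cap.
#' @return The settled `m` value.
#' @export
relax_fixed_xi <- function(model, xi, m0, dt = 0.01, tol = 1e-9,
                           max_steps = 1e7) {
  check_model(model)
  relax_fixed_xi_cpp(model$alpha, model$beta, model$gamma, xi, m0,
                     dt, tol, as.integer(max_steps))
}
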