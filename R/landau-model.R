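#' Specify a Landau free-energy model for a stem cell population
#'
#' Constructs the polynomial free-energy model
#' \deqn{V(m, \xi) = -\frac{1-\xi}{2} m^2 + \frac{\alpha}{3} m^3 +
#'       \frac{\beta}{4} m^4 + \frac{\gamma}{6} m^6,}
#' where `m` is the order parameter (the population-average cell state;
#' `m = 0` is pluripotent, `m != 0` differentiated) and `xi >= 0` plays the
#' role of temperature: the strength of intrinsic gene-expression noise.
#'
#' Three named presets cover the standard phenomenologies:
#' \describe{
#'   \item{`"model1"`}{`(alpha, beta, gamma) = (0, 1, 0)` — quartic double
#'     well; supercritical pitchfork and a second-order phase transition.}
#'   \item{`"model2"`}{`(0, -1, 1)` — sextic potential; double saddle-node
#'     bifurcation and a first-order transition with hysteresis.}
#'   \item{`"model3"`}{`(-1, 1, 0)` — asymmetric quartic; single saddle-node
#'     plus transcritical bifurcation and a first-order transition.}
#' }
#'
#' Arbitrary real coefficients are accepted provided the potential is bounded
#' below (`gamma > 0`, or `gamma == 0` with `beta > 0`); unbounded
#' combinations are rejected.
#'
#' @param model Either a preset name (`"model1"`, `"model2"`, `"model3"`) or
#'   `NULL` to use explicit coefficients.
#' @param alpha,beta,gamma Real coefficients of the cubic, quartic and sextic
#'   terms (ignored when a preset name is given).
#' @return An object of class `landau_model`: a list with elements `alpha`,
#'   `beta`, `gamma` and `name`.
#' @examples
#' landau_model("model2")
#' landau_model(alpha = 0, beta = 2, gamma = 0.5)
#' @export
landau_model <- function(model = NULL, alpha = 0, beta = 1, gamma = 0) {
  if (is.character(model)) {
    presets <- list(
      model1 = c(alpha = 0, beta = 1, gamma = 0),
      model2 = c(alpha = 0, beta = -1, gamma = 1),
      model3 = c(alpha = -1, beta = 1, gamma = 0)
    )
    if (!model %in% names(presets)) {
      rlang::abort(sprintf(
        "unknown preset '%s'; available presets: %s",
        model, paste(names(presets), collapse = ", ")
      ))
    }
    p <- presets[[model]]
    return(new_landau_model(p[["alpha"]], p[["beta"]], p[["gamma"]], model))
  }
  if (!is.null(model)) {
    rlang::abort("`model` must be a preset name or NULL")
  }
  new_landau_model(alpha, beta, gamma, "custom")
}

new_landau_model <- function(alpha, beta, gamma, name) {
  for (v in list(alpha, beta, gamma)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      rlang::abort("coefficients must be finite numeric scalars")
    }
  }
  if (gamma < 0) {
    rlang::abort("gamma must be >= 0: the sextic term would make the potential unbounded below")
  }
  if (gamma == 0 && beta <= 0) {
    rlang::abort(paste0(
      "potential unbounded below: with gamma = 0 the quartic coefficient ",
      "beta must be positive"
    ))
  }
  structure(
    list(alpha = as.numeric(alpha), beta = as.numeric(beta),
         gamma = as.numeric(gamma), name = name),
    class = "landau_model"
  )
}

#' @export
print.landau_model <- function(x, ...) {
  cat(sprintf(
    "<landau_model '%s'>  V(m, xi) = -(1-xi)/2 m^2 %+g/3 m^3 %+g/4 m^4 %+g/6 m^6\n",
    x$name, x$alpha, x$beta, x$gamma
  ))
  invisible(x)
}

is_landau_model <- function(x) inherits(x, "landau_model")

check_model <- function(model) {
  if (!is_landau_model(model)) {
    rlang::abort("`model` must be a landau_model object (see landau_model())")
  }
  invisible(model)
}

check_scalar_finite <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    rlang::abort(sprintf("`%s` must be a finite numeric scalar", name))
  }
  invisible(x)
}

check_finite_vec <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    rlang::abort(sprintf("`%s` must be finite numeric", name))
  }
  invisible(x)
}

#' Validate feedback control parameters
#'
#' The intrinsic noise evolves under the negative feedback
#' \eqn{d\xi_t = G (m_t^2 - M^2)\, dt}; `G` is the feedback gain and `M` the
#' set-point for the magnitude of the order parameter. `G = 0` (feedback off)
#' is allowed for fixed-noise runs; analyses that require a genuine feedback
#' loop (equilibria, Hopf detection) demand `G > 0`.
#'
#' @param G Feedback gain, `>= 0`.
#' @param M Set-point, `>= 0`.
#' @param require_positive_G Demand strictly positive gain.
#' @return Invisibly `TRUE`; aborts on invalid input.
#' @export
check_feedback <- function(G, M, require_positive_G = FALSE) {
  check_scalar_finite(G, "G")
  check_scalar_finite(M, "M")
  if (G < 0) rlang::abort("feedback gain `G` must be non-negative")
  if (require_positive_G && G <= 0) {
    rlang::abort("this analysis requires a strictly positive feedback gain `G`")
  }
  if (M < 0) rlang::abort("set-point `M` must be non-negative")
  invisible(TRUE)
}

#' Landau potential
#'
#' Evaluates the free-energy potential `V(m, xi)`; the order-parameter drift
#' is its negative gradient. Vectorised over `m` and `xi` (recycled).
#'
#' @param m Order parameter value(s).
#' @param xi Intrinsic noise value(s).
#' @param model A [landau_model()].
#' @return Numeric vector of potential values; `V(0, xi) = 0` for all `xi`.
#' @examples
#' potential(1, 0, landau_model("model1"))  # -0.25
#' @export
potential <- function(m, xi, model) {
  check_model(model)
  check_finite_vec(m, "m")
  check_finite_vec(xi, "xi")
  -(1 - xi) / 2 * m^2 + model$alpha / 3 * m^3 + model$beta / 4 * m^4 +
    model$gamma / 6 * m^6
}

#' Deterministic drift of the order parameter
#'
#' The gradient-descent drift \eqn{\dot m = -\partial V/\partial m =
#' (1-\xi) m - \alpha m^2 - \beta m^3 - \gamma m^5}. Vectorised.
#'
#' @inheritParams potential
#' @return Numeric vector of rates.
#' @examples
#' drift(0.5, 0.5, landau_model("model1"))  # 0.125
#' @export
drift <- function(m, xi, model) {
  check_model(model)
  check_finite_vec(m, "m")
  check_finite_vec(xi, "xi")
  (1 - xi) * m - model$alpha * m^2 - model$beta * m^3 - model$gamma * m^5
}

# d(drift)/dm, used for stability flags and linearization
drift_dm <- function(m, xi, model) {
  (1 - xi) - 2 * model$alpha * m - 3 * model$beta * m^2 -
    5 * model$gamma * m^4
}

#' Noise feedback rate
#'
#' Rate of change of the intrinsic noise, \eqn{G (m^2 - M^2)}: noise rises
#' when the order parameter overshoots the set-point `M` and falls below it,
#' closing a negative feedback loop on differentiation. Zero iff `|m| = M`.
#'
#' @param m Order parameter value(s).
#' @param G Feedback gain (`>= 0`).
#' @param M Set-point (`>= 0`).
#' @return Numeric vector of rates.
#' @export
feedback_rate <- function(m, G, M) {
  check_feedback(G, M)
  check_finite_vec(m, "m")
  G * (m^2 - M^2)
}

# Closed-form equilibrium noise level at m = +M / m = -M:
# drift(m, xi) = 0 at m != 0  <=>  1 - xi = alpha m + beta m^2 + gamma m^4.
xi_star <- function(m, model) {
  1 - model$alpha * m - model$beta * m^2 - model$gamma * m^4
}

#' Equilibria of the coupled order-parameter/noise system
#'
#' The feedback pins `|m| = M`, so the coupled system has the two equilibria
#' \eqn{E_\pm = (\pm M,\ \xi^*_\pm)} with
#' \eqn{\xi^*_\pm = 1 \mp \alpha M - \beta M^2 - \gamma M^4}. For the presets
#' this reduces to the closed forms \eqn{(\pm M, 1 - M^2)} (model 1),
#' \eqn{(\pm M, 1 + M^2 - M^4)} (model 2) and the asymmetric pair
#' \eqn{(\pm M, 1 \pm M - M^2)} (model 3). `M` must lie strictly below the
#' admissible bound ([admissible_M_max()]) so that both equilibrium noise
#' levels are non-negative.
#'
#' @param model A [landau_model()].
#' @param G Feedback gain, `> 0`.
#' @param M Set-point, in `[0, admissible_M_max(model))`.
#' @return A tibble with columns `branch` (`"E_plus"`, `"E_minus"`), `m`, `xi`.
#' @examples
#' equilibria(landau_model("model1"), G = 0.6, M = 0.2)
#' @export
equilibria <- function(model, G, M) {
  check_model(model)
  check_feedback(G, M, require_positive_G = TRUE)
  m_vals <- c(M, -M)
  xi_vals <- xi_star(m_vals, model)
  if (any(xi_vals < 0)) {
    bound <- admissible_M_max(model)
    rlang::abort(sprintf(
      paste0("M = %g gives a negative equilibrium noise level; ",
             "positivity of xi* requires M < %.6g"),
      M, bound
    ))
  }
  out <- tibble::tibble(
    branch = c("E_plus", "E_minus"),
    m = m_vals,
    xi = xi_vals
  )
  # closed form must satisfy both stationarity conditions exactly
  resid <- pmax(abs(drift(out$m, out$xi, model)),
                abs(feedback_rate(out$m, G, M)))
  stopifnot(all(resid < 1e-12 * max(1, abs(1 - out$xi))))
  out
}

#' Admissible range of the feedback set-point
#'
#' Upper bound on `M` for which every equilibrium's noise level
#' \eqn{\xi^*(M)} stays non-negative: the smallest positive root of
#' \eqn{\xi^*_\pm(M) = 0} across both branches. Evaluates to 1 for model 1,
#' \eqn{\sqrt{(1+\sqrt 5)/2} \approx 1.272} for model 2 and
#' \eqn{(\sqrt 5 - 1)/2 \approx 0.618} for model 3.
#'
#' @param model A [landau_model()].
#' @return The supremum of admissible `M` (a positive number), or `Inf` when
#'   no positive root exists.
#' @export
admissible_M_max <- function(model) {
  check_model(model)
  roots <- c(real_poly_roots(c(1, -model$alpha, -model$beta, 0, -model$gamma)),
             real_poly_roots(c(1, model$alpha, -model$beta, 0, -model$gamma)))
  roots <- roots[roots > 1e-12]
  if (length(roots) == 0) return(Inf)
  min(roots)
}

# real roots of sum(coef[k] x^(k-1)), trailing zero coefficients tolerated
real_poly_roots <- function(coefs, im_tol = 1e-8) {
  while (length(coefs) > 1 && coefs[length(coefs)] == 0) {
    coefs <- coefs[-length(coefs)]
  }
  if (length(coefs) <= 1) return(numeric(0))
  z <- polyroot(coefs)
  Re(z[abs(Im(z)) < im_tol])
}
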