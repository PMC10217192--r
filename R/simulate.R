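#' Single Euler--Maruyama step of the coupled system
#'
#' One explicit step of the stochastic dynamics:
#' \eqn{m' = m + \dot m\, dt + \sigma \sqrt{dt}\, z},
#' \eqn{\xi' = \xi + G(m^2 - M^2)\, dt}, with `z` a standard-normal draw.
#' Exposed mainly as the elementary contract behind [simulate_path()]; the
#' integration loops themselves run in compiled code.
#'
#' @param m,xi Current state.
#' @param model A [landau_model()].
#' @param G,M Feedback parameters.
#' @param dt Time step, `> 0`.
#' @param sigma Noise amplitude, `>= 0`.
#' @param z Standard-normal draw (ignored when `sigma = 0`).
#' @param xi_floor `"none"` or `"clamp"` (floor the updated noise at zero).
#' @return A tibble with one row and columns `m`, `xi`.
#' @export
step_em <- function(m, xi, model, G, M, dt, sigma = 0, z = 0,
                    xi_floor = c("none", "clamp")) {
  check_model(model)
  check_feedback(G, M)
  xi_floor <- match.arg(xi_floor)
  check_scalar_finite(m, "m")
  check_scalar_finite(xi, "xi")
  check_scalar_finite(dt, "dt")
  check_scalar_finite(sigma, "sigma")
  check_scalar_finite(z, "z")
  if (dt <= 0) rlang::abort("`dt` must be positive")
  if (sigma < 0) rlang::abort("`sigma` must be non-negative")
  m_new <- m + drift(m, xi, model) * dt + sigma * sqrt(dt) * z
  xi_new <- xi + feedback_rate(m, G, M) * dt
  if (xi_floor == "clamp" && xi_new < 0) xi_new <- 0
  if (!is.finite(m_new) || !is.finite(xi_new)) {
    rlang::abort("non-finite state after step")
  }
  tibble::tibble(m = m_new, xi = xi_new)
}

#' Simulate one trajectory of the self-regulated system
#'
#' Euler--Maruyama integration of the coupled order-parameter/noise dynamics
#' at fixed step `dt` (default `1e-3`). With `sigma = 0` this is the
#' deterministic flow; the default initial order parameter is offset to
#' `1e-3` because the line `m = 0` is invariant under the deterministic
#' dynamics and would never break symmetry.
#'
#' @param model A [landau_model()].
#' @param G,M Feedback parameters (`G >= 0`; `G = 0` switches the feedback
#'   off, holding `xi` fixed at `xi0`).
#' @param sigma Noise amplitude `>= 0`; the finite-size scaling
#'   [sigma_finite_size()] maps a population size to an amplitude.
#' @param m0,xi0 Initial state.
#' @param t_final Integration horizon (time units).
#' @param dt Step size, `> 0`.
#' @param record_stride Store every `record_stride`-th step (default 100,
#'   i.e. every 0.1 time units at the default `dt`).
#' @param seed Optional integer seed (`set.seed` is called when given).
#' @param xi_floor `"none"` (default; the drift stays well defined for
#'   `xi < 0`) or `"clamp"` (floor the noise at zero).
#' @return A tibble of class `landau_trajectory` with columns `t`, `m`, `xi`
#'   and the full configuration in `attr(, "config")`.
#' @examples
#' simulate_path(landau_model("model1"), G = 0.6, M = 0.2, t_final = 1)
#' @export
simulate_path <- function(model, G, M, sigma = 0, m0 = 1e-3, xi0 = 1.5,
                          t_final = 100, dt = 1e-3, record_stride = 100L,
                          seed = NULL, xi_floor = c("none", "clamp")) {
  check_model(model)
  check_feedback(G, M)
  xi_floor <- match.arg(xi_floor)
  check_scalar_finite(sigma, "sigma")
  check_scalar_finite(m0, "m0")
  check_scalar_finite(xi0, "xi0")
  check_scalar_finite(t_final, "t_final")
  check_scalar_finite(dt, "dt")
  if (dt <= 0) rlang::abort("`dt` must be positive")
  if (t_final < dt) rlang::abort("`t_final` must be at least one step `dt`")
  if (sigma < 0) rlang::abort("`sigma` must be non-negative")
  record_stride <- as.integer(record_stride)
  if (record_stride < 1) rlang::abort("`record_stride` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n_steps <- as.integer(round(t_final / dt))
  mat <- em_path_cpp(model$alpha, model$beta, model$gamma, G, M, sigma,
                     m0, xi0, dt, n_steps, record_stride,
                     xi_floor == "clamp")
  out <- tibble::tibble(t = mat[, 1], m = mat[, 2], xi = mat[, 3])
  attr(out, "config") <- list(
    model = model, G = G, M = M, sigma = sigma, m0 = m0, xi0 = xi0,
    t_final = t_final, dt = dt, record_stride = record_stride,
    seed = seed, xi_floor = xi_floor
  )
  class(out) <- c("landau_trajectory", class(out))
  out
}

#' Simulate an ensemble of independent trajectories
#'
#' Runs `n_traj` independent realizations of [simulate_path()]. Per-trajectory
#' seeds are drawn once from `master_seed`, so the ensemble is bitwise
#' reproducible and each trajectory can be regenerated in isolation from its
#' own recorded seed.
#'
#' @inheritParams simulate_path
#' @param n_traj Number of trajectories, `>= 1`.
#' @param master_seed Integer seed controlling the whole ensemble.
#' @param m0 Initial order parameter (default 0: the pluripotent state; with
#'   `sigma > 0` the noise term breaks the symmetry).
#' @return A tibble of class `landau_ensemble` with columns `traj`, `t`, `m`,
#'   `xi`; configuration and the per-trajectory seed table are stored in
#'   `attr(, "config")` and `attr(, "seeds")`.
#' @examples
#' simulate_ensemble(landau_model("model1"), G = 0.6, M = 0.2, sigma = 1e-4,
#'                   n_traj = 3, master_seed = 1, t_final = 1)
#' @export
simulate_ensemble <- function(model, G, M, sigma, n_traj, master_seed,
                              m0 = 0, xi0 = 1.5, t_final = 100, dt = 1e-3,
                              record_stride = 100L,
                              xi_floor = c("none", "clamp")) {
  xi_floor <- match.arg(xi_floor)
  n_traj <- as.integer(n_traj)
  if (is.na(n_traj) || n_traj < 1) rlang::abort("`n_traj` must be >= 1")
  check_scalar_finite(master_seed, "master_seed")
  set.seed(as.integer(master_seed))
  seeds <- sample.int(2147483646L, n_traj)
  out <- purrr::map_dfr(seq_len(n_traj), function(i) {
    traj <- simulate_path(model, G = G, M = M, sigma = sigma, m0 = m0,
                          xi0 = xi0, t_final = t_final, dt = dt,
                          record_stride = record_stride, seed = seeds[i],
                          xi_floor = xi_floor)
    dplyr::mutate(tibble::as_tibble(traj), traj = i, .before = 1)
  })
  attr(out, "config") <- list(
    model = model, G = G, M = M, sigma = sigma, m0 = m0, xi0 = xi0,
    t_final = t_final, dt = dt, record_stride = record_stride,
    n_traj = n_traj, master_seed = as.integer(master_seed),
    xi_floor = xi_floor
  )
  attr(out, "seeds") <- tibble::tibble(traj = seq_len(n_traj), seed = seeds)
  class(out) <- c("landau_ensemble", class(out))
  out
}

#' Finite-size noise amplitude
#'
#' Maps a population size `N` to the stochastic forcing amplitude
#' `sigma = c / sqrt(N)`: the fluctuations of an average over `N` cells decay
#' as the square root of the population size (the exponent is exposed through
#' `c` deliberately; see the methods vignette).
#'
#' @param N Population size, `> 0`.
#' @param c Scaling constant (default 1).
#' @return Noise amplitude `sigma`.
#' @export
sigma_finite_size <- function(N, c = 1) {
  check_scalar_finite(N, "N")
  check_scalar_finite(c, "c")
  if (N <= 0) rlang::abort("`N` must be positive")
  c / sqrt(N)
}
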