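# High-level reproducible runs: each bundles the analysis modules behind a
# single call, validates the configuration up front, and (optionally) writes
# self-describing text outputs.

#' Full stability report for a parameter set
#'
#' Aggregates the equilibrium, Jacobian, classification and Hopf analyses of
#' the feedback-coupled system at one `(G, M)` point. Deterministic.
#'
#' @param model A [landau_model()].
#' @param G Feedback gain, `> 0`.
#' @param M Set-point, inside the admissible range.
#' @param detect_character Passed to [hopf_point()].
#' @return An object of class `landau_stability_report`: list with `params`,
#'   `equilibria` (classification table from [equilibrium_report()]), `hopf`
#'   and the admissible bound `M_max`. Use [tidy()]/[glance()] or
#'   [write_report()] on it.
#' @examples
#' run_stability(landau_model("model1"), G = 0.6, M = 0.2)
#' @export
run_stability <- function(model, G, M, detect_character = FALSE) {
  check_model(model)
  check_feedback(G, M, require_positive_G = TRUE)
  M_max <- admissible_M_max(model)
  if (M >= M_max) {
    rlang::abort(sprintf(
      "M = %g outside the admissible range: positivity of the equilibrium noise requires M < %.6g",
      M, M_max
    ))
  }
  structure(
    list(
      params = list(model = model, G = G, M = M),
      equilibria = equilibrium_report(model, G, M),
      hopf = hopf_point(model, G, detect_character = detect_character),
      M_max = M_max
    ),
    class = "landau_stability_report"
  )
}

#' @export
print.landau_stability_report <- function(x, ...) {
  cat(sprintf("<landau_stability_report '%s'> G = %g, M = %g (admissible M < %.6g)\n",
              x$params$model$name, x$params$G, x$params$M, x$M_max))
  print(x$equilibria)
  print(x$hopf)
  invisible(x)
}

#' Fixed-noise bifurcation tables for a model
#'
#' Drives the static (feedback-off) analysis over a noise grid: equilibrium
#' branches with stability, the critical-noise set, and the ground state at
#' each grid value.
#'
#' @param model A [landau_model()].
#' @param xi_grid Noise grid (non-negative, non-empty).
#' @return A list with `branches` (tibble from [equilibrium_branches()]),
#'   `critical` (one-row tibble from [critical_noise()]), `ground_states`
#'   (tibble `xi`, `m` with one row per global minimizer).
#' @examples
#' run_bifurcation(landau_model("model2"), xi_grid = seq(0.8, 1.4, by = 0.1))
#' @export
run_bifurcation <- function(model, xi_grid) {
  check_model(model)
  branches <- equilibrium_branches(model, xi_grid)
  ground <- purrr::map_dfr(xi_grid, function(xi) {
    tibble::tibble(xi = xi, m = ground_state(model, xi))
  })
  list(
    branches = branches,
    critical = tidy(critical_noise(model)),
    ground_states = ground
  )
}

#' Simulate an ensemble and write its analysis products
#'
#' Runs [simulate_ensemble()] and the requested observables, writing
#' everything under `out_dir` as self-describing text files (JSON-headed TSV
#' plus a JSON report carrying all parameters, the master seed and the
#' package version). On error any partial output written during the call is
#' removed.
#'
#' @inheritParams simulate_ensemble
#' @param out_dir Output directory (created if needed).
#' @param analyses Subset of `c("density", "quasipotential", "fates")`.
#' @param radius Capture radius for fate fractions.
#' @param m_edges Histogram edges for the density grid.
#' @param t_nodes Density time nodes (default: every recorded time).
#' @return Invisibly, a list with the computed objects and the written file
#'   paths.
#' @export
run_simulation <- function(model, G, M, sigma, n_traj, master_seed,
                           out_dir,
                           analyses = c("density", "quasipotential", "fates"),
                           m0 = 0, xi0 = 1.5, t_final = 100, dt = 1e-3,
                           record_stride = 100L,
                           xi_floor = c("none", "clamp"),
                           radius = 0.1,
                           m_edges = seq(-1.5, 1.5, length.out = 202),
                           t_nodes = NULL) {
  check_model(model)
  analyses <- match.arg(analyses, several.ok = TRUE)
  xi_floor <- match.arg(xi_floor)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  result <- tryCatch({
    ens <- simulate_ensemble(model, G = G, M = M, sigma = sigma,
                             n_traj = n_traj, master_seed = master_seed,
                             m0 = m0, xi0 = xi0, t_final = t_final, dt = dt,
                             record_stride = record_stride,
                             xi_floor = xi_floor)
    files <- list()
    objects <- list(ensemble = ens)
    p <- file.path(out_dir, "ensemble.tsv")
    write_trajectory(ens, p)
    written <- c(written, p)
    files$ensemble <- p

    if (any(c("density", "quasipotential") %in% analyses)) {
      dens <- pdf_over_time(ens, t_nodes = t_nodes, m_edges = m_edges)
      objects$density <- dens
      if ("density" %in% analyses) {
        p <- file.path(out_dir, "density.tsv")
        write_density(dens, p)
        written <- c(written, p)
        files$density <- p
      }
      if ("quasipotential" %in% analyses) {
        qp <- quasi_potential(dens)
        objects$quasipotential <- qp
        p <- file.path(out_dir, "quasipotential.tsv")
        write_density(qp, p)
        written <- c(written, p)
        files$quasipotential <- p
      }
    }
    if ("fates" %in% analyses) {
      eq <- equilibria(model, G = max(G, 1e-12), M = M)
      fates <- fate_fractions(ens, eq, radius = radius)
      objects$fates <- fates
    } else {
      fates <- NULL
    }
    report <- list(
      schema = "landaucell_run_v1",
      package_version = as.character(utils::packageVersion("landaucell")),
      params = attr(ens, "config"),
      analyses = analyses,
      fates = fates,
      warnings = if (xi_floor == "none" && any(ens$xi < 0)) {
        "xi went negative during the run (floor policy 'none')"
      }
    )
    p <- file.path(out_dir, "report.json")
    write_report(report, p)
    written <- c(written, p)
    files$report <- p
    list(objects = objects, files = files)
  }, error = function(e) {
    unlink(written)
    rlang::abort(sprintf("run_simulation failed (partial outputs removed): %s",
                         conditionMessage(e)), parent = e)
  })
  invisible(result)
}
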