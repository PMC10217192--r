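#' Time-resolved probability density of the order parameter
#'
#' Histograms the order parameter across the trajectories of an ensemble at
#' each requested time node, normalized so that `sum(P * dm) = 1` at every
#' node — the time evolution of the population's cell-state distribution.
#'
#' @param ens A `landau_ensemble` from [simulate_ensemble()].
#' @param t_nodes Time nodes (must coincide with recorded times to within
#'   half a recording interval); default: all recorded times.
#' @param m_edges Histogram bin edges (default 201 uniform bins on
#'   `[-1.5, 1.5]`).
#' @return A tibble of class `landau_density` with columns `t`, `m` (bin
#'   midpoint) and `density`; bin edges kept in `attr(, "m_edges")`.
#' @export
pdf_over_time <- function(ens, t_nodes = NULL,
                          m_edges = seq(-1.5, 1.5, length.out = 202)) {
  if (!inherits(ens, "landau_ensemble")) {
    rlang::abort("`ens` must be a landau_ensemble (see simulate_ensemble())")
  }
  if (nrow(ens) == 0) rlang::abort("empty ensemble")
  check_finite_vec(m_edges, "m_edges")
  if (length(m_edges) < 2 || any(diff(m_edges) <= 0)) {
    rlang::abort("`m_edges` must be increasing with at least two edges")
  }
  rec_times <- sort(unique(ens$t))
  if (is.null(t_nodes)) {
    t_nodes <- rec_times
  } else {
    check_finite_vec(t_nodes, "t_nodes")
    stride_dt <- min(diff(rec_times))
    idx <- vapply(t_nodes, function(tt) which.min(abs(rec_times - tt)), 1L)
    if (any(abs(rec_times[idx] - t_nodes) > stride_dt / 2 + 1e-12)) {
      rlang::abort("`t_nodes` must fall within the recorded time range")
    }
    t_nodes <- rec_times[idx]
  }
  mids <- (m_edges[-1] + m_edges[-length(m_edges)]) / 2
  widths <- diff(m_edges)
  sub <- dplyr::filter(ens, .data$t %in% t_nodes)
  out <- sub |>
    dplyr::group_by(.data$t) |>
    dplyr::group_modify(function(d, key) {
      h <- graphics::hist(pmin(pmax(d$m, m_edges[1]), m_edges[length(m_edges)]),
                          breaks = m_edges, plot = FALSE)
      tibble::tibble(m = mids, density = h$counts / (nrow(d) * widths))
    }) |>
    dplyr::ungroup()
  attr(out, "m_edges") <- m_edges
  attr(out, "n_traj") <- length(unique(ens$traj))
  class(out) <- c("landau_density", class(out))
  out
}

#' Quasi-potential (Waddington landscape) from a density grid
#'
#' Reconstructs the effective epigenetic landscape as
#' \eqn{\Phi(m, t) = -\ln P(m, t)} on bins with positive density; empty bins
#' are masked (`NA`), never imputed, so the landscape shows only where the
#' ensemble has actually been.
#'
#' @param dens A `landau_density` from [pdf_over_time()].
#' @return A tibble of class `landau_quasipotential` with columns `t`, `m`,
#'   `density`, `phi`.
#' @export
quasi_potential <- function(dens) {
  if (!inherits(dens, "landau_density")) {
    rlang::abort("`dens` must come from pdf_over_time()")
  }
  out <- dplyr::mutate(
    tibble::as_tibble(dens),
    phi = dplyr::if_else(.data$density > 0, -log(.data$density), NA_real_)
  )
  attr(out, "m_edges") <- attr(dens, "m_edges")
  class(out) <- c("landau_quasipotential", class(out))
  out
}

#' Cell-fate fractions of an ensemble
#'
#' Fraction of trajectories that sit within `radius` (in `m`) of each
#' attractor at evaluation time `t_eval`; trajectories near no attractor are
#' `undecided`. Fractions sum to 1.
#'
#' @param ens A `landau_ensemble`.
#' @param attractors A data frame with columns `branch` and `m` (e.g. the
#'   output of [equilibria()]).
#' @param radius Capture radius in `m`, `> 0`.
#' @param t_eval Evaluation time (default: last recorded time).
#' @return A tibble with columns `label`, `n`, `fraction`.
#' @export
fate_fractions <- function(ens, attractors, radius = 0.1, t_eval = NULL) {
  if (!inherits(ens, "landau_ensemble")) {
    rlang::abort("`ens` must be a landau_ensemble")
  }
  stopifnot(is.data.frame(attractors),
            all(c("branch", "m") %in% names(attractors)))
  check_scalar_finite(radius, "radius")
  if (radius <= 0) rlang::abort("`radius` must be positive")
  rec_times <- sort(unique(ens$t))
  if (is.null(t_eval)) t_eval <- max(rec_times)
  check_scalar_finite(t_eval, "t_eval")
  t_use <- rec_times[which.min(abs(rec_times - t_eval))]
  final <- dplyr::filter(ens, .data$t == t_use)
  lab <- vapply(final$m, function(mv) {
    d <- abs(mv - attractors$m)
    if (min(d) <= radius) attractors$branch[which.min(d)] else "undecided"
  }, "")
  counts <- table(factor(lab, levels = c(attractors$branch, "undecided")))
  tibble::tibble(
    label = names(counts),
    n = as.integer(counts),
    fraction = as.numeric(counts) / nrow(final)
  )
}

# local maxima with a prominence rule: strictly higher than neighbours and
# exceeding the midline by `prom_frac` of the half peak-to-peak range
find_peaks <- function(x, prom_frac = 0.3) {
  n <- length(x)
  if (n < 3) return(integer(0))
  mid <- (max(x) + min(x)) / 2
  amp <- (max(x) - min(x)) / 2
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  idx[x[idx] > mid + prom_frac * amp]
}

#' Summarize a limit cycle from a trajectory
#'
#' Detects sustained oscillation after discarding a transient: a cycle is
#' reported when the post-transient oscillation amplitude in `m` exceeds
#' `amplitude_threshold` and successive maxima are regularly spaced
#' (coefficient of variation of the peak spacing below `period_cv_max`). The
#' period is the mean peak spacing; the orientation is the sign of the signed
#' area accumulated along the `(m, xi)` loop (positive = counterclockwise).
#' A decaying oscillation (a spiral still converging) also has regular peaks,
#' so a sustained cycle additionally requires the oscillation amplitude in
#' the second half of the analysis window to hold at least `decay_ratio_min`
#' of the first half's. Intended for deterministic (`sigma = 0`)
#' trajectories.
#'
#' @param traj A `landau_trajectory`.
#' @param transient_fraction Fraction of the horizon discarded before
#'   analysis, in `[0, 1)` (default 0.5).
#' @param amplitude_threshold Minimum half peak-to-peak amplitude in `m` to
#'   call a cycle (default `1e-3`).
#' @param period_cv_max Maximum coefficient of variation of peak spacings.
#' @param min_periods Minimum number of full periods required; fewer flags
#'   the result `undetermined`.
#' @param decay_ratio_min Minimum ratio of second-half to first-half
#'   amplitude for a sustained (non-decaying) oscillation.
#' @return An object of class `landau_cycle`: list with `is_cycle`,
#'   `undetermined`, `period`, `m_amplitude`, `orientation`, `mean_m`,
#'   `mean_xi`, `n_peaks`, `decay_ratio`.
#' @export
limit_cycle_summary <- function(traj, transient_fraction = 0.5,
                                amplitude_threshold = 1e-3,
                                period_cv_max = 0.05, min_periods = 5,
                                decay_ratio_min = 0.9) {
  if (!inherits(traj, "landau_trajectory")) {
    rlang::abort("`traj` must be a landau_trajectory")
  }
  check_scalar_finite(transient_fraction, "transient_fraction")
  if (transient_fraction < 0 || transient_fraction >= 1) {
    rlang::abort("`transient_fraction` must be in [0, 1)")
  }
  post <- dplyr::filter(tibble::as_tibble(traj),
                        .data$t >= transient_fraction * max(.data$t))
  amp <- (max(post$m) - min(post$m)) / 2
  halves <- split(post$m, post$t > (min(post$t) + max(post$t)) / 2)
  half_amp <- vapply(halves, function(v) (max(v) - min(v)) / 2, 1)
  decay_ratio <- if (half_amp[1] > 0) half_amp[2] / half_amp[1] else NA_real_
  base <- list(
    is_cycle = FALSE, undetermined = FALSE, period = NA_real_,
    m_amplitude = amp, orientation = NA_character_,
    mean_m = mean(post$m), mean_xi = mean(post$xi),
    n_peaks = 0L, decay_ratio = unname(decay_ratio)
  )
  if (amp < amplitude_threshold) {
    return(structure(base, class = "landau_cycle"))
  }
  pk <- find_peaks(post$m)
  base$n_peaks <- length(pk)
  if (length(pk) < min_periods + 1) {
    base$undetermined <- TRUE
    return(structure(base, class = "landau_cycle"))
  }
  spac <- diff(post$t[pk])
  period <- mean(spac)
  cv <- stats::sd(spac) / period
  # signed (shoelace) area of the (m, xi) path; positive = counterclockwise
  n <- nrow(post)
  area <- sum(post$m[-n] * post$xi[-1] - post$m[-1] * post$xi[-n]) / 2
  base$period <- period
  base$is_cycle <- cv < period_cv_max && decay_ratio >= decay_ratio_min
  base$orientation <- if (area > 0) "counterclockwise" else "clockwise"
  structure(base, class = "landau_cycle")
}

#' @export
print.landau_cycle <- function(x, ...) {
  if (x$undetermined) {
    cat("<landau_cycle> undetermined (trajectory shorter than the required number of periods)\n")
  } else if (!x$is_cycle) {
    cat(sprintf("<landau_cycle> no cycle (amplitude %.3g); mean point (%.4g, %.4g)\n",
                x$m_amplitude, x$mean_m, x$mean_xi))
  } else {
    cat(sprintf(
      "<landau_cycle> %s limit cycle: period %.4g, m-amplitude %.4g, mean point (%.4g, %.4g)\n",
      x$orientation, x$period, x$m_amplitude, x$mean_m, x$mean_xi))
  }
  invisible(x)
}

#' Basin intervals around attractor locations
#'
#' Builds disjoint labeled `m`-intervals centred on attractor positions, with
#' half-width a fraction of the smallest spacing between neighbouring
#' attractors — the capture bands used by [switching_report()].
#'
#' @param centers Named numeric vector of attractor `m`-positions (names
#'   become labels).
#' @param half_width Interval half-width; default `0.3 *` minimum spacing.
#' @return A tibble with columns `label`, `lo`, `hi`.
#' @examples
#' basin_intervals(c(m0 = 0, m_plus = 0.9))
#' @export
basin_intervals <- function(centers, half_width = NULL) {
  check_finite_vec(centers, "centers")
  if (is.null(names(centers)) || any(names(centers) == "")) {
    rlang::abort("`centers` must be a named vector")
  }
  cs <- sort(centers)
  if (is.null(half_width)) {
    if (length(cs) < 2) rlang::abort("provide `half_width` for a single basin")
    half_width <- 0.3 * min(diff(cs))
  }
  check_scalar_finite(half_width, "half_width")
  if (half_width <= 0) rlang::abort("`half_width` must be positive")
  if (length(cs) > 1 && half_width >= min(diff(cs)) / 2) {
    rlang::abort("`half_width` too large: basins would overlap")
  }
  tibble::tibble(label = names(cs), lo = unname(cs) - half_width,
                 hi = unname(cs) + half_width)
}

#' Basin occupancy and switching statistics of a trajectory
#'
#' Assigns each recorded time to a basin with hysteretic (Schmitt-trigger)
#' labeling: the label changes only when the trajectory *enters* a new
#' interval, so excursions through unlabeled gaps do not chatter. Reports the
#' label sequence, the number of transitions, and per-visit dwell times —
#' the raw material of noise-induced phenotype-switching statistics.
#'
#' @param traj A `landau_trajectory`.
#' @param basins A data frame with columns `label`, `lo`, `hi` (disjoint
#'   intervals), e.g. from [basin_intervals()].
#' @return An object of class `landau_switching`: list with `labels` (tibble
#'   `t`, `label`), `transitions` (count of label changes), `dwell` (tibble
#'   `label`, `enter`, `duration`, one row per completed or ongoing visit).
#' @export
switching_report <- function(traj, basins) {
  if (!inherits(traj, "landau_trajectory")) {
    rlang::abort("`traj` must be a landau_trajectory")
  }
  stopifnot(is.data.frame(basins),
            all(c("label", "lo", "hi") %in% names(basins)))
  b <- dplyr::arrange(tibble::as_tibble(basins), .data$lo)
  if (nrow(b) > 1 && any(b$lo[-1] < b$hi[-nrow(b)])) {
    rlang::abort("basin intervals must be disjoint")
  }
  inside <- rep(NA_character_, nrow(traj))
  for (i in seq_len(nrow(b))) {
    inside[traj$m >= b$lo[i] & traj$m <= b$hi[i]] <- b$label[i]
  }
  # hysteretic carry-forward of the last entered basin
  lab <- inside
  for (i in seq_along(lab)[-1]) {
    if (is.na(lab[i])) lab[i] <- lab[i - 1]
  }
  labels <- tibble::tibble(t = traj$t, label = lab)
  known <- !is.na(lab)
  transitions <- 0L
  dwell <- tibble::tibble(label = character(0), enter = numeric(0),
                          duration = numeric(0))
  if (any(known)) {
    lk <- lab[known]
    tk <- traj$t[known]
    r <- rle(lk)
    ends <- cumsum(r$lengths)
    starts <- c(1L, utils::head(ends, -1) + 1L)
    dt_rec <- if (length(tk) > 1) stats::median(diff(tk)) else 0
    dwell <- tibble::tibble(
      label = r$values,
      enter = tk[starts],
      duration = tk[ends] - tk[starts] + dt_rec
    )
    transitions <- length(r$values) - 1L
  }
  structure(
    list(labels = labels, transitions = transitions, dwell = dwell),
    class = "landau_switching"
  )
}

#' @export
print.landau_switching <- function(x, ...) {
  cat(sprintf("<landau_switching> %d transitions across %d basin visit(s)\n",
              x$transitions, nrow(x$dwell)))
  if (nrow(x$dwell) > 0) {
    agg <- dplyr::summarise(
      dplyr::group_by(x$dwell, .data$label),
      visits = dplyr::n(), mean_dwell = mean(.data$duration)
    )
    print(agg)
  }
  invisible(x)
}
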