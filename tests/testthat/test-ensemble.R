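# one moderate ensemble shared across the density/fate tests: the classic
# symmetry-breaking run (pluripotent start, high noise, weak finite-size
# forcing)
shared_ens <- simulate_ensemble(m1, G = 0.6, M = 0.2, sigma = 1e-4,
                                n_traj = 80, master_seed = 2, m0 = 0,
                                xi0 = 1.5, t_final = 150)

# a handcrafted ensemble whose states tile the bin centres uniformly
uniform_ensemble <- function(edges) {
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  out <- tibble::tibble(
    traj = seq_along(mids), t = 0, m = mids, xi = 1
  )
  class(out) <- c("landau_ensemble", class(out))
  out
}

test_that("time-resolved densities are normalized at every node", {
  dens <- pdf_over_time(shared_ens, t_nodes = c(5, 50, 100, 150))
  dm <- diff(attr(dens, "m_edges"))[1]
  tot <- dplyr::summarise(dplyr::group_by(dens, .data$t),
                          z = sum(.data$density) * dm)
  expect_equal(tot$z, rep(1, 4), tolerance = 1e-9)
})

test_that("the symmetry-breaking ensemble is unimodal early, bimodal late", {
  dens <- pdf_over_time(shared_ens, t_nodes = c(10, 150))
  early <- dplyr::filter(dens, .data$t == 10)
  expect_lt(abs(early$m[which.max(early$density)]), 0.05)
  late <- dplyr::filter(dens, .data$t == 150)
  pos <- dplyr::filter(late, .data$m > 0.1)
  neg <- dplyr::filter(late, .data$m < -0.1)
  expect_equal(pos$m[which.max(pos$density)], 0.2, tolerance = 0.05)
  expect_equal(neg$m[which.max(neg$density)], -0.2, tolerance = 0.05)
  # mass near the pluripotent state has drained away by the end
  expect_lt(sum(late$density[abs(late$m) < 0.05]), 0.05 * sum(late$density))
})

test_that("late-time density is symmetric within sampling error", {
  dens <- pdf_over_time(shared_ens, t_nodes = 150)
  dm <- diff(attr(dens, "m_edges"))[1]
  p_pos <- sum(dens$density[dens$m > 0]) * dm
  expect_lt(abs(p_pos - 0.5), 3 * sqrt(0.25 / 80))
})

test_that("quasi-potential is -log(P) with masking and argmin duality", {
  edges <- seq(-1.5, 1.5, length.out = 202)
  dens <- pdf_over_time(uniform_ensemble(edges), m_edges = edges)
  qp <- quasi_potential(dens)
  k <- length(edges) - 1
  dm <- diff(edges)[1]
  expect_equal(unique(round(qp$phi, 12)), round(log(k * dm), 12))

  qp2 <- quasi_potential(pdf_over_time(shared_ens, t_nodes = c(50, 150)))
  for (tt in unique(qp2$t)) {
    slice <- dplyr::filter(qp2, .data$t == tt)
    expect_true(anyNA(slice$phi))  # unvisited bins are masked
    expect_equal(slice$m[which.min(slice$phi)],
                 slice$m[which.max(slice$density)])
  }
  # late-time landscape has wells at both differentiated states
  late <- dplyr::filter(qp2, .data$t == 150, !is.na(.data$phi))
  expect_equal(late$m[which.min(late$phi[late$m > 0]) + sum(late$m <= 0)],
               0.2, tolerance = 0.05)
})

test_that("fate fractions split evenly for the symmetric model", {
  eq <- equilibria(m1, G = 0.6, M = 0.2)
  ff <- fate_fractions(shared_ens, eq, radius = 0.1)
  expect_equal(sum(ff$fraction), 1)
  expect_equal(ff$fraction[ff$label == "undecided"], 0)
  k <- ff$n[ff$label == "E_plus"]
  expect_lt(abs(k - 40), 3 * sqrt(80 * 0.25))
  bt <- stats::binom.test(k, 80, p = 0.5)
  expect_gt(bt$p.value, 0.01)
})

test_that("deterministic ensembles from identical starts share one fate", {
  ens <- simulate_ensemble(m1, G = 0.6, M = 0.2, sigma = 0, n_traj = 5,
                           master_seed = 1, m0 = 0.05, xi0 = 1.2,
                           t_final = 120)
  ff <- fate_fractions(ens, equilibria(m1, G = 0.6, M = 0.2), radius = 0.1)
  expect_equal(ff$fraction[ff$label == "E_plus"], 1)
})

test_that("model 3 noisy ensembles inevitably settle on the asymmetric E_minus", {
  # once noise kicks the oscillating state across m = 0 it is captured by the
  # only asymptotically stable point, E_minus, and cannot return
  ens <- simulate_ensemble(m3, G = 0.2, M = 0.35, sigma = 1e-3, n_traj = 30,
                           master_seed = 6, m0 = 0, xi0 = 1.5, t_final = 1500,
                           record_stride = 500L)
  ff <- fate_fractions(ens, equilibria(m3, G = 0.2, M = 0.35), radius = 0.15)
  expect_equal(ff$fraction[ff$label == "E_minus"], 1)
  expect_equal(ff$fraction[ff$label == "E_plus"], 0)
})

test_that("limit-cycle detection separates cycles from converged spirals", {
  lc <- limit_cycle_summary(
    simulate_path(m2, G = 0.05, M = 0.68, sigma = 0, m0 = 0.001, xi0 = 1.5,
                  t_final = 800, record_stride = 20L))
  expect_true(lc$is_cycle)
  expect_equal(lc$orientation, "counterclockwise")
  expect_gt(lc$m_amplitude, 0.1)
  sp <- limit_cycle_summary(
    simulate_path(m2, G = 0.05, M = 0.71, sigma = 0, m0 = 0.001, xi0 = 1.5,
                  t_final = 800, record_stride = 20L))
  expect_false(sp$is_cycle)
})

test_that("cycle orientation flips with the sign of the initial state", {
  lc_minus <- limit_cycle_summary(
    simulate_path(m2, G = 0.05, M = 0.68, sigma = 0, m0 = -0.001, xi0 = 1.5,
                  t_final = 800, record_stride = 20L))
  expect_true(lc_minus$is_cycle)
  expect_equal(lc_minus$orientation, "clockwise")
})

test_that("cycle period and amplitude are robust to dt and transient choices", {
  mk <- function(dt) {
    simulate_path(m2, G = 0.05, M = 0.68, sigma = 0, m0 = 0.001, xi0 = 1.5,
                  t_final = 800, dt = dt, record_stride = as.integer(0.02 / dt))
  }
  a <- limit_cycle_summary(mk(1e-3))
  b <- limit_cycle_summary(mk(5e-4))
  expect_lt(abs(a$period - b$period) / a$period, 0.02)
  expect_lt(abs(a$m_amplitude - b$m_amplitude) / a$m_amplitude, 0.02)
  c2 <- limit_cycle_summary(mk(1e-3), transient_fraction = 0.25)
  expect_lt(abs(a$period - c2$period) / a$period, 0.02)
  expect_lt(abs(a$m_amplitude - c2$m_amplitude) / a$m_amplitude, 0.02)
})

test_that("short trajectories come back undetermined rather than classified", {
  short <- simulate_path(m2, G = 0.05, M = 0.68, sigma = 0, m0 = 0.6,
                         xi0 = 1.17, t_final = 60, record_stride = 20L)
  res <- limit_cycle_summary(short, transient_fraction = 0.1)
  expect_true(res$undetermined)
  expect_false(res$is_cycle)
})

test_that("basin intervals are disjoint, labeled, and validated", {
  b <- basin_intervals(c(m0 = 0, m_plus = 1, m_minus = -1))
  expect_equal(b$hi - b$lo, rep(0.6, 3))
  expect_true(all(b$lo[-1] > b$hi[-3]))
  expect_error(basin_intervals(c(0, 1)), "named")
  expect_error(basin_intervals(c(a = 0, b = 1), half_width = 0.6), "overlap")
  expect_error(basin_intervals(c(a = 0)), "half_width")
})

test_that("large-amplitude model 3 cycle dwells longer at m0 than at m_plus", {
  traj <- simulate_path(m3, G = 0.2, M = 0.35, sigma = 0, m0 = 0.001,
                        xi0 = 1.5, t_final = 600, record_stride = 20L)
  expect_true(limit_cycle_summary(traj)$is_cycle)
  sw <- switching_report(traj, basin_intervals(c(m0 = 0, m_plus = 1)))
  dw <- dplyr::summarise(dplyr::group_by(tidy(sw), .data$label),
                         mean_dwell = mean(.data$duration))
  expect_gt(dw$mean_dwell[dw$label == "m0"],
            dw$mean_dwell[dw$label == "m_plus"])
  expect_gt(sw$transitions, 5)
})

test_that("stochastic forcing produces a hybrid three-state occupancy", {
  mp <- sqrt(0.5 + sqrt(0.25))
  traj <- simulate_path(m2, G = 0.05, M = 0.5, sigma = 1e-3, m0 = 0,
                        xi0 = 1.5, t_final = 3000, seed = 1,
                        record_stride = 200L)
  sw <- switching_report(traj,
                         basin_intervals(c(m0 = 0, m_plus = mp, m_minus = -mp)))
  visited <- unique(stats::na.omit(sw$labels$label))
  expect_setequal(visited, c("m0", "m_plus", "m_minus"))
  expect_gt(sw$transitions, 0)
})

test_that("strong forcing drives direct transitions between the two cycles", {
  traj <- simulate_path(m2, G = 0.05, M = 0.65, sigma = 1e-2, m0 = 0,
                        xi0 = 1.5, t_final = 3000, seed = 1,
                        record_stride = 200L)
  sw <- switching_report(traj, basin_intervals(c(lc_plus = 0.65,
                                                 lc_minus = -0.65)))
  expect_gt(sw$transitions, 0)
})

test_that("dwell times account for the full labeled duration", {
  traj <- simulate_path(m3, G = 0.2, M = 0.35, sigma = 0, m0 = 0.001,
                        xi0 = 1.5, t_final = 300, record_stride = 20L)
  sw <- switching_report(traj, basin_intervals(c(m0 = 0, m_plus = 1)))
  first_labeled <- min(sw$labels$t[!is.na(sw$labels$label)])
  labeled_span <- max(traj$t) - first_labeled
  expect_equal(sum(sw$dwell$duration), labeled_span,
               tolerance = 0.05 * labeled_span)
})
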