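test_that("Jacobian at equilibria reproduces the closed-form trace and det", {
  for (M in c(0.2, 0.4, 0.7)) {
    G <- 0.1
    eq <- equilibria(m1, G, M)
    J <- jacobian(m1, G, M, eq$m[1], eq$xi[1])
    expect_equal(J$trace, -2 * M^2)
    expect_equal(J$det, 2 * G * M^2)
  }
  for (M in c(0.3, 0.68, 0.71)) {
    G <- 0.05
    eq <- equilibria(m2, G, M)
    J <- jacobian(m2, G, M, eq$m[1], eq$xi[1])
    expect_equal(J$trace, 2 * M^2 - 4 * M^4)
    expect_equal(J$det, 2 * G * M^2)
  }
  # model 3 is asymmetric: E_plus trace M - 2M^2, E_minus trace -M - 2M^2
  M <- 0.35; G <- 0.2
  eq <- equilibria(m3, G, M)
  Jp <- jacobian(m3, G, M, M, eq$xi[eq$branch == "E_plus"])
  Jm <- jacobian(m3, G, M, -M, eq$xi[eq$branch == "E_minus"])
  expect_equal(Jp$trace, M - 2 * M^2)
  expect_equal(Jm$trace, -M - 2 * M^2)
})

test_that("Jacobian structure holds at arbitrary states, including m = 0", {
  J <- jacobian(m2, G = 0.4, M = 0.3, m = 0, xi = 1.2)
  expect_equal(J$matrix, matrix(c(1 - 1.2, 0, 0, 0), 2))
  set.seed(5)
  for (i in 1:5) {
    model <- random_model()
    m <- runif(1, -1, 1); xi <- runif(1, 0, 1.5); G <- runif(1, 0.01, 1)
    J <- jacobian(model, G, 0.5, m, xi)
    h <- 1e-6
    expect_equal(J$matrix[1, 1],
                 (drift(m + h, xi, model) - drift(m - h, xi, model)) / (2 * h),
                 tolerance = 1e-5)
    expect_equal(J$matrix[1, 2], -m)
    expect_equal(J$matrix[2, 1], 2 * G * m)
    expect_equal(J$matrix[2, 2], 0)
  }
})

test_that("eigenvalues satisfy the quadratic relations and known cases", {
  ev <- trace_det_eigenvalues(0, 1)
  expect_equal(sort(Im(ev)), c(-1, 1))
  expect_equal(Re(ev), c(0, 0))
  # model 1, M = 0.4, G = 0.07: discriminant > 0, two real negative roots
  ev <- trace_det_eigenvalues(-0.32, 0.0224)
  expect_true(all(Im(ev) == 0))
  expect_true(all(Re(ev) < 0))
  # model 1, M = 0.2, G = 0.6: complex pair with negative real part
  ev <- trace_det_eigenvalues(-0.08, 0.048)
  expect_true(all(Im(ev) != 0))
  expect_true(all(Re(ev) < 0))
  set.seed(3)
  for (i in 1:50) {
    tr <- runif(1, -2, 2); dt <- runif(1, -1, 2)
    ev <- trace_det_eigenvalues(tr, dt)
    expect_equal(Re(sum(ev)), tr, tolerance = 1e-10)
    expect_equal(Re(prod(ev)), dt, tolerance = 1e-10)
  }
})

test_that("classification agrees with eigenvalue signs on random Jacobians", {
  set.seed(99)
  n_checked <- 0
  for (i in 1:10000) {
    tr <- runif(1, -3, 3)
    dt <- runif(1, -2, 3)
    lab <- classify_stability(tr, dt)
    ev <- eigen(matrix(c(tr, 1, -dt, 0), 2), only.values = TRUE)$values
    re <- Re(ev); im <- Im(ev)
    expected <- if (any(abs(re) < 1e-9)) {
      c("center_candidate", "nonhyperbolic")
    } else if (all(re < 0)) {
      if (all(im == 0)) c("stable_node", "stable_degenerate_node") else "stable_spiral"
    } else if (all(re > 0)) {
      if (all(im == 0)) c("unstable_node", "unstable_degenerate_node") else "unstable_spiral"
    } else {
      "saddle"
    }
    expect_in(lab, expected)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 10000)
})

test_that("model 1 equilibria classify as spiral or node at the canonical parameter sets", {
  rep1 <- equilibrium_report(m1, G = 0.6, M = 0.2)
  expect_equal(rep1$label, c("stable_spiral", "stable_spiral"))
  rep2 <- equilibrium_report(m1, G = 0.07, M = 0.4)
  expect_equal(rep2$label, c("stable_node", "stable_node"))
  # boundary case G = M^2/2 exactly
  rep3 <- equilibrium_report(m1, G = 0.02, M = 0.2)
  expect_equal(rep3$label, c("stable_degenerate_node", "stable_degenerate_node"))
})

test_that("model 1 spiral/node boundary over a (M, G) grid is G = M^2/2", {
  for (M in seq(0.1, 0.9, by = 0.1)) {
    crit <- M^2 / 2
    lab_lo <- equilibrium_report(m1, G = crit * 0.98, M = M)$label[1]
    lab_hi <- equilibrium_report(m1, G = crit * 1.02, M = M)$label[1]
    expect_equal(lab_lo, "stable_node")
    expect_equal(lab_hi, "stable_spiral")
  }
})

test_that("Hopf points land at the analytic critical set-points", {
  for (G in c(0.05, 0.2, 1)) {
    h2 <- hopf_point(m2, G)
    expect_true(h2$exists)
    expect_equal(h2$Mc, sqrt(2) / 2, tolerance = 1e-9)
    expect_gt(h2$det_at_Mc, 0)
    h3 <- hopf_point(m3, G)
    expect_true(h3$exists)
    expect_equal(h3$Mc, 0.5, tolerance = 1e-9)
    expect_equal(h3$branch, "E_plus")
    h1 <- hopf_point(m1, G)
    expect_false(h1$exists)
  }
})

test_that("eigenvalues are purely imaginary at the Hopf set-point", {
  for (model in list(m2, m3)) {
    G <- 0.1
    h <- hopf_point(model, G)
    eq <- equilibria(model, G, h$Mc)
    eq <- eq[eq$branch == ifelse(h$branch == "E_both", "E_plus", h$branch), ]
    J <- jacobian(model, G, h$Mc, eq$m, eq$xi)
    expect_lt(abs(Re(J$eigenvalues[1])), 1e-8)
    expect_gt(abs(Im(J$eigenvalues[1])), 0)
  }
})

test_that("admissible set-point bounds match the closed-form roots", {
  expect_equal(admissible_M_max(m1), 1, tolerance = 1e-9)
  expect_equal(admissible_M_max(m2), sqrt((1 + sqrt(5)) / 2), tolerance = 1e-9)
  expect_equal(admissible_M_max(m3), (sqrt(5) - 1) / 2, tolerance = 1e-9)
  # printed two/three-decimal values
  expect_equal(admissible_M_max(m2), 1.272, tolerance = 1e-3)
  expect_equal(admissible_M_max(m3), 0.618, tolerance = 1e-3)
})

test_that("Hopf character probe identifies the supercritical signature", {
  h <- hopf_point(m2, G = 0.05, detect_character = TRUE)
  expect_equal(h$character, "supercritical")
  h3 <- hopf_point(m3, G = 0.2, detect_character = TRUE)
  expect_equal(h3$character, "supercritical")
})

test_that("limit-cycle amplitude scales as sqrt(Mc - M) near the Hopf point", {
  # the square-root law is the normal-form asymptotic: it holds in the window
  # where the cycle is still small (Mc - M of order 1e-2 and below); farther
  # from onset the amplitude picks up strong higher-order corrections
  G <- 0.05
  Mc <- hopf_point(m2, G)$Mc
  deltas <- c(0.01, 0.005, 0.002, 0.001)
  amps <- vapply(deltas, function(d) {
    M <- Mc - d
    eq <- equilibria(m2, G, M)
    traj <- simulate_path(m2, G = G, M = M, sigma = 0,
                          m0 = M + 0.01, xi0 = eq$xi[1],
                          t_final = 3000 + 15 / d, dt = 1e-3,
                          record_stride = 100L)
    limit_cycle_summary(traj, transient_fraction = 0.75)$m_amplitude
  }, 1)
  expect_true(all(diff(amps) < 0))
  fit <- stats::lm(log(amps) ~ log(deltas))
  expect_lt(abs(unname(stats::coef(fit)[2]) - 0.5), 0.1)
})
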