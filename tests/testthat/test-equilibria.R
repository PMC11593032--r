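test_that("R0 reproduces the printed values", {
  expect_equal(reproduction_number(fig_params(30)), 0.75)
  expect_equal(reproduction_number(fig_params(50)), 1.25)
  expect_equal(reproduction_number(fig3_params(6)), 0.15)
  expect_equal(reproduction_number(realworld_params()), 5)
  p1 <- crime_params(alpha = 1, beta = 1, gamma = 1, delta = 1, eta = 1,
                     kappa = 1, rho = 1, sigma = 1, phi = 1)
  expect_equal(reproduction_number(p1), 1)
})

test_that("bifurcation thresholds match the printed case-4 values", {
  th <- bifurcation_thresholds(fig3_params(6))
  expect_identical(th$case, 4L)
  expect_equal(th$r, 0.18141, tolerance = 1e-5 / 0.18141)
  expect_equal(round(th$r1, 3), 0.071)
  expect_equal(round(th$r2, 3), 0.393)
  expect_equal(th$r1, th$r * th$r2)
  # r is maximized (= 1) when eta = rho * sigma
  th <- bifurcation_thresholds(fig_params(30, beta = 0, rho = 0.005))
  expect_equal(th$r, 1)
  # cases 1-2 have no r / r1 / r2
  th1 <- bifurcation_thresholds(fig_params(30))
  expect_true(is.na(th1$r) && is.na(th1$r1) && is.na(th1$r2))
  th2 <- bifurcation_thresholds(fig_params(30, beta = 30))
  expect_true(is.na(th2$r1) && is.na(th2$r2))
})

test_that("r2 <= 0 is reported as a missing bistability window", {
  # (beta/kappa)(1 + rho/delta) = 1 * (1 + 2) = 3 >= 1
  p <- crime_params(alpha = 1, beta = 2, gamma = 1, delta = 1, eta = 0.5,
                    kappa = 2, rho = 2, sigma = 3, phi = 0.5)
  th <- bifurcation_thresholds(p)
  expect_false(th$bistability_window)
  expect_true(is.na(th$r1) && is.na(th$r2))
  ca <- critical_alphas(p)
  expect_true(is.na(ca$saddle_node))
  expect_true(ca$no_bistability)
})

test_that("r stays below one over random positive (eta, rho, sigma) draws", {
  set.seed(3)
  for (i in 1:200) {
    p <- draw_params(sample(3:4, 1))
    expect_lte(bifurcation_thresholds(p)$r, 1)
  }
})

test_that("endemic quadratic roots reproduce the bistable-window geometry", {
  # alpha = 6: two positive roots, printed upper root 17.11
  rt <- endemic_roots(fig3_params(6))
  expect_equal(round(rt$G_plus, 2), 17.11)
  expect_equal(round(rt$G_minus, 2), 1.89)
  expect_equal(rt$A, 0.0075)
  expect_equal(rt$B, -0.1425)
  expect_equal(rt$const, 0.2425)
  # alpha = 2: R0 = 0.050 < r1, no real endemic state
  rt <- endemic_roots(fig3_params(2))
  expect_lt(rt$discriminant, 0)
  expect_true(is.na(rt$G_plus) && is.na(rt$G_minus))
  # at R0 = r2 exactly (H = 0): G_plus = -B/A, G_minus = 0
  th <- bifurcation_thresholds(fig3_params(6))
  alpha_r2 <- th$r2 * 10 * 8 / (0.1 * 20)
  rt <- endemic_roots(fig3_params(alpha_r2))
  expect_equal(rt$G_plus, -rt$B / rt$A, tolerance = 1e-10)
  expect_equal(rt$G_minus, 0, tolerance = 1e-8)
  # degenerate for rho = 0
  expect_error(endemic_roots(fig_params(30)), "rho > 0")
})

test_that("quadratic evaluates to zero at both returned roots", {
  set.seed(5)
  n_checked <- 0
  while (n_checked < 25) {
    p <- draw_params(sample(3:4, 1))
    rt <- endemic_roots(p)
    if (is.na(rt$G_plus)) next
    for (G in c(rt$G_plus, rt$G_minus)) {
      val <- rt$A * G^2 + rt$B * G + rt$const
      expect_lt(abs(val) / max(1, abs(rt$A * G^2)), 1e-10)
    }
    n_checked <- n_checked + 1
  }
})

test_that("closed-form equilibria reproduce the printed steady states", {
  # case 1, alpha = 50
  eqs <- crime_equilibria(fig_params(50))
  expect_named(eqs, c("E0", "E1"))
  expect_equal(unname(eqs$E0$coordinates), c(0, 100, 0, 0))
  expect_equal(unname(eqs$E1$coordinates), c(4, 100, 0, 64))
  expect_true(eqs$E1$physical)
  # case 4, alpha = 20 and alpha = 6 (printed to two decimals)
  eqs <- crime_equilibria(fig3_params(20))
  expect_equal(round(unname(eqs$E5$coordinates), 2), c(19.22, 4.94, 9.61, 15.40))
  eqs <- crime_equilibria(fig3_params(6))
  expect_equal(round(unname(eqs$E5$coordinates), 2), c(17.11, 5.52, 8.56, 15.31))
  # endemic C and J closed forms
  G5 <- eqs$E5$coordinates[["G"]]
  expect_equal(eqs$E5$coordinates[["C"]], 0.1 * G5 / 0.2)
  expect_equal(eqs$E5$coordinates[["J"]], 10 / (0.1 + 0.1 * G5))
  # total recidivism: the gang reaches carrying capacity despite honest judges
  eqs <- crime_equilibria(fig_params(30, beta = 50))
  expect_equal(eqs$E2$coordinates[["G"]], 20)
})

test_that("unphysical and complex equilibria are flagged, not dropped", {
  # alpha = 30 < 40: G1* < 0, retained for bifurcation sweeps
  eqs <- crime_equilibria(fig_params(30))
  expect_false(eqs$E1$physical)
  expect_lt(eqs$E1$coordinates[["G"]], 0)
  # complex endemic pair below the saddle-node
  eqs <- crime_equilibria(fig3_params(2))
  expect_false(eqs$E5$physical)
  expect_true(anyNA(eqs$E5$coordinates))
  expect_named(eqs, c("E0", "E5", "E6"))
})

test_that("setting beta to zero collapses case-4 formulas onto case 3", {
  p3 <- fig_params(6, beta = 0, rho = 0.1)
  p4 <- fig_params(6, beta = 1e-11, rho = 0.1)
  rt3 <- endemic_roots(p3)
  rt4 <- endemic_roots(p4)
  expect_equal(rt4$const, rt3$const, tolerance = 1e-9)
  expect_equal(rt4$G_plus, rt3$G_plus, tolerance = 1e-9)
  expect_equal(rt4$G_minus, rt3$G_minus, tolerance = 1e-9)
  th3 <- bifurcation_thresholds(p3)
  th4 <- bifurcation_thresholds(p4)
  expect_equal(th4$r2, 1, tolerance = 1e-9)
  expect_equal(th4$r1, th3$r, tolerance = 1e-9)
})

test_that("R0 elasticities are +/-1/0 and agree with finite differences", {
  p <- fig3_params(6)
  el <- r0_elasticity(p)
  expect_equal(el[c("alpha", "eta", "sigma")], c(alpha = 1, eta = 1, sigma = 1))
  expect_equal(el[c("gamma", "delta")], c(gamma = -1, delta = -1))
  expect_equal(el[c("beta", "kappa", "rho", "phi")],
               c(beta = 0, kappa = 0, rho = 0, phi = 0))
  # central finite differences of R0 itself
  set.seed(9)
  p <- draw_params(4)
  for (nm in names(el)) {
    h <- 1e-6 * p[[nm]]
    up <- p; up[[nm]] <- p[[nm]] + h
    dn <- p; dn[[nm]] <- p[[nm]] - h
    fd <- (reproduction_number(up) - reproduction_number(dn)) / (2 * h) *
      p[[nm]] / reproduction_number(p)
    expect_equal(unname(el[nm]), fd, tolerance = 1e-4)
  }
})
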