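test_that("numeric eigenvalues classify the printed regimes", {
  # below threshold (R0 = 0.75) the crime-free state is stable, with the
  # explicit eigenvalues (R0-1)gamma*delta/eta = -200, -eta = -0.1,
  # -gamma*phi/eta = -20 and -kappa = -50
  p <- fig_params(30)
  eqs <- crime_equilibria(p)
  rep0 <- stability_numeric(eqs$E0, p)
  expect_identical(rep0$verdict, "stable")
  ev <- sort(Re(rep0$eigenvalues))
  expect_equal(ev, c(-200, -50, -20, -0.1))
  # above threshold (R0 = 1.25) the crime-free state loses stability,
  # lambda1 = (R0-1)gamma*delta/eta = 0.25 * 800 = +200
  p <- fig_params(50)
  rep0 <- stability_numeric(crime_equilibria(p)$E0, p)
  expect_identical(rep0$verdict, "unstable")
  expect_equal(max(Re(rep0$eigenvalues)), 200)
  # the lower endemic state of the bistable window is a saddle
  p <- fig3_params(6)
  expect_identical(stability_numeric(crime_equilibria(p)$E6, p)$verdict,
                   "unstable")
  expect_identical(stability_numeric(crime_equilibria(p)$E5, p)$verdict,
                   "stable")
  expect_error(stability_numeric(crime_equilibria(fig3_params(2))$E5, p),
               "complex")
})

test_that("characteristic-polynomial coefficients follow the closed forms", {
  p <- fig3_params(6)
  eqs <- crime_equilibria(p)
  co5 <- charpoly_coefficients(eqs$E5, p)
  expect_true(co5$y1 > 0 && co5$y2 > 0 && co5$y3 > 0 && co5$delta > 0)
  expect_true(routh_hurwitz_cubic(co5$y1, co5$y2, co5$y3))
  # lower root: y3 < 0 alone forces instability
  co6 <- charpoly_coefficients(eqs$E6, p)
  expect_lt(co6$y3, 0)
  expect_false(routh_hurwitz_cubic(co6$y1, co6$y2, co6$y3))
  # case 2 endemic state: v2 = alpha kappa G2 > 0
  p2 <- fig_params(50, beta = 30)
  eqs2 <- crime_equilibria(p2)
  co2 <- charpoly_coefficients(eqs2$E2, p2)
  expect_equal(co2$v2, p2[["alpha"]] * p2[["kappa"]] * eqs2$E2$coordinates[["G"]])
  expect_gt(co2$v2, 0)
  # fully explicit case 1 is not served here
  expect_error(charpoly_coefficients(crime_equilibria(fig_params(30))$E0,
                                     fig_params(30)), "case 1")
})

test_that("Routh-Hurwitz cubic verdicts match brute-force root finding", {
  expect_true(routh_hurwitz_cubic(3, 3, 1))    # delta = 8 > 0
  expect_false(routh_hurwitz_cubic(1, 1, 2))   # delta = -1 < 0
  expect_false(routh_hurwitz_cubic(5, 5, -1))  # y3 < 0: a positive real root
  set.seed(13)
  for (i in 1:100) {
    y <- runif(3, -3, 5)
    roots <- polyroot(c(y[3], y[2], y[1], 1))
    expect_identical(routh_hurwitz_cubic(y[1], y[2], y[3]),
                     all(Re(roots) < 0))
  }
})

test_that("closed-form eigenvalues match the explicit case-1 formulas", {
  p <- fig_params(30)
  rep0 <- analytic_eigenvalues(crime_equilibria(p)$E0, p)
  expect_equal(sort(Re(rep0$eigenvalues)), c(-200, -50, -20, -0.1))
  expect_identical(rep0$verdict, "stable")
  # endemic state above threshold: lambda1 = (1-R0)gamma*delta/eta = -200
  p <- fig_params(50)
  rep1 <- analytic_eigenvalues(crime_equilibria(p)$E1, p)
  expect_equal(sort(Re(rep1$eigenvalues)), c(-200, -50, -20, -0.1))
  expect_identical(rep1$verdict, "stable")
  # case-3 endemic state carries the factors -phi*gamma/(eta+rho*G) and -kappa
  p <- fig_params(10, rho = 0.1)
  eqs <- crime_equilibria(p)
  G3 <- eqs$E3$coordinates[["G"]]
  ev <- Re(analytic_eigenvalues(eqs$E3, p)$eigenvalues)
  expect_true(any(abs(ev - (-0.2 * 10 / (0.1 + 0.1 * G3))) < 1e-10))
  expect_true(any(abs(ev - (-50)) < 1e-10))
})

test_that("analytic and numeric eigenvalue multisets coincide for cases 1-3", {
  set.seed(17)
  for (case in 1:3) {
    for (i in 1:10) {
      p <- draw_params(case)
      for (eq in crime_equilibria(p)) {
        if (anyNA(eq$coordinates)) next
        a <- sort(Re(analytic_eigenvalues(eq, p)$eigenvalues))
        n <- sort(Re(stability_numeric(eq, p)$eigenvalues))
        expect_equal(a, n, tolerance = 1e-8 / max(1, max(abs(n))))
      }
    }
  }
})

test_that("case-4 closed forms approach the numeric eigenvalues as rho, phi shrink", {
  # at rho = phi = 1e-6 the physical equilibria agree to 1e-4 absolute
  p <- fig_params(6, beta = 30, rho = 1e-6)
  p[["phi"]] <- 1e-6
  for (eq in crime_equilibria(p)) {
    if (!eq$physical) next
    rep_a <- analytic_eigenvalues(eq, p)
    expect_true(rep_a$analytic_regime_ok)
    a <- sort(Re(rep_a$eigenvalues))
    n <- sort(Re(stability_numeric(eq, p)$eigenvalues))
    expect_lt(max(abs(a - n)), 1e-4)
  }
  # and the discrepancy shrinks monotonically along rho = phi -> 0
  gap <- sapply(c(1e-4, 1e-5, 1e-6), function(sc) {
    p <- fig_params(6, beta = 30, rho = sc)
    p[["phi"]] <- sc
    eq <- crime_equilibria(p)$E5
    max(abs(sort(Re(analytic_eigenvalues(eq, p)$eigenvalues)) -
              sort(Re(stability_numeric(eq, p)$eigenvalues))))
  })
  expect_true(all(diff(gap) < 0))
  # outside the regime the report is flagged, and strict mode refuses
  p <- fig3_params(6)
  eq5 <- crime_equilibria(p)$E5
  expect_false(analytic_eigenvalues(eq5, p)$analytic_regime_ok)
  expect_error(analytic_eigenvalues(eq5, p, strict = TRUE), "rho <=")
})

test_that("crime-free and endemic states exchange stability across the transcritical point", {
  a_crit <- critical_alphas(fig_params(30))$transcritical
  below <- fig_params(a_crit * 0.99)
  above <- fig_params(a_crit * 1.01)
  v <- function(p, lab) stability_numeric(crime_equilibria(p)[[lab]], p)$verdict
  expect_identical(v(below, "E0"), "stable")
  expect_identical(v(below, "E1"), "unstable")
  expect_identical(v(above, "E0"), "unstable")
  expect_identical(v(above, "E1"), "stable")
})

test_that("the upper endemic state never satisfies the Hopf condition", {
  # delta = y1 y2 - y3 stays positive across random physical draws
  set.seed(23)
  found <- 0
  while (found < 30) {
    p <- draw_params(4)
    eqs <- crime_equilibria(p)
    if (!eqs$E5$physical || anyNA(eqs$E5$coordinates)) next
    co <- charpoly_coefficients(eqs$E5, p)
    expect_gt(co$delta, 0)
    found <- found + 1
  }
})

test_that("total recidivism makes the crime-free state unstable", {
  # beta = kappa, case 2 and case 4
  p2 <- fig_params(30, beta = 50)
  expect_identical(stability_numeric(crime_equilibria(p2)$E0, p2)$verdict,
                   "unstable")
  co <- charpoly_coefficients(crime_equilibria(p2)$E0, p2)
  expect_lt(co$u2, 0)
  p4 <- fig_params(30, beta = 50, rho = 0.1)
  expect_identical(stability_numeric(crime_equilibria(p4)$E0, p4)$verdict,
                   "unstable")
})
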