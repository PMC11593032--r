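eq_state <- function(eq) {
  if (inherits(eq, "crime_equilibrium")) {
    if (anyNA(eq$coordinates))
      stop("equilibrium '", eq$label, "' has complex/undefined coordinates; ",
           "stability is not defined", call. = FALSE)
    eq$coordinates
  } else as_state(eq)
}

eq_label <- function(eq) if (inherits(eq, "crime_equilibrium")) eq$label else "state"

new_stability_report <- function(eq, eigenvalues, method, eps,
                                 analytic_regime_ok = NA) {
  re <- Re(eigenvalues)
  verdict <- if (all(re < -eps)) "stable"
  else if (any(re > eps)) "unstable"
  else "marginal"
  structure(list(equilibrium = eq, eigenvalues = eigenvalues,
                 verdict = verdict, method = method, eps = eps,
                 analytic_regime_ok = analytic_regime_ok),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, digits = 5, ...) {
  cat(eq_label(x$equilibrium), " is ", x$verdict, " (", x$method,
      " eigenvalues", if (isFALSE(x$analytic_regime_ok)) ", outside the small rho/phi regime: approximate",
      ")\n", sep = "")
  print(signif(x$eigenvalues, digits))
  invisible(x)
}

#' Numeric stability classification of an equilibrium
#'
#' Computes the eigenvalues of the analytic Jacobian at the equilibrium and
#' classifies local stability: `stable` when all real parts are below `-eps`,
#' `unstable` when any exceeds `+eps`, otherwise `marginal` (as happens at
#' bifurcation points, where an eigenvalue crosses zero). This is the
#' authoritative classifier for every case; the closed-form eigenvalue
#' formulas ([analytic_eigenvalues()]) are exact for cases 1-3 but only
#' approximate for case 4.
#'
#' @param eq a `"crime_equilibrium"` (see [crime_equilibria()]) or a state
#'   vector.
#' @inheritParams validate_params
#' @param eps marginality band on eigenvalue real parts (default `1e-9`).
#' @return A `"stability_report"`: equilibrium, complex eigenvalues, verdict,
#'   method.
#' @export
stability_numeric <- function(eq, params, eps = 1e-9) {
  p <- validate_params(params)
  ev <- eigen(crime_jacobian(eq_state(eq), p), only.values = TRUE)$values
  new_stability_report(eq, ev, "numeric", eps)
}

#' Characteristic-polynomial coefficients at an equilibrium (cases 2-4)
#'
#' The non-trivial eigenvalues at the equilibria of cases 2-4 are roots of a
#' quadratic (cases 2-3) or cubic (case 4) factor of the characteristic
#' polynomial. This returns the closed-form coefficients:
#' \itemize{
#' \item case 2, E0: `lambda^2 + u1 lambda + u2` with
#'   `u1 = kappa + gamma delta/eta - alpha sigma`,
#'   `u2 = -alpha sigma kappa + (kappa-beta) gamma delta/eta`;
#' \item case 2, E2: `v1 = alpha G2 + kappa + beta gamma delta/(eta kappa)`,
#'   `v2 = alpha kappa G2`;
#' \item case 3, E3/E4: `p1 = eta + (alpha+rho) G`,
#'   `p2 = +/- gamma delta G sqrt(B^2 - 4AD)` (plus sign on the upper root);
#' \item case 4, E5/E6: cubic `lambda^3 + y1 lambda^2 + y2 lambda + y3` with
#'   `y1 = alpha G + eta + beta delta J/kappa + kappa`,
#'   `y2 = kappa(alpha G + eta) + beta delta eta J/kappa + gamma delta G (2AG+B)`,
#'   `y3 = gamma delta kappa G (2AG+B)`,
#'   plus the Routh-Hurwitz determinant `delta = y1 y2 - y3`. At the upper
#'   root `2AG+B = +sqrt(disc) > 0` so `y3 > 0`; at the lower root `y3 < 0`,
#'   which alone makes E6 unstable. When `beta = kappa` the reduced forms
#'   `y1 = alpha G + eta + delta J + kappa`,
#'   `y2 = kappa(alpha G + eta) + alpha G(eta + rho G) + delta eta J`,
#'   `y3 = kappa alpha G (eta + rho G)` are used.
#' }
#' The case-4 cubic is derived in the small co-optation/small corrupt-judge
#' incarceration regime (`rho << 1`, `phi << 1`) and is approximate outside
#' it; [stability_numeric()] remains the ground truth.
#'
#' @inheritParams stability_numeric
#' @return List of class `"charpoly_coefficients"` with the populated
#'   coefficients for the active case/equilibrium (`u1,u2`, `v1,v2`, `p1,p2`,
#'   `q1,q2`, or `y1,y2,y3,delta`), plus `case` and `label`.
#' @export
charpoly_coefficients <- function(eq, params) {
  p <- validate_params(params)
  case <- classify_case(p)
  if (case == 1L)
    stop("case 1 eigenvalues are fully explicit; use analytic_eigenvalues()",
         call. = FALSE)
  label <- eq_label(eq)
  s <- eq_state(eq)
  G <- s[["G"]]; J <- s[["J"]]
  alpha <- p[["alpha"]]; beta <- p[["beta"]]; gamma <- p[["gamma"]]
  delta <- p[["delta"]]; eta <- p[["eta"]]; kappa <- p[["kappa"]]
  rho <- p[["rho"]]
  out <- list(case = case, label = label)
  if (case == 2L) {
    if (label == "E0") {
      out$u1 <- kappa + gamma * delta / eta - alpha * p[["sigma"]]
      out$u2 <- -alpha * p[["sigma"]] * kappa + (kappa - beta) * gamma * delta / eta
    } else {
      out$v1 <- alpha * G + kappa + beta * gamma * delta / (eta * kappa)
      out$v2 <- alpha * kappa * G
    }
  } else if (case == 3L) {
    rt <- endemic_roots(p)
    sq <- sqrt(max(rt$discriminant, 0))
    if (label == "E4") {
      out$q1 <- eta + (alpha + rho) * G
      out$q2 <- -gamma * delta * G * sq
    } else {
      out$p1 <- eta + (alpha + rho) * G
      out$p2 <- gamma * delta * G * sq
    }
  } else {
    if (label == "E0") {
      # crime-free state: same quadratic as case 2 (approximate for rho > 0)
      out$u1 <- kappa + gamma * delta / eta - alpha * p[["sigma"]]
      out$u2 <- -alpha * p[["sigma"]] * kappa + (kappa - beta) * gamma * delta / eta
    } else if (beta == kappa) {
      out$y1 <- alpha * G + eta + delta * J + kappa
      out$y2 <- kappa * (alpha * G + eta) + alpha * G * (eta + rho * G) +
        delta * eta * J
      out$y3 <- kappa * alpha * G * (eta + rho * G)
      out$delta <- out$y1 * out$y2 - out$y3
    } else {
      rt <- endemic_roots(p)
      two_ab <- 2 * rt$A * G + rt$B
      out$y1 <- alpha * G + eta + beta * delta * J / kappa + kappa
      out$y2 <- kappa * (alpha * G + eta) + beta * delta * eta * J / kappa +
        gamma * delta * G * two_ab
      out$y3 <- gamma * delta * kappa * G * two_ab
      out$delta <- out$y1 * out$y2 - out$y3
    }
  }
  structure(out, class = "charpoly_coefficients")
}

#' Routh-Hurwitz test for a cubic
#'
#' For `lambda^3 + y1 lambda^2 + y2 lambda + y3`, all roots have negative real
#' parts iff `y1 > 0`, `y2 > 0`, `y3 > 0` and `y1 y2 - y3 > 0`.
#'
#' @param y1,y2,y3 real coefficients.
#' @return `TRUE` (all roots in the open left half plane) or `FALSE`.
#' @export
routh_hurwitz_cubic <- function(y1, y2, y3) {
  stopifnot(is.finite(y1), is.finite(y2), is.finite(y3))
  y1 > 0 && y2 > 0 && y3 > 0 && (y1 * y2 - y3) > 0
}

#' Closed-form eigenvalues and stability verdict
#'
#' Returns the explicit eigenvalues known in closed form:
#' \itemize{
#' \item case 1: E0 has `(R0-1) gamma delta/eta, -eta, -gamma phi/eta,
#'   -kappa`; E1 the same with `(1-R0)` in the first slot — hence the
#'   transcritical exchange at `R0 = 1`;
#' \item case 2: `-eta`, `-gamma phi/eta`, and the roots of the `u` (E0) or
#'   `v` (E2) quadratic;
#' \item case 3: E0 as in case 1; E3/E4 have `-phi gamma/(eta + rho G)`,
#'   `-kappa`, and the roots of the `p`/`q` quadratic;
#' \item case 4: `-phi J` and the roots of the `y` cubic (endemic states), or
#'   the case-2 quadratic (E0). These case-4 formulas are derived for
#'   `rho << 1`, `phi << 1` and are flagged approximate outside that regime.
#' }
#'
#' @inheritParams stability_numeric
#' @param rho_max,phi_max smallness bounds defining the regime in which the
#'   case-4 closed forms are trusted (defaults `1e-3` and `1e-2`).
#' @param strict if `TRUE`, a case-4 request outside the regime is an error
#'   instead of an approximate report.
#' @return A `"stability_report"` with `method = "analytic"`;
#'   `analytic_regime_ok` is `TRUE` for cases 1-3 and reflects the smallness
#'   bounds in case 4.
#' @export
analytic_eigenvalues <- function(eq, params, eps = 1e-9,
                                 rho_max = 1e-3, phi_max = 1e-2,
                                 strict = FALSE) {
  p <- validate_params(params)
  case <- classify_case(p)
  label <- eq_label(eq)
  s <- eq_state(eq)
  gamma <- p[["gamma"]]; delta <- p[["delta"]]; eta <- p[["eta"]]
  phi <- p[["phi"]]; rho <- p[["rho"]]; kappa <- p[["kappa"]]
  R0 <- reproduction_number(p)
  regime_ok <- TRUE
  if (case %in% c(1L, 3L) && label == "E0" || case == 1L) {
    lam1 <- if (label == "E0") (R0 - 1) * gamma * delta / eta
    else (1 - R0) * gamma * delta / eta
    ev <- as.complex(c(lam1, -eta, -gamma * phi / eta, -kappa))
  } else if (case == 2L || (case == 4L && label == "E0")) {
    co <- charpoly_coefficients(eq, p)
    quad <- if (label == "E0") c(co$u2, co$u1, 1) else c(co$v2, co$v1, 1)
    ev <- c(polyroot(quad), complex(real = c(-eta, -gamma * phi / eta)))
    if (case == 4L) regime_ok <- rho <= rho_max && phi <= phi_max
  } else if (case == 3L) {
    co <- charpoly_coefficients(eq, p)
    quad <- if (label == "E4") c(co$q2, co$q1, 1) else c(co$p2, co$p1, 1)
    G <- s[["G"]]
    ev <- c(polyroot(quad),
            complex(real = c(-phi * gamma / (eta + rho * G), -kappa)))
  } else {
    regime_ok <- rho <= rho_max && phi <= phi_max
    if (!regime_ok && strict)
      stop("case-4 closed-form eigenvalues are valid only for rho <= ",
           rho_max, " and phi <= ", phi_max,
           "; use stability_numeric() or strict = FALSE", call. = FALSE)
    co <- charpoly_coefficients(eq, p)
    ev <- c(complex(real = -phi * s[["J"]]),
            polyroot(c(co$y3, co$y2, co$y1, 1)))
  }
  new_stability_report(eq, ev, "analytic", eps,
                       analytic_regime_ok = if (case == 4L) regime_ok else TRUE)
}
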