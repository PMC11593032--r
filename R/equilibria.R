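#' Basic reproduction number R0
#'
#' The threshold quantity \eqn{R_0 = \alpha\eta\sigma/(\gamma\delta)}. By
#' analogy with disease eradication, `R0 < 1` is necessary (and, absent
#' co-optation and recidivism, sufficient) for organized criminal activity to
#' die out; `R0 > 1` makes the endemic state attracting.
#'
#' @inheritParams validate_params
#' @return A single dimensionless number.
#' @export
reproduction_number <- function(params) {
  p <- validate_params(params)
  p[["alpha"]] * p[["eta"]] * p[["sigma"]] / (p[["gamma"]] * p[["delta"]])
}

#' Elasticities (normalized sensitivities) of R0
#'
#' Returns \eqn{(\partial R_0/\partial p)\,(p/R_0)} for each parameter:
#' `+1` for `alpha`, `eta`, `sigma`; `-1` for `gamma`, `delta`; `0` for the
#' parameters absent from R0 (`beta`, `kappa`, `rho`, `phi`). Because R0 is a
#' monomial in the parameters, the elasticities are exact integers: a 1%
#' increase in `alpha` raises R0 by 1%, a 1% increase in `delta` lowers it
#' by 1%.
#'
#' @inheritParams validate_params
#' @return Named numeric vector over the nine parameters.
#' @export
r0_elasticity <- function(params) {
  validate_params(params)
  c(alpha = 1, beta = 0, gamma = -1, delta = -1, eta = 1,
    kappa = 0, rho = 0, sigma = 1, phi = 0)
}

#' Bifurcation thresholds of the active case
#'
#' Computes R0 together with the thresholds that organize the long-term
#' behaviour:
#' \itemize{
#' \item `r = 4\eta\rho\sigma/(\eta+\rho\sigma)^2` (defined when `rho > 0`):
#'   the saddle-node threshold of the recidivism-free endemic pair; always
#'   `<= 1` since `4mn <= (m+n)^2`.
#' \item `r2 = 1 - (beta/kappa)(1 + rho/delta)` (case 4): above it the upper
#'   endemic state is the only positive endemic equilibrium.
#' \item `r1 = r * r2` (case 4): the backward-bifurcation (saddle-node)
#'   threshold; for `r1 <= R0 < r2` two endemic states exist and the
#'   crime-free state coexists with the stable one.
#' }
#' When `r2 <= 0` (possible for `(beta/kappa)(1+rho/delta) >= 1`) there is no
#' bistability window: R0, being positive, always exceeds `r1`, and the set is
#' flagged accordingly with `r1`/`r2` reported as `NA`.
#'
#' @inheritParams validate_params
#' @return An object of class `"crime_thresholds"`: list with elements `R0`,
#'   `r`, `r1`, `r2` (NA where not defined for the active case), `case`, and
#'   `bistability_window` (`NA` for cases 1-2, else logical).
#' @export
bifurcation_thresholds <- function(params) {
  p <- validate_params(params)
  case <- classify_case(p)
  R0 <- reproduction_number(p)
  r <- r1 <- r2 <- NA_real_
  window <- NA
  if (p[["rho"]] > 0) {
    m <- p[["eta"]]; n <- p[["rho"]] * p[["sigma"]]
    r <- 4 * m * n / (m + n)^2
    window <- TRUE
  }
  if (case == 4L) {
    r2_raw <- 1 - (p[["beta"]] / p[["kappa"]]) * (1 + p[["rho"]] / p[["delta"]])
    if (r2_raw <= 0) {
      window <- FALSE
    } else {
      r2 <- r2_raw
      r1 <- r * r2
    }
  }
  structure(list(R0 = R0, r = r, r1 = r1, r2 = r2, case = case,
                 bistability_window = window),
            class = "crime_thresholds")
}

#' @export
print.crime_thresholds <- function(x, ...) {
  cat("Thresholds (case ", x$case, "):  R0 = ", format(x$R0), "\n", sep = "")
  if (!is.na(x$r))  cat("  r  =", format(x$r), "\n")
  if (!is.na(x$r1)) cat("  r1 =", format(x$r1), " r2 =", format(x$r2), "\n")
  if (identical(x$bistability_window, FALSE))
    cat("  no bistability window (r2 <= 0): R0 >= r1 holds vacuously\n")
  invisible(x)
}

# coefficients of the endemic quadratic A G^2 + B G + const, cases 3-4
endemic_quadratic <- function(p) {
  case <- classify_case(p)
  if (p[["rho"]] == 0)
    stop("the endemic quadratic is defined only for rho > 0 (cases 3-4); ",
         "cases 1-2 have linear closed forms", call. = FALSE)
  gd <- p[["gamma"]] * p[["delta"]]
  A <- p[["alpha"]] * p[["rho"]] / gd
  B <- p[["alpha"]] * (p[["eta"]] - p[["rho"]] * p[["sigma"]]) / gd
  R0 <- reproduction_number(p)
  const <- if (case == 3L) 1 - R0 else
    1 - R0 - (p[["beta"]] / p[["kappa"]]) * (1 + p[["rho"]] / p[["delta"]])
  list(A = A, B = B, const = const, case = case)
}

#' Endemic gang-density roots (cases 3 and 4)
#'
#' Solves the quadratic \eqn{A G^2 + B G + const = 0} whose positive roots are
#' the gang coordinates of the endemic equilibria when judges can be co-opted
#' (`rho > 0`). Here `A = alpha rho/(gamma delta) > 0`,
#' `B = alpha(eta - rho sigma)/(gamma delta)`, and the constant term is
#' `D = 1 - R0` (case 3, no recidivism) or
#' `H = 1 - R0 - (beta/kappa)(1 + rho/delta)` (case 4). The plus root is the
#' gang coordinate of the upper (stable) endemic state E3/E5; the minus root
#' that of the lower (unstable) state E4/E6.
#'
#' A discriminant within `1e-12` of zero is treated as exactly zero (double
#' root) so the saddle-node point is numerically stable; a negative
#' discriminant gives `NA` roots (no real endemic state).
#'
#' @inheritParams validate_params
#' @return List with `G_plus`, `G_minus` (NA when complex), `A`, `B`, `const`,
#'   `discriminant`, `case`.
#' @export
endemic_roots <- function(params) {
  p <- validate_params(params)
  q <- endemic_quadratic(p)
  disc <- q$B^2 - 4 * q$A * q$const
  if (abs(disc) <= 1e-12) disc <- 0
  if (disc < 0) {
    G_plus <- G_minus <- NA_real_
  } else {
    G_plus <- (-q$B + sqrt(disc)) / (2 * q$A)
    G_minus <- (-q$B - sqrt(disc)) / (2 * q$A)
  }
  list(G_plus = G_plus, G_minus = G_minus, A = q$A, B = q$B, const = q$const,
       discriminant = disc, case = q$case)
}

# full endemic coordinates from a gang density, cases 3-4
endemic_point_from_G <- function(G, p) {
  J <- p[["gamma"]] / (p[["eta"]] + p[["rho"]] * G)
  c(G = G, J = J, C = p[["rho"]] * G / p[["phi"]],
    P = (p[["delta"]] + p[["rho"]]) * p[["gamma"]] * G /
      (p[["kappa"]] * (p[["eta"]] + p[["rho"]] * G)))
}

new_equilibrium <- function(label, coords, case) {
  physical <- !anyNA(coords) && all(coords >= -1e-12)
  structure(list(label = label,
                 coordinates = if (anyNA(coords))
                   stats::setNames(rep(NA_real_, 4), c("G", "J", "C", "P"))
                 else as_state(coords),
                 case = case, physical = physical),
            class = "crime_equilibrium")
}

#' @export
print.crime_equilibrium <- function(x, digits = 4, ...) {
  cat(x$label, ": (", paste(signif(x$coordinates, digits), collapse = ", "),
      ")", if (!x$physical) "  [not physical]", "\n", sep = "")
  invisible(x)
}

#' Closed-form equilibria of the active case
#'
#' Returns every steady state defined for the structural case of `params`:
#' \itemize{
#' \item all cases: the crime-free state `E0 = (0, gamma/eta, 0, 0)`;
#' \item case 1 (`rho = beta = 0`): the corruption-free endemic state `E1`
#'   with `G1 = (R0-1) gamma delta/(alpha eta)`;
#' \item case 2 (`rho = 0 < beta`): `E2` with
#'   `G2 = (R0 - 1 + beta/kappa) gamma delta/(alpha eta)` (so `G2 = sigma`
#'   at total recidivism `beta = kappa`);
#' \item cases 3-4 (`rho > 0`): the endemic pair (E3/E4 or E5/E6) built from
#'   the [endemic_roots()] quadratic, with `J = gamma/(eta + rho G)`,
#'   `C = rho G/phi`,
#'   `P = (delta+rho) gamma G / (kappa (eta + rho G))`.
#' }
#' Equilibria with a negative or complex coordinate are returned with
#' `physical = FALSE` rather than dropped, so bifurcation sweeps can draw
#' unstable and unphysical branches.
#'
#' @inheritParams validate_params
#' @return Object of class `"crime_equilibria"`: a named list of
#'   `"crime_equilibrium"` objects.
#' @examples
#' p <- crime_params(alpha = 50, beta = 0, gamma = 10, delta = 8, eta = 0.1,
#'                   kappa = 50, rho = 0, sigma = 20, phi = 0.2)
#' crime_equilibria(p)   # E1 = (4, 100, 0, 64)
#' @export
crime_equilibria <- function(params) {
  p <- validate_params(params)
  case <- classify_case(p)
  R0 <- reproduction_number(p)
  gd <- p[["gamma"]] * p[["delta"]]
  Jfree <- p[["gamma"]] / p[["eta"]]
  eqs <- list(new_equilibrium("E0", c(0, Jfree, 0, 0), case))
  if (case == 1L) {
    G1 <- (R0 - 1) * gd / (p[["alpha"]] * p[["eta"]])
    P1 <- (R0 - 1) * gd^2 / (p[["alpha"]] * p[["kappa"]] * p[["eta"]]^2)
    eqs <- c(eqs, list(new_equilibrium("E1", c(G1, Jfree, 0, P1), case)))
  } else if (case == 2L) {
    s <- R0 - 1 + p[["beta"]] / p[["kappa"]]
    G2 <- s * gd / (p[["alpha"]] * p[["eta"]])
    P2 <- s * gd^2 / (p[["alpha"]] * p[["kappa"]] * p[["eta"]]^2)
    eqs <- c(eqs, list(new_equilibrium("E2", c(G2, Jfree, 0, P2), case)))
  } else {
    roots <- endemic_roots(p)
    labels <- if (case == 3L) c("E3", "E4") else c("E5", "E6")
    coords_plus <- if (is.na(roots$G_plus)) rep(NA_real_, 4) else
      endemic_point_from_G(roots$G_plus, p)
    coords_minus <- if (is.na(roots$G_minus)) rep(NA_real_, 4) else
      endemic_point_from_G(roots$G_minus, p)
    eqs <- c(eqs, list(new_equilibrium(labels[1], coords_plus, case),
                       new_equilibrium(labels[2], coords_minus, case)))
  }
  names(eqs) <- vapply(eqs, `[[`, "", "label")
  structure(eqs, class = "crime_equilibria")
}

#' @export
print.crime_equilibria <- function(x, ...) {
  cat("Equilibria (case ", x[[1]]$case, "):\n", sep = "")
  for (eq in x) print(eq, ...)
  invisible(x)
}

#' @export
as.data.frame.crime_equilibria <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), function(eq) {
    data.frame(label = eq$label, G = eq$coordinates[["G"]],
               J = eq$coordinates[["J"]], C = eq$coordinates[["C"]],
               P = eq$coordinates[["P"]], physical = eq$physical,
               row.names = NULL)
  }))
}
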