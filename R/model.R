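#' Vector field of the gang-judiciary model
#'
#' Evaluates the right-hand side of the four coupled ODEs:
#' \deqn{dG/dt = \alpha G(\sigma - G) - \delta G J + \beta P}
#' \deqn{dJ/dt = \gamma - \eta J - \rho G J}
#' \deqn{dC/dt = \rho G J - \phi C J}
#' \deqn{dP/dt = \delta G J + \phi C J - \kappa P}
#' Gang members grow logistically towards the carrying capacity `sigma`, are
#' jailed on contact with honest judges (`delta`), and are replenished by
#' relapsing ex-prisoners (`beta`). Judges flow in at rate `gamma`, retire at
#' rate `eta`, and are co-opted on contact with the gang (`rho`); corrupt
#' judges are themselves jailed on contact with honest ones (`phi`).
#'
#' Negative state components are accepted (no clamping) so that integrator
#' diagnostics can observe undershoot; physical validity is enforced at the
#' trajectory level.
#'
#' @param state numeric state vector `(G, J, C, P)`.
#' @inheritParams validate_params
#' @return Named numeric vector of the four time derivatives.
#' @seealso [crime_jacobian()], [simulate_crime()]
#' @export
crime_rhs <- function(state, params) {
  p <- validate_params(params)
  s <- as_state(state)
  G <- s[["G"]]; J <- s[["J"]]; C <- s[["C"]]; P <- s[["P"]]
  c(G = p[["alpha"]] * G * (p[["sigma"]] - G) - p[["delta"]] * G * J + p[["beta"]] * P,
    J = p[["gamma"]] - p[["eta"]] * J - p[["rho"]] * G * J,
    C = p[["rho"]] * G * J - p[["phi"]] * C * J,
    P = p[["delta"]] * G * J + p[["phi"]] * C * J - p[["kappa"]] * P)
}

#' Jacobian matrix of the model vector field
#'
#' Analytic 4x4 matrix of partial derivatives of [crime_rhs()] with respect to
#' the state, evaluable at any state (not only equilibria). Row/column order
#' is `(G, J, C, P)`; the `(P, P)` entry is the constant `-kappa`.
#'
#' @inheritParams crime_rhs
#' @return A 4x4 numeric matrix with dimnames `(G, J, C, P)`.
#' @export
crime_jacobian <- function(state, params) {
  p <- validate_params(params)
  s <- as_state(state)
  G <- s[["G"]]; J <- s[["J"]]; C <- s[["C"]]
  alpha <- p[["alpha"]]; delta <- p[["delta"]]; rho <- p[["rho"]]
  phi <- p[["phi"]]
  m <- matrix(c(
    alpha * p[["sigma"]] - 2 * alpha * G - delta * J, -delta * G, 0, p[["beta"]],
    -rho * J, -p[["eta"]] - rho * G, 0, 0,
    rho * J, rho * G - phi * C, -phi * J, 0,
    delta * J, delta * G + phi * C, phi * J, -p[["kappa"]]),
    nrow = 4, byrow = TRUE)
  dimnames(m) <- list(c("G", "J", "C", "P"), c("G", "J", "C", "P"))
  m
}
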