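#' Parameter set for the gang-judiciary model
#'
#' Constructs and validates the nine rate/capacity constants of the
#' four-compartment model. All parameters must be strictly positive, except
#' `rho` (judge co-optation) and `beta` (recidivism), which may be exactly
#' zero; the zero/positive pattern of these two selects the structural case
#' (see [classify_case()]). Recidivism cannot exceed the release rate, so
#' `beta <= kappa` is enforced.
#'
#' @param alpha intraspecific-competition coefficient of the gang's logistic
#'   growth, per (density x time); `alpha * sigma` is the low-density growth
#'   rate constant.
#' @param beta recidivism rate constant (released prisoners rejoining the
#'   gang), per time. May be 0.
#' @param gamma constant influx of non-corrupt judges, density per time.
#' @param delta incarceration rate constant of gang members by non-corrupt
#'   judges, per (density x time).
#' @param eta judge retirement/death rate constant, per time (career length
#'   `1/eta`).
#' @param kappa prisoner release/death rate constant, per time.
#' @param rho judge co-optation (corruption) rate constant, per
#'   (density x time). May be 0.
#' @param sigma gang carrying capacity, density (persons per area unit).
#' @param phi incarceration rate constant of corrupt judges by non-corrupt
#'   judges, per (density x time).
#'
#' @return A named numeric vector of class `"crime_params"`.
#' @seealso [classify_case()], [crime_rhs()], [reproduction_number()]
#' @examples
#' crime_params(alpha = 30, beta = 0, gamma = 10, delta = 8, eta = 0.1,
#'              kappa = 50, rho = 0, sigma = 20, phi = 0.2)
#' @export
crime_params <- function(alpha, beta, gamma, delta, eta, kappa, rho, sigma, phi) {
  p <- c(alpha = alpha, beta = beta, gamma = gamma, delta = delta, eta = eta,
         kappa = kappa, rho = rho, sigma = sigma, phi = phi)
  validate_params(structure(p, class = "crime_params"))
}

#' Validate a model parameter set
#'
#' Checks finiteness, positivity (strict, except `beta` and `rho` which may be
#' exactly zero) and the recidivism constraint `beta <= kappa`. Returns its
#' input unchanged on success, so it can be used as a pass-through guard.
#'
#' @param params a `"crime_params"` object or a named numeric vector with
#'   elements `alpha, beta, gamma, delta, eta, kappa, rho, sigma, phi`.
#' @return The validated `"crime_params"` object.
#' @export
validate_params <- function(params) {
  nm <- c("alpha", "beta", "gamma", "delta", "eta", "kappa", "rho", "sigma", "phi")
  if (!is.numeric(params) || !all(nm %in% names(params)))
    stop("`params` must be a named numeric vector with elements ",
         paste(nm, collapse = ", "), call. = FALSE)
  p <- unclass(params)[nm]
  if (any(!is.finite(p)))
    stop("non-finite parameter value: ",
         paste(nm[!is.finite(p)], collapse = ", "), call. = FALSE)
  strict <- setdiff(nm, c("beta", "rho"))
  bad <- strict[p[strict] <= 0]
  if (length(bad))
    stop("parameters must be strictly positive: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (p[["beta"]] < 0 || p[["rho"]] < 0)
    stop("beta and rho must be >= 0", call. = FALSE)
  if (p[["beta"]] > p[["kappa"]])
    stop("beta must not exceed kappa (recidivism cannot outpace release)",
         call. = FALSE)
  structure(p, class = "crime_params")
}

#' @export
print.crime_params <- function(x, digits = 6, ...) {
  cat("Gang-judiciary model parameters (case ", classify_case(x), "):\n", sep = "")
  print(signif(unclass(x), digits), ...)
  invisible(x)
}

#' State vector of the model
#'
#' @param G gang-member density.
#' @param J non-corrupt-judge density.
#' @param C corrupt-judge density.
#' @param P prisoner density.
#'
#' All densities are persons per area unit. The component order `(G, J, C, P)`
#' is fixed throughout the package.
#'
#' @return Named numeric vector `c(G, J, C, P)`.
#' @export
crime_state <- function(G, J, C, P) {
  s <- c(G = G, J = J, C = C, P = P)
  if (any(!is.finite(s))) stop("state components must be finite", call. = FALSE)
  s
}

as_state <- function(state) {
  if (length(state) != 4 || !is.numeric(state))
    stop("a state must be a numeric vector of length 4 (G, J, C, P)",
         call. = FALSE)
  if (any(!is.finite(state))) stop("state components must be finite", call. = FALSE)
  stats::setNames(as.numeric(state), c("G", "J", "C", "P"))
}

#' Structural case of a parameter set
#'
#' The long-term behaviour of the model splits into four structural cases by
#' exact-zero tests on the co-optation rate `rho` and the recidivism rate
#' `beta`:
#' case 1 (`rho = 0, beta = 0`), case 2 (`rho = 0, beta > 0`),
#' case 3 (`rho > 0, beta = 0`), case 4 (`rho > 0, beta > 0`).
#' The cases are structural, not numerical: a tiny positive `rho` is case 3/4,
#' never "approximately" case 1/2.
#'
#' @inheritParams validate_params
#' @return Integer 1, 2, 3, or 4.
#' @export
classify_case <- function(params) {
  p <- validate_params(params)
  if (p[["rho"]] == 0) {
    if (p[["beta"]] == 0) 1L else 2L
  } else {
    if (p[["beta"]] == 0) 3L else 4L
  }
}
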