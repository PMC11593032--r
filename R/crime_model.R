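#' Gang-judiciary model object
#'
#' Bundles a validated parameter set into a model object with the usual
#' methods: `print`, `summary` (thresholds, equilibria and their stability),
#' `simulate` (RK4 trajectory), and `plot` (bifurcation diagram over alpha).
#' The lower-level functions ([crime_equilibria()], [stability_numeric()],
#' [simulate_crime()], [sweep_alpha()], ...) are all also exported and accept
#' either the model or its parameter vector.
#'
#' @param params a `"crime_params"` vector, or `NULL` to build one from the
#'   named rate arguments.
#' @param ... the nine rate arguments of [crime_params()] when `params` is
#'   `NULL`.
#' @return Object of class `"crime_model"`.
#' @examples
#' m <- crime_model(alpha = 6, beta = 30, gamma = 10, delta = 8, eta = 0.1,
#'                  kappa = 50, rho = 0.1, sigma = 20, phi = 0.2)
#' summary(m)
#' @export
crime_model <- function(params = NULL, ...) {
  p <- if (is.null(params)) crime_params(...) else validate_params(params)
  structure(list(params = p, case = classify_case(p)), class = "crime_model")
}

#' @export
print.crime_model <- function(x, ...) {
  cat("Gang-judiciary compartmental model, structural case ", x$case,
      "\nR0 = ", format(reproduction_number(x$params)), "\n", sep = "")
  print(x$params)
  invisible(x)
}

#' @export
summary.crime_model <- function(object, ...) {
  p <- object$params
  eqs <- crime_equilibria(p)
  verdicts <- vapply(eqs, function(eq) {
    if (anyNA(eq$coordinates)) "no real coordinates"
    else stability_numeric(eq, p)$verdict
  }, "")
  out <- list(model = object, thresholds = bifurcation_thresholds(p),
              equilibria = eqs, verdicts = verdicts,
              elasticity = r0_elasticity(p))
  class(out) <- "summary.crime_model"
  out
}

#' @export
print.summary.crime_model <- function(x, ...) {
  print(x$model)
  print(x$thresholds)
  df <- as.data.frame(x$equilibria)
  df$stability <- unname(x$verdicts[df$label])
  cat("Equilibria:\n")
  print(df, digits = 6)
  invisible(x)
}

#' Simulate a model object
#'
#' Deterministic RK4 integration; `nsim` and `seed` are accepted for
#' compatibility with the [stats::simulate()] generic but the model has no
#' stochastic component, so `nsim > 1` returns identical trajectories.
#'
#' @param object a `"crime_model"`.
#' @param nsim number of trajectories (all identical; default 1).
#' @param seed ignored (kept for generic compatibility).
#' @param init,t_end,dt,thin passed to [simulate_crime()].
#' @param ... unused.
#' @return A `"crime_trajectory"` (or a list of them when `nsim > 1`).
#' @export
simulate.crime_model <- function(object, nsim = 1, seed = NULL, init, t_end,
                                 dt = 0.01, thin = 1L, ...) {
  one <- function() simulate_crime(object$params, init, t_end, dt, thin)
  if (nsim == 1) one() else replicate(nsim, one(), simplify = FALSE)
}

#' @rdname plot.crime_bifurcation
#' @param alpha_range,n_points passed to [sweep_alpha()] when plotting a
#'   `"crime_model"`.
#' @export
plot.crime_model <- function(x, alpha_range = NULL, n_points = 200L, ...) {
  if (is.null(alpha_range)) {
    a0 <- x$params[["alpha"]]
    alpha_range <- c(a0 / 4, a0 * 2.5)
  }
  plot(sweep_alpha(x$params, alpha_range, n_points), ...)
}
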