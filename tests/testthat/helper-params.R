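# Parameter sets used throughout the suite: the figure parameterizations
# (gamma=10, delta=8, eta=0.1, kappa=50, sigma=20, phi=0.2 with alpha, beta,
# rho varying) and the real-world scenario.

fig_params <- function(alpha, beta = 0, rho = 0) {
  crime_params(alpha = alpha, beta = beta, gamma = 10, delta = 8, eta = 0.1,
               kappa = 50, rho = rho, sigma = 20, phi = 0.2)
}

fig3_params <- function(alpha) fig_params(alpha, beta = 30, rho = 0.1)

realworld_params <- function() {
  crime_params(alpha = 1 / 40, beta = 1 / 6, gamma = 1 / 3, delta = 1 / 50,
               eta = 1 / 30, kappa = 1 / 5, rho = 1 / 40000, sigma = 40,
               phi = 1 / 100)
}

# random valid parameter draw for a given structural case
draw_params <- function(case = 4L) {
  repeat {
    kappa <- runif(1, 0.5, 50)
    p <- try(crime_params(
      alpha = runif(1, 0.1, 50),
      beta = if (case %in% c(1L, 3L)) 0 else runif(1, 0.01, 1) * kappa,
      gamma = runif(1, 0.5, 20),
      delta = runif(1, 0.5, 10),
      eta = runif(1, 0.02, 2),
      kappa = kappa,
      rho = if (case %in% c(1L, 2L)) 0 else runif(1, 0.01, 2),
      sigma = runif(1, 1, 40),
      phi = runif(1, 0.05, 2)), silent = TRUE)
    if (!inherits(p, "try-error")) return(p)
  }
}

# random nonnegative state
draw_state <- function(scale = 50) runif(4, 0, scale)
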