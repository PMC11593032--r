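# Shipped scenario fixtures: the five simulation experiments of the source
# figures, with the printed parameter values, initial conditions (where
# printed) and expected limits. Values are immutable; load_scenario() returns
# a fresh copy each time.
#
# fig1a/fig1b have no printed initial condition; (1, 100, 0, 0) -- one gang
# member per area unit entering a crime-free region -- is used, and the
# expected limits are initial-condition independent in those monostable
# regimes. fig3a/fig3b/fig3d carry dt = 0.002 because their initial
# transient (delta * J of order 10^2-10^3) is outside the RK4 stability
# region at dt = 0.01.
base_fig_params <- function(alpha, beta, rho) {
  crime_params(alpha = alpha, beta = beta, gamma = 10, delta = 8, eta = 0.1,
               kappa = 50, rho = rho, sigma = 20, phi = 0.2)
}

scenario_fixtures <- function() {
  list(
    fig1a = list(
      name = "fig1a", params = base_fig_params(30, 0, 0),
      initial_state = c(G = 1, J = 100, C = 0, P = 0),
      sim = list(dt = 0.01, t_end = 100),
      expected = list(attractor = "E0", limit = c(0, 100, 0, 0), R0 = 0.75)),
    fig1b = list(
      name = "fig1b", params = base_fig_params(50, 0, 0),
      initial_state = c(G = 1, J = 100, C = 0, P = 0),
      sim = list(dt = 0.01, t_end = 100),
      expected = list(attractor = "E1", limit = c(4, 100, 0, 64), R0 = 1.25)),
    fig3a = list(
      name = "fig3a", params = base_fig_params(2, 30, 0.1),
      initial_state = c(G = 20, J = 102, C = 20, P = 20),
      sim = list(dt = 0.002, t_end = 100),
      expected = list(attractor = "E0", limit = c(0, 100, 0, 0), R0 = 0.05)),
    fig3b = list(
      name = "fig3b", params = base_fig_params(6, 30, 0.1),
      initial_state = c(G = 20, J = 102, C = 20, P = 20),
      sim = list(dt = 0.002, t_end = 100),
      expected = list(attractor = "E0", limit = c(0, 100, 0, 0), R0 = 0.15)),
    fig3c = list(
      name = "fig3c", params = base_fig_params(6, 30, 0.1),
      initial_state = c(G = 20, J = 20, C = 20, P = 20),
      sim = list(dt = 0.01, t_end = 100),
      expected = list(attractor = "E5", limit = c(17.11, 5.52, 8.56, 15.31),
                      R0 = 0.15)),
    fig3d = list(
      name = "fig3d", params = base_fig_params(20, 30, 0.1),
      initial_state = c(G = 20, J = 20, C = 20, P = 20),
      sim = list(dt = 0.002, t_end = 100),
      expected = list(attractor = "E5", limit = c(19.22, 4.94, 9.61, 15.40),
                      R0 = 0.5)),
    fig5 = list(
      name = "fig5",
      params = crime_params(alpha = 1 / 40, beta = 1 / 6, gamma = 1 / 3,
                            delta = 1 / 50, eta = 1 / 30, kappa = 1 / 5,
                            rho = 1 / 40000, sigma = 40, phi = 1 / 100),
      initial_state = c(G = 10, J = 0.1, C = 0, P = 0),
      sim = list(dt = 0.01, t_end = 300),
      expected = list(attractor = "E5", limit = c(38.71, 9.72, 0.097, 37.67),
                      R0 = 5))
  )
}

scenario_keys <- c("name", "params", "initial_state", "sim", "expected")
sim_keys <- c("dt", "t_end")
expected_keys <- c("attractor", "limit", "R0")

new_scenario <- function(x, source = "fixture") {
  extra <- setdiff(names(x), scenario_keys)
  if (length(extra))
    stop("unknown scenario keys: ", paste(extra, collapse = ", "), call. = FALSE)
  if (is.null(x$name) || is.null(x$params))
    stop("a scenario needs at least `name` and `params`", call. = FALSE)
  pr <- x$params
  if (!inherits(pr, "crime_params")) {
    pr <- unlist(pr)
    pr <- validate_params(structure(
      as.numeric(pr[c("alpha", "beta", "gamma", "delta", "eta", "kappa",
                      "rho", "sigma", "phi")]),
      names = c("alpha", "beta", "gamma", "delta", "eta", "kappa",
                "rho", "sigma", "phi"), class = "crime_params"))
  }
  sim <- x$sim %||% list()
  extra <- setdiff(names(sim), sim_keys)
  if (length(extra))
    stop("unknown sim keys: ", paste(extra, collapse = ", "), call. = FALSE)
  sim$dt <- sim$dt %||% 0.01
  sim$t_end <- sim$t_end %||% 100
  init <- if (is.null(x$initial_state)) NULL else as_state(unlist(x$initial_state))
  expected <- x$expected
  if (!is.null(expected)) {
    extra <- setdiff(names(expected), expected_keys)
    if (length(extra))
      stop("unknown expected keys: ", paste(extra, collapse = ", "), call. = FALSE)
    if (!is.null(expected$limit)) expected$limit <- as.numeric(unlist(expected$limit))
  }
  structure(list(name = x$name, params = pr, initial_state = init, sim = sim,
                 expected = expected, source = source),
            class = "crime_scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a scenario: shipped fixture or configuration file
#'
#' `source` is either the name of a shipped fixture — `fig1a`, `fig1b`,
#' `fig3a`, `fig3b`, `fig3c`, `fig3d`, `fig5`, carrying the printed parameter
#' values, initial conditions and expected limits of the corresponding
#' simulation experiments — or a path to a YAML/JSON file with keys `name`,
#' `params` (the nine rates), and optional `initial_state`, `sim` (`dt`,
#' `t_end`), `expected` (`attractor`, `limit`, `R0`). Unknown keys are
#' rejected; parameter constraints (positivity, `beta <= kappa`) are enforced.
#'
#' @param source fixture name or file path.
#' @return Object of class `"crime_scenario"`.
#' @export
load_scenario <- function(source) {
  stopifnot(is.character(source), length(source) == 1)
  fixtures <- scenario_fixtures()
  if (source %in% names(fixtures))
    return(new_scenario(fixtures[[source]], source = "fixture"))
  if (!file.exists(source))
    stop("unknown fixture or missing file: '", source, "' (fixtures: ",
         paste(names(fixtures), collapse = ", "), ")", call. = FALSE)
  raw <- if (grepl("\\.json$", source, ignore.case = TRUE))
    jsonlite::read_json(source, simplifyVector = TRUE)
  else yaml::read_yaml(source)
  new_scenario(raw, source = source)
}

#' Write a scenario to a YAML or JSON file
#'
#' The on-disk representation round-trips through [load_scenario()].
#'
#' @param scenario a `"crime_scenario"`.
#' @param file output path ending in `.yaml`, `.yml` or `.json`.
#' @return Invisibly, the file path.
#' @export
write_scenario <- function(scenario, file) {
  stopifnot(inherits(scenario, "crime_scenario"))
  x <- list(name = scenario$name,
            params = as.list(unclass(scenario$params)),
            initial_state = if (!is.null(scenario$initial_state))
              as.list(scenario$initial_state),
            sim = scenario$sim,
            expected = scenario$expected)
  x <- x[!vapply(x, is.null, TRUE)]
  if (grepl("\\.json$", file, ignore.case = TRUE))
    jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(x, file)
  invisible(file)
}

#' @export
print.crime_scenario <- function(x, ...) {
  cat("Scenario '", x$name, "' (", x$source, "), case ",
      classify_case(x$params), "\n", sep = "")
  print(x$params)
  if (!is.null(x$initial_state))
    cat("initial state: (", paste(x$initial_state, collapse = ", "), ")\n", sep = "")
  cat("sim: dt =", x$sim$dt, ", t_end =", x$sim$t_end, "\n")
  if (!is.null(x$expected))
    cat("expected attractor:", x$expected$attractor %||% "?", "\n")
  invisible(x)
}

#' Run a scenario and check it against its expected block
#'
#' Simulates the scenario with its own `dt` and horizon, detects the
#' attractor, and — when the scenario carries expectations — compares the
#' detected label, the trailing-state coordinates and R0 against them.
#' Expected limits follow the two-decimal display convention, so coordinates
#' are compared with an absolute tolerance of 0.005 plus the relative
#' convergence tolerance `tol`.
#'
#' @param scenario a `"crime_scenario"` or fixture name.
#' @param tol relative convergence tolerance (default `1e-4`).
#' @return Object of class `"scenario_result"`: list with `name`, `pass`
#'   (`NA` when the scenario has no expectations), `attractor`, `final`
#'   state, `R0`, `checks` data frame, and the `trajectory`.
#' @examples
#' \donttest{
#' run_scenario("fig1b")
#' }
#' @export
run_scenario <- function(scenario, tol = 1e-4) {
  if (is.character(scenario)) scenario <- load_scenario(scenario)
  stopifnot(inherits(scenario, "crime_scenario"))
  init <- scenario$initial_state
  if (is.null(init))
    stop("scenario '", scenario$name, "' has no initial state", call. = FALSE)
  traj <- simulate_crime(scenario$params, init, t_end = scenario$sim$t_end,
                         dt = scenario$sim$dt)
  eqs <- crime_equilibria(scenario$params)
  lab <- detect_attractor(traj, eqs, tol = tol)
  traj$converged_to <- lab
  final <- traj$states[nrow(traj$states), ]
  R0 <- reproduction_number(scenario$params)
  checks <- NULL
  pass <- NA
  exp <- scenario$expected
  if (!is.null(exp)) {
    checks <- data.frame(check = character(), expected = numeric(),
                         got = numeric(), ok = logical())
    add <- function(check, expected, got, ok)
      rbind(checks, data.frame(check = check, expected = expected, got = got,
                               ok = ok))
    if (!is.null(exp$attractor))
      checks <- add("attractor", NA, NA, identical(lab, exp$attractor))
    if (!is.null(exp$limit))
      for (i in 1:4)
        checks <- add(paste0("limit_", c("G", "J", "C", "P")[i]),
                      exp$limit[i], final[i],
                      abs(final[i] - exp$limit[i]) <=
                        0.005 + tol * abs(exp$limit[i]))
    if (!is.null(exp$R0))
      checks <- add("R0", exp$R0, R0, abs(R0 - exp$R0) <= 1e-9 + 0.005)
    pass <- all(checks$ok)
  }
  structure(list(name = scenario$name, pass = pass, attractor = lab,
                 final = final, R0 = R0, checks = checks, trajectory = traj),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Scenario '", x$name, "': attractor ", x$attractor, ", final state (",
      paste(signif(x$final, 6), collapse = ", "), "), R0 = ", format(x$R0),
      "\n", sep = "")
  if (!is.na(x$pass)) {
    cat(if (x$pass) "PASS" else "FAIL", "against expected values\n")
    if (!x$pass) print(x$checks)
  }
  invisible(x)
}
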