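#' Simulate the model with fixed-step fourth-order Runge-Kutta
#'
#' Integrates the four ODEs with the classic 4-stage RK4 scheme at a fixed
#' step `dt` (default 0.01 time units). The state is recorded at every step
#' (or every `thin`-th step). Small negative excursions are tolerated down to
#' `-1e-6`; beyond that the integration aborts with an error advising a
#' smaller step, rather than silently projecting back onto the positive
#' orthant. Note that the initial transient can be stiff when `delta * J(0)`
#' is large (the fast jailing mode), in which case `dt` must satisfy
#' `dt * delta * J(0) < 2.78` for RK4 stability.
#'
#' @inheritParams validate_params
#' @param init nonnegative initial state `(G, J, C, P)`.
#' @param t_end simulation horizon (time units).
#' @param dt integration step (default 0.01).
#' @param thin record every `thin`-th step (default 1 = all).
#' @return Object of class `"crime_trajectory"`: list with `times`, `states`
#'   (matrix with columns G, J, C, P), `params`, `dt`, and `converged_to`
#'   (filled by [detect_attractor()], else `NA`).
#' @examples
#' p <- crime_params(alpha = 50, beta = 0, gamma = 10, delta = 8, eta = 0.1,
#'                   kappa = 50, rho = 0, sigma = 20, phi = 0.2)
#' tr <- simulate_crime(p, init = c(1, 100, 0, 0), t_end = 100)
#' tail(as.data.frame(tr), 1)  # approaches E1 = (4, 100, 0, 64)
#' @export
simulate_crime <- function(params, init, t_end, dt = 0.01, thin = 1L) {
  p <- validate_params(params)
  s <- as_state(init)
  if (any(s < 0)) stop("initial state must be nonnegative", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (!is.numeric(t_end) || length(t_end) != 1 || t_end < dt)
    stop("t_end must be at least dt", call. = FALSE)
  thin <- max(1L, as.integer(thin))
  n_steps <- as.integer(round(t_end / dt))

  alpha <- p[["alpha"]]; beta <- p[["beta"]]; gamma <- p[["gamma"]]
  delta <- p[["delta"]]; eta <- p[["eta"]]; kappa <- p[["kappa"]]
  rho <- p[["rho"]]; sigma <- p[["sigma"]]; phi <- p[["phi"]]
  f <- function(y) {
    GJ <- y[1L] * y[2L]
    c(alpha * y[1L] * (sigma - y[1L]) - delta * GJ + beta * y[4L],
      gamma - eta * y[2L] - rho * GJ,
      rho * GJ - phi * y[3L] * y[2L],
      delta * GJ + phi * y[3L] * y[2L] - kappa * y[4L])
  }

  n_rec <- n_steps %/% thin + 1L
  states <- matrix(NA_real_, n_rec, 4L,
                   dimnames = list(NULL, c("G", "J", "C", "P")))
  times <- numeric(n_rec)
  y <- unname(s)
  states[1L, ] <- y
  rec <- 1L
  half <- dt / 2
  for (i in seq_len(n_steps)) {
    k1 <- f(y)
    k2 <- f(y + half * k1)
    k3 <- f(y + half * k2)
    k4 <- f(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(y)))
      stop("trajectory diverged (non-finite state) at t = ", i * dt,
           "; the step dt = ", dt, " is too large for this initial transient",
           call. = FALSE)
    if (any(y < -1e-6))
      stop("state undershot below -1e-6 at t = ", i * dt,
           "; reduce dt (stiff transient: dt * delta * J must stay well below 2.78)",
           call. = FALSE)
    if (i %% thin == 0L) {
      rec <- rec + 1L
      states[rec, ] <- y
      times[rec] <- i * dt
    }
  }
  structure(list(times = times[seq_len(rec)],
                 states = states[seq_len(rec), , drop = FALSE],
                 params = p, dt = dt, converged_to = NA_character_),
            class = "crime_trajectory")
}

#' @export
print.crime_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat("RK4 trajectory: ", n, " recorded states, t in [0, ",
      format(x$times[n]), "], dt = ", format(x$dt), "\n", sep = "")
  cat("final state: (", paste(signif(x$states[n, ], 6), collapse = ", "),
      ")\n", sep = "")
  if (!is.na(x$converged_to)) cat("converged to:", x$converged_to, "\n")
  invisible(x)
}

#' @export
as.data.frame.crime_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states)
}

#' Plot a trajectory
#'
#' Time evolution of the four densities, colour-coded: gang members red,
#' non-corrupt judges blue, corrupt judges magenta, prisoners green.
#'
#' @param x a `"crime_trajectory"`.
#' @param log_time plot time on a log axis (useful for fast transients).
#' @param ... passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.crime_trajectory <- function(x, log_time = FALSE, ...) {
  graphics::matplot(x$times, x$states, type = "l", lty = 1,
                    col = c("red", "blue", "magenta", "green3"),
                    xlab = "time", ylab = "density (persons / area unit)",
                    log = if (log_time) "x" else "", ...)
  graphics::legend("topright", legend = c("G", "J", "C", "P"),
                   col = c("red", "blue", "magenta", "green3"), lty = 1, bty = "n")
  invisible(x)
}

#' Export a trajectory as CSV
#'
#' Writes the trajectory with header `time,G,J,C,P`.
#'
#' @param traj a `"crime_trajectory"`.
#' @param file output path.
#' @return Invisibly, the file path.
#' @export
write_trajectory <- function(traj, file) {
  stopifnot(inherits(traj, "crime_trajectory"))
  utils::write.csv(as.data.frame(traj), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Match the tail of a trajectory to a candidate equilibrium
#'
#' Decides which equilibrium (if any) the trajectory has settled on. Over a
#' trailing window (default the final 10% of recorded states) the state must
#' be quasi-stationary — the per-component range below tolerance — and the
#' window mean must match a candidate's coordinates component-wise within the
#' relative tolerance `tol`, with an absolute floor of `1e-6` for components
#' whose target is zero. If several candidates match (possible very close to
#' a saddle-node), the closest is reported.
#'
#' @param traj a `"crime_trajectory"`.
#' @param candidates a `"crime_equilibria"` list or list of
#'   `"crime_equilibrium"` objects (typically [crime_equilibria()] output).
#' @param tol relative convergence tolerance (default `1e-4`).
#' @param window trailing fraction of recorded states examined (default 0.1).
#' @return The matched label (e.g. `"E5"`), or `"not converged"`.
#' @export
detect_attractor <- function(traj, candidates, tol = 1e-4, window = 0.1) {
  stopifnot(inherits(traj, "crime_trajectory"), tol > 0)
  if (length(candidates) == 0) stop("empty candidate list", call. = FALSE)
  if (inherits(candidates, "crime_equilibrium")) candidates <- list(candidates)
  n <- nrow(traj$states)
  i0 <- max(1L, n - max(2L, ceiling(window * n)) + 1L)
  tail_states <- traj$states[i0:n, , drop = FALSE]
  mid <- colMeans(tail_states)
  spread <- apply(tail_states, 2, function(v) max(v) - min(v))
  band <- pmax(tol * abs(mid), 1e-6)
  if (any(spread > band)) return("not converged")
  best <- NULL; best_d <- Inf
  for (eq in candidates) {
    co <- eq$coordinates
    if (anyNA(co)) next
    err <- abs(mid - co)
    if (all(err <= pmax(tol * abs(co), 1e-6))) {
      d <- max(err)
      if (d < best_d) { best_d <- d; best <- eq$label }
    }
  }
  if (is.null(best)) "not converged" else best
}

#' Probe basins of attraction
#'
#' Runs [simulate_crime()] followed by [detect_attractor()] for each initial
#' state and reports the attractor partition. In the bistable window
#' `r1 < R0 < r2` the initial condition decides whether the gang is
#' eradicated (E0) or persists (E5); this probe maps that empirically,
#' without any claim about the separatrix geometry. Integration failures for
#' an individual initial state are recorded as `"error: ..."` without
#' aborting the batch.
#'
#' @inheritParams simulate_crime
#' @param initial_states list (or matrix rows) of nonnegative initial states.
#' @param candidates optional `"crime_equilibria"`; defaults to
#'   [crime_equilibria()] of `params`.
#' @param tol,window passed to [detect_attractor()].
#' @return A data frame with the initial coordinates and an `attractor`
#'   column.
#' @export
probe_basin <- function(params, initial_states, t_end, dt = 0.01,
                        candidates = NULL, tol = 1e-4, window = 0.1) {
  p <- validate_params(params)
  if (is.matrix(initial_states))
    initial_states <- lapply(seq_len(nrow(initial_states)),
                             function(i) initial_states[i, ])
  if (is.null(candidates)) candidates <- crime_equilibria(p)
  rows <- lapply(initial_states, function(s0) {
    s0 <- as_state(s0)
    lab <- tryCatch(
      detect_attractor(simulate_crime(p, s0, t_end = t_end, dt = dt),
                       candidates, tol = tol, window = window),
      error = function(e) paste0("error: ", conditionMessage(e)))
    data.frame(G0 = s0[["G"]], J0 = s0[["J"]], C0 = s0[["C"]], P0 = s0[["P"]],
               attractor = lab)
  })
  do.call(rbind, rows)
}
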