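#' Critical values of the gang growth parameter alpha
#'
#' With alpha as the bifurcation parameter, `R0 = alpha eta sigma/(gamma
#' delta)` is linear in alpha while the thresholds `r`, `r1`, `r2` do not
#' depend on it, so inverting `R0(alpha) = target` is exact:
#' `alpha = target * gamma delta/(eta sigma)`. The targets are
#' \itemize{
#' \item transcritical (crime-free state exchanges stability): `1` (case 1
#'   and case 3), `1 - beta/kappa` (case 2), `r2` (case 4);
#' \item saddle-node (backward bifurcation, the endemic pair coalesces):
#'   `r` (case 3) or `r1` (case 4).
#' }
#' A threshold that is absent for the active case — or non-positive, as when
#' `beta = kappa` removes the transcritical point, or `r2 <= 0` removes the
#' bistability window — is reported as `NA` with an explanatory flag.
#'
#' @inheritParams validate_params
#' @return Object of class `"critical_alphas"`: list with `transcritical`,
#'   `saddle_node` (either may be `NA`), `case`, `no_bistability`.
#' @export
critical_alphas <- function(params) {
  p <- validate_params(params)
  case <- classify_case(p)
  th <- bifurcation_thresholds(p)
  to_alpha <- function(target) {
    if (is.na(target) || target <= 0) NA_real_
    else target * p[["gamma"]] * p[["delta"]] / (p[["eta"]] * p[["sigma"]])
  }
  trans_target <- switch(case,
                         1,                               # case 1
                         1 - p[["beta"]] / p[["kappa"]],  # case 2
                         1,                               # case 3
                         th$r2)                           # case 4
  sn_target <- switch(case, NA_real_, NA_real_, th$r, th$r1)
  structure(list(transcritical = to_alpha(trans_target),
                 saddle_node = to_alpha(sn_target),
                 case = case,
                 no_bistability = identical(th$bistability_window, FALSE)),
            class = "critical_alphas")
}

#' @export
print.critical_alphas <- function(x, ...) {
  cat("Critical alpha values (case ", x$case, "):\n", sep = "")
  cat("  transcritical:", format(x$transcritical), "\n")
  cat("  saddle-node:  ", format(x$saddle_node), "\n")
  if (x$no_bistability) cat("  (no bistability window: r2 <= 0)\n")
  invisible(x)
}

#' Sweep alpha and assemble bifurcation branches
#'
#' Computes the closed-form equilibria and their numeric stability on a grid
#' of alpha values, returning one branch per equilibrium label. The model
#' admits explicit equilibrium formulas, so no numerical continuation is
#' needed. Critical alpha values inside the range are inserted into the grid
#' exactly, so diagrams show the touching point of coalescing branches.
#' Unphysical segments (negative or complex gang density) are retained and
#' flagged rather than dropped, so the unstable/unphysical branches can be
#' drawn.
#'
#' @inheritParams validate_params
#' @param alpha_range length-2 positive interval swept (the `alpha` entry of
#'   `params` is ignored).
#' @param n_points number of uniformly spaced grid values (default 500).
#' @return Object of class `"crime_bifurcation"`: list with `branches` (data
#'   frame `label, alpha, G_star, J_star, C_star, P_star, stable, physical`),
#'   `critical` (a `"critical_alphas"`), and `params`.
#' @export
sweep_alpha <- function(params, alpha_range, n_points = 500L) {
  p <- validate_params(params)
  if (length(alpha_range) != 2 || any(alpha_range <= 0) ||
      diff(alpha_range) <= 0)
    stop("alpha_range must be a positive increasing interval", call. = FALSE)
  n_points <- as.integer(n_points)
  if (n_points < 2) stop("n_points must be >= 2", call. = FALSE)
  crit <- critical_alphas(p)
  crit_vals <- c(crit$transcritical, crit$saddle_node)
  crit_vals <- crit_vals[!is.na(crit_vals) & crit_vals > alpha_range[1] &
                           crit_vals < alpha_range[2]]
  grid <- sort(unique(c(seq(alpha_range[1], alpha_range[2],
                            length.out = n_points), crit_vals)))
  rows <- lapply(grid, function(a) {
    pa <- p; pa[["alpha"]] <- a
    eqs <- crime_equilibria(pa)
    do.call(rbind, lapply(unclass(eqs), function(eq) {
      stable <- if (anyNA(eq$coordinates)) NA else
        stability_numeric(eq, pa)$verdict == "stable"
      data.frame(label = eq$label, alpha = a,
                 G_star = eq$coordinates[["G"]],
                 J_star = eq$coordinates[["J"]],
                 C_star = eq$coordinates[["C"]],
                 P_star = eq$coordinates[["P"]],
                 stable = stable, physical = eq$physical, row.names = NULL)
    }))
  })
  branches <- do.call(rbind, rows)
  branches <- branches[order(branches$label, branches$alpha), ]
  rownames(branches) <- NULL
  structure(list(branches = branches, critical = crit, params = p),
            class = "crime_bifurcation")
}

#' @export
print.crime_bifurcation <- function(x, ...) {
  b <- x$branches
  cat("Bifurcation sweep over alpha in [", min(b$alpha), ", ", max(b$alpha),
      "]: ", length(unique(b$alpha)), " grid points, branches ",
      paste(unique(b$label), collapse = ", "), "\n", sep = "")
  print(x$critical)
  invisible(x)
}

#' Plot a bifurcation diagram
#'
#' Gang density of each equilibrium branch against alpha: solid where
#' asymptotically stable, dashed where unstable (the field's usual
#' convention). Vertical dotted guides mark the critical alpha values.
#'
#' @param x a `"crime_bifurcation"` from [sweep_alpha()].
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.crime_bifurcation <- function(x, ...) {
  b <- x$branches[!is.na(x$branches$G_star), ]
  graphics::plot(range(b$alpha), range(b$G_star), type = "n",
                 xlab = expression(alpha), ylab = "G*", ...)
  cols <- c(E0 = "black", E1 = "red", E2 = "red", E3 = "red", E4 = "orange",
            E5 = "red", E6 = "orange")
  for (lab in unique(b$label)) {
    for (st in c(TRUE, FALSE)) {
      seg <- b[b$label == lab & b$stable %in% st, ]
      if (nrow(seg))
        graphics::lines(seg$alpha, seg$G_star, lty = if (st) 1 else 2,
                        col = cols[[lab]])
    }
  }
  for (a in c(x$critical$transcritical, x$critical$saddle_node))
    if (!is.na(a)) graphics::abline(v = a, lty = 3, col = "grey40")
  invisible(x)
}

#' Export bifurcation branches as CSV
#'
#' Writes the branch table with header
#' `label,alpha,G_star,J_star,C_star,P_star,stable,physical`.
#'
#' @param bif a `"crime_bifurcation"`.
#' @param file output path.
#' @return Invisibly, the file path.
#' @export
write_branches <- function(bif, file) {
  stopifnot(inherits(bif, "crime_bifurcation"))
  utils::write.csv(bif$branches, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
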