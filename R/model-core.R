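#' Closed-form solution of the three-state fate model
#'
#' For distinct eigenvalues `l1 != l2` of the living-state matrix A, the
#' living densities follow
#' `(P, D)(t) = c1 v1 exp(l1 t) + c2 v2 exp(l2 t)`
#' with coefficients `c1, c2` fixed by the initial condition. The cumulative
#' dead density integrates the death fluxes in closed form:
#' `N(t) = N(0) + sum_i c_i (d1 v_i[P] + d2 v_i[D]) * (exp(l_i t) - 1) / l_i`
#' (with the `l_i = 0` limit `t`). The five auxiliary constants of the N(t)
#' expression (one amplitude per eigenmode for each of P, D and the
#' integrated death flux, plus the constant offset) are returned in `aux`.
#'
#' @inheritParams build_system_matrix
#' @param init A [state_vector()] with the initial densities.
#' @return An object of class `analytic_solution`: eigenvalues, eigenvectors,
#'   mode coefficients, auxiliary N(t) constants, and an `eval(times)`
#'   closure returning a data.frame with columns `day, P, D, N`.
#' @seealso [solve_ode()] for the numeric path used when the spectrum is
#'   degenerate.
#' @export
analytic_solution <- function(params, init) {
  p <- as_rate_params(params)
  y0 <- unclass(init)[c("P", "D", "N")]
  es <- eigen_system(p)
  l <- es$values
  if (abs(l[1] - l[2]) <= 1e-12 * max(1, abs(l[1]), abs(l[2]))) {
    stop(degenerate_spectrum_error(l))
  }
  V <- es$vectors
  cc <- solve(V, y0[c("P", "D")])
  # death-flux amplitude of each eigenmode: d1 * v[P] + d2 * v[D]
  w <- c(p[["d1"]], p[["d2"]])
  death_amp <- as.numeric(crossprod(w, V)) * cc
  aux <- c(P1 = cc[1] * V[1, 1], P2 = cc[2] * V[1, 2],
           D1 = cc[1] * V[2, 1], D2 = cc[2] * V[2, 2],
           N0 = unname(y0[["N"]]))
  sol <- list(
    eigenvalues = l, eigenvectors = V, coefficients = cc,
    death_amplitudes = death_amp, aux = aux, params = p, init = y0
  )
  sol$eval <- function(times) {
    e1 <- exp(l[1] * times); e2 <- exp(l[2] * times)
    h <- function(lam, e) if (abs(lam) < 1e-14) times else (e - 1) / lam
    data.frame(
      day = times,
      P = aux[["P1"]] * e1 + aux[["P2"]] * e2,
      D = aux[["D1"]] * e1 + aux[["D2"]] * e2,
      N = aux[["N0"]] + death_amp[1] * h(l[1], e1) + death_amp[2] * h(l[2], e2)
    )
  }
  class(sol) <- "analytic_solution"
  sol
}

degenerate_spectrum_error <- function(l) {
  structure(
    class = c("cellfate_degenerate_spectrum", "error", "condition"),
    list(message = sprintf(
      "repeated eigenvalue (%.6g); use the numeric integrator solve_ode()",
      l[1]), call = NULL)
  )
}

#' @export
print.analytic_solution <- function(x, ...) {
  cat(sprintf("Analytic fate-model solution: eigenvalues %.4g, %.4g\n",
              x$eigenvalues[1], x$eigenvalues[2]))
  invisible(x)
}

#' Integrate the fate-model ODEs numerically
#'
#' Solves dP/dt = (alpha - beta - d1) P + gamma D,
#' dD/dt = beta P - (gamma + d2) D, dN/dt = d1 P + d2 D with an adaptive
#' stiff-capable integrator (`deSolve::lsoda`, rtol 1e-8, atol 1e-10).
#' Tiny negative densities from round-off are clipped to zero in the
#' returned table only, never inside the solver state.
#'
#' @inheritParams analytic_solution
#' @param times Strictly increasing time grid in days starting at 0.
#' @return A `trajectory`: data.frame with columns `day, P, D, N`.
#' @export
solve_ode <- function(params, init, times) {
  p <- as_rate_params(params)
  y0 <- unclass(init)[c("P", "D", "N")]
  if (length(times) < 2 || times[1] != 0 || any(diff(times) <= 0))
    stop("times must be strictly increasing and start at 0", call. = FALSE)
  A <- build_system_matrix(p)
  rhs <- function(t, y, parms) {
    list(c(A[1, 1] * y[1] + A[1, 2] * y[2],
           A[2, 1] * y[1] + A[2, 2] * y[2],
           p[["d1"]] * y[1] + p[["d2"]] * y[2]))
  }
  out <- deSolve::lsoda(y = unname(y0), times = times, func = rhs,
                        parms = NULL, rtol = 1e-8, atol = 1e-10)
  if (any(!is.finite(out)))
    stop("numerical failure: non-finite solver output", call. = FALSE)
  traj <- data.frame(day = out[, 1],
                     P = pmax(out[, 2], 0),
                     D = pmax(out[, 3], 0),
                     N = out[, 4])
  class(traj) <- c("trajectory", "data.frame")
  traj
}

#' Model trajectory, analytic where possible
#'
#' Evaluates the closed-form solution when the spectrum is distinct and
#' falls back to numeric integration in the measure-zero repeated-eigenvalue
#' case.
#'
#' @inheritParams solve_ode
#' @return A `trajectory` data.frame (`day, P, D, N`).
#' @export
model_trajectory <- function(params, init, times) {
  sol <- tryCatch(analytic_solution(params, init),
                  cellfate_degenerate_spectrum = function(e) NULL)
  if (is.null(sol)) return(solve_ode(params, init, times))
  traj <- sol$eval(times)
  traj$P <- pmax(traj$P, 0)
  traj$D <- pmax(traj$D, 0)
  class(traj) <- c("trajectory", "data.frame")
  traj
}

#' Write a trajectory as tidy CSV
#'
#' @param traj A `trajectory` data.frame.
#' @param path Output file.
#' @param condition,replicate Optional annotation columns.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, condition = NA, replicate = NA) {
  out <- data.frame(traj, condition = condition, replicate = replicate)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
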