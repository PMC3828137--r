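#' Single-cell fate-transition rates
#'
#' Bundle the five per-cell transition rates of the three-state fate model
#' into a validated object. All rates are intensities in 1/day: `alpha`
#' (proliferation, P -> 2P), `beta` (differentiation, P -> D), `gamma`
#' (de-differentiation, D -> P), `d1` (death of proliferating cells,
#' P -> dead) and `d2` (death of differentiated cells, D -> dead).
#'
#' @param alpha,beta,gamma,d1,d2 Non-negative finite rates (1/day).
#' @return An object of class `rate_params`: a named numeric vector of
#'   length five.
#' @examples
#' rate_params(alpha = 0.6, beta = 0.05, gamma = 0.2, d1 = 0.05, d2 = 0.05)
#' @export
rate_params <- function(alpha, beta, gamma, d1, d2) {
  x <- c(alpha = unname(alpha)[1], beta = unname(beta)[1],
         gamma = unname(gamma)[1], d1 = unname(d1)[1], d2 = unname(d2)[1])
  validate_rate_params(x)
  structure(x, class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat("Cell-fate transition rates (1/day):\n")
  print(unclass(x), ...)
  invisible(x)
}

validate_rate_params <- function(x) {
  nm <- c("alpha", "beta", "gamma", "d1", "d2")
  if (!is.numeric(x) || length(x) != 5L || !all(nm %in% names(x)))
    stop("rate parameters must be five named numerics: ",
         paste(nm, collapse = ", "), call. = FALSE)
  if (any(!is.finite(x)))
    stop("rate parameters must be finite", call. = FALSE)
  if (any(x < 0))
    stop("rate parameters must be non-negative, got: ",
         paste(sprintf("%s = %g", names(x)[x < 0], x[x < 0]), collapse = ", "),
         call. = FALSE)
  invisible(x)
}

as_rate_params <- function(x) {
  x <- unlist(x)
  if (is.null(names(x)) && length(x) == 5L)
    names(x) <- c("alpha", "beta", "gamma", "d1", "d2")
  x <- x[c("alpha", "beta", "gamma", "d1", "d2")]
  validate_rate_params(x)
  structure(x, class = "rate_params")
}

#' Initial state densities
#'
#' @param P,D Densities of proliferating and differentiated cells
#'   (cells/mm^2), non-negative.
#' @param N Cumulative density of dead cells (cells/mm^2); dead cells are
#'   counted cumulatively since debris persists in the field of view.
#' @return Named numeric vector of class `state_vector`.
#' @export
state_vector <- function(P, D = 0, N = 0) {
  x <- c(P = unname(P)[1], D = unname(D)[1], N = unname(N)[1])
  if (any(!is.finite(x)) || any(x < 0))
    stop("state densities must be finite and non-negative", call. = FALSE)
  structure(x, class = "state_vector")
}

#' Linear system matrix of the living states
#'
#' The dynamics of the living states (P, D) are linear,
#' d/dt (P, D) = A (P, D), with
#' `A = [[alpha - beta - d1, gamma], [beta, -(gamma + d2)]]`.
#' A has non-negative off-diagonal entries (a Metzler matrix), so its
#' eigenvalues are always real for non-negative rates.
#'
#' @param params A [rate_params()] object.
#' @return A 2x2 numeric matrix with dimnames `c("P", "D")`.
#' @export
build_system_matrix <- function(params) {
  p <- as_rate_params(params)
  matrix(c(p[["alpha"]] - p[["beta"]] - p[["d1"]], p[["beta"]],
           p[["gamma"]], -(p[["gamma"]] + p[["d2"]])),
         nrow = 2, dimnames = list(c("P", "D"), c("P", "D")))
}

# Closed-form eigenvalues of the 2x2 system matrix. The discriminant
# (tr A)^2 - 4 det A = (a11 - a22)^2 + 4 beta gamma >= 0, so roots are real.
eigen_system <- function(params) {
  A <- build_system_matrix(params)
  tr <- A[1, 1] + A[2, 2]
  det <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  disc <- tr^2 - 4 * det
  disc <- max(disc, 0)  # guaranteed >= 0 analytically; guard round-off
  s <- sqrt(disc)
  lambda <- c((tr + s) / 2, (tr - s) / 2)
  vec <- function(l) {
    # eigenvector of A for eigenvalue l; pick the numerically stable row
    if (abs(A[1, 2]) >= abs(A[2, 1])) v <- c(A[1, 2], l - A[1, 1])
    else v <- c(l - A[2, 2], A[2, 1])
    if (max(abs(v)) == 0) v <- c(1, 0)  # diagonal matrix case
    v / sqrt(sum(v^2))
  }
  list(A = A, trace = tr, det = det, discriminant = disc,
       values = lambda, vectors = cbind(vec(lambda[1]), vec(lambda[2])))
}

#' Malthus coefficient (asymptotic population growth rate)
#'
#' The dominant eigenvalue of the living-state system matrix. The number of
#' surviving cells asymptotically grows like `exp(lambda_M * t)`: a positive
#' value means unbounded growth, a negative one extinction.
#'
#' @inheritParams build_system_matrix
#' @return Growth rate in 1/day.
#' @export
malthus_coefficient <- function(params) {
  max(eigen_system(params)$values)
}

#' Classify the critical point of the living-state dynamics
#'
#' For non-negative rates the discriminant of the characteristic equation is
#' always non-negative, so the origin is never a centre or spiral: it is an
#' asymptotically stable node (both eigenvalues negative: the population goes
#' extinct), a saddle (opposite signs: unbounded growth along the dominant
#' direction), or a degenerate case with a zero eigenvalue.
#'
#' @inheritParams build_system_matrix
#' @return A list with class `critical_point` carrying the trace `p`,
#'   determinant `q`, `discriminant`, `eigenvalues`, and a `label` in
#'   `c("stable_node", "saddle", "degenerate")`.
#' @export
classify_critical_point <- function(params) {
  es <- eigen_system(params)
  l <- es$values
  label <- if (all(l < 0)) "stable_node"
  else if (max(l) > 0 && min(l) < 0) "saddle"
  else if (any(l == 0)) "degenerate"
  else "unstable_node"  # both > 0: alpha dominates every loss term
  structure(list(p = es$trace, q = es$det, discriminant = es$discriminant,
                 eigenvalues = l, label = label),
            class = "critical_point")
}

#' @export
print.critical_point <- function(x, ...) {
  cat(sprintf("Critical point: %s (eigenvalues %.4g, %.4g; discriminant %.4g)\n",
              x$label, x$eigenvalues[1], x$eigenvalues[2], x$discriminant))
  invisible(x)
}
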