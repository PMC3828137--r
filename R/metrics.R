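#' Shannon entropy of the fate fractions
#'
#' Heterogeneity of a population split into proliferating, differentiated
#' and dead fractions: `S = -sum p_i log p_i` with `0 log 0 = 0`. With the
#' natural logarithm (default) S ranges from 0 (homogeneous population) to
#' `log(3)` for the uniform three-way split; the two-state even split gives
#' `log(2)`.
#'
#' @param frac Numeric vector of three fractions summing to 1.
#' @param base Logarithm base; `exp(1)` (nats) by default.
#' @return Entropy (nats by default).
#' @examples
#' shannon_entropy(c(1, 0, 0))          # 0
#' shannon_entropy(rep(1, 3) / 3)       # log(3)
#' @export
shannon_entropy <- function(frac, base = exp(1)) {
  if (!is.numeric(frac) || length(frac) != 3L || any(!is.finite(frac)))
    stop("frac must be three finite numbers", call. = FALSE)
  if (any(frac < -1e-12) || abs(sum(frac) - 1) > 1e-8)
    stop("fractions must be non-negative and sum to 1", call. = FALSE)
  p <- pmax(frac, 0)
  nz <- p > 0
  -sum(p[nz] * log(p[nz], base = base))
}

#' Entropy time course of a trajectory
#'
#' Converts each row of a trajectory to fate fractions
#' `(P, D, N) / (P + D + N)` and applies [shannon_entropy()].
#'
#' @param traj A `trajectory` data.frame with columns `day, P, D, N`.
#' @inheritParams shannon_entropy
#' @return data.frame with columns `day`, `S`.
#' @export
entropy_timecourse <- function(traj, base = exp(1)) {
  tot <- traj$P + traj$D + traj$N
  if (any(tot <= 0))
    stop("fractions undefined: P + D + N must be positive at every time",
         call. = FALSE)
  S <- vapply(seq_len(nrow(traj)), function(i)
    shannon_entropy(c(traj$P[i], traj$D[i], traj$N[i]) / tot[i], base = base),
    numeric(1))
  data.frame(day = traj$day, S = S)
}

#' Initial net fluxes of the three states
#'
#' The instantaneous rates of change of the three densities at t = 0: the
#' right-hand sides of the model ODEs evaluated at the initial condition.
#' `JN >= 0` always, since the dead flux is `d1 P + d2 D`.
#'
#' @inheritParams analytic_solution
#' @return A `flux_set`: named numeric `c(JP, JD, JN)` in cells/mm^2/day,
#'   with attribute `flavor = "initial"`.
#' @export
initial_flux <- function(params, init) {
  p <- as_rate_params(params)
  y <- unclass(init)
  JP <- (p[["alpha"]] - p[["beta"]] - p[["d1"]]) * y[["P"]] + p[["gamma"]] * y[["D"]]
  JD <- p[["beta"]] * y[["P"]] - (p[["gamma"]] + p[["d2"]]) * y[["D"]]
  JN <- p[["d1"]] * y[["P"]] + p[["d2"]] * y[["D"]]
  structure(c(JP = unname(JP), JD = unname(JD), JN = unname(JN)),
            flavor = "initial", class = "flux_set")
}

#' Time-averaged net fluxes over the experiment horizon
#'
#' `(1/T) * integral_0^T J_X(t) dt`, which for any dynamics equals
#' `(X(T) - X(0)) / T`. The default horizon of 5 days matches the length of
#' a culture experiment before confluence.
#'
#' @inheritParams analytic_solution
#' @param T_horizon Averaging horizon in days (> 0).
#' @return A `flux_set` with attribute `flavor = "mean"` and `T = T_horizon`.
#' @export
mean_flux <- function(params, init, T_horizon = 5) {
  if (!is.finite(T_horizon) || T_horizon <= 0)
    stop("T_horizon must be positive", call. = FALSE)
  traj <- model_trajectory(params, init, times = c(0, T_horizon))
  y0 <- traj[1, ]; y1 <- traj[2, ]
  structure(c(JP = (y1$P - y0$P) / T_horizon,
              JD = (y1$D - y0$D) / T_horizon,
              JN = (y1$N - y0$N) / T_horizon),
            flavor = "mean", T = T_horizon, class = "flux_set")
}

#' @export
print.flux_set <- function(x, ...) {
  cat(sprintf("Net fluxes (%s; cells/mm^2/day):\n", attr(x, "flavor")))
  print(unclass(x)[1:3], ...)
  invisible(x)
}

#' Growth-factor response indices
#'
#' Compares a stimulated condition against its matched control through the
#' Malthus coefficient and the initial and time-averaged fluxes. Two
#' normalisations are provided: `"ratio"` (stimulus / control, neutral value
#' 1) and `"difference"` (stimulus - control, neutral value 0). Indices with
#' a zero control denominator are reported as `NA`, never as infinity.
#'
#' @param params_gf Rates under the growth-factor stimulus.
#' @param params_ctl Rates under the matched control.
#' @param init Shared initial condition.
#' @param T_horizon Horizon for the mean-flux indices (days).
#' @param normalization `"ratio"` (default) or `"difference"`.
#' @return A `response_indices` list: `R_lambda`, `R_J0` (named JP/JD/JN),
#'   `R_Jmean` (named JP/JD/JN), plus the normalisation used.
#' @export
response_indices <- function(params_gf, params_ctl, init, T_horizon = 5,
                             normalization = c("ratio", "difference")) {
  normalization <- match.arg(normalization)
  norm <- function(gf, ctl) {
    if (normalization == "difference") return(unname(gf - ctl))
    unname(ifelse(abs(ctl) < .Machine$double.eps^0.75, NA_real_, gf / ctl))
  }
  lam <- c(malthus_coefficient(params_gf), malthus_coefficient(params_ctl))
  J0 <- list(gf = initial_flux(params_gf, init),
             ctl = initial_flux(params_ctl, init))
  Jm <- list(gf = mean_flux(params_gf, init, T_horizon),
             ctl = mean_flux(params_ctl, init, T_horizon))
  r <- list(
    R_lambda = norm(lam[1], lam[2]),
    R_J0 = stats::setNames(norm(unclass(J0$gf)[1:3], unclass(J0$ctl)[1:3]),
                           c("JP", "JD", "JN")),
    R_Jmean = stats::setNames(norm(unclass(Jm$gf)[1:3], unclass(Jm$ctl)[1:3]),
                              c("JP", "JD", "JN")),
    normalization = normalization, T_horizon = T_horizon
  )
  class(r) <- "response_indices"
  r
}

#' @export
print.response_indices <- function(x, ...) {
  cat(sprintf("Growth-factor response indices (%s normalisation):\n",
              x$normalization))
  cat(sprintf("  R_lambda: %.4g\n", x$R_lambda))
  cat("  R_J0:   "); print(x$R_J0)
  cat("  R_Jmean:"); print(x$R_Jmean)
  invisible(x)
}

#' Cohen's d with mean-of-SDs pooling
#'
#' Standardised mean difference `(mean_a - mean_b) / s` where the default
#' denominator is the arithmetic mean of the two group standard deviations.
#' The classic variance-pooled denominator is available via
#' `pooling = "classic"`.
#'
#' @param group_a,group_b Numeric samples, each of size >= 2.
#' @param pooling `"mean_sd"` (default) or `"classic"`.
#' @return Effect size (dimensionless); `NA` with a warning if the pooled
#'   SD is zero.
#' @export
cohens_d <- function(group_a, group_b, pooling = c("mean_sd", "classic")) {
  pooling <- match.arg(pooling)
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 values", call. = FALSE)
  sa <- sd(group_a); sb <- sd(group_b)
  s <- if (pooling == "mean_sd") (sa + sb) / 2
  else {
    na <- length(group_a); nb <- length(group_b)
    sqrt(((na - 1) * sa^2 + (nb - 1) * sb^2) / (na + nb - 2))
  }
  if (s == 0) {
    warning("zero pooled SD: effect size undefined", call. = FALSE)
    return(NA_real_)
  }
  (mean(group_a) - mean(group_b)) / s
}

#' Eta-squared effect size for K groups
#'
#' `eta^2 = S_B / S_T`: between-group sum of squares over the total sum of
#' squares about the grand mean. Always in \[0, 1\] when defined; `NA` when
#' all values are identical (`S_T = 0`).
#'
#' @param groups A list of K >= 2 numeric vectors of repeated measurements.
#' @return Effect size in \[0, 1\], or `NA` if the total sum of squares is 0.
#' @export
eta_squared <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("groups must be a list of at least two samples", call. = FALSE)
  all_v <- unlist(groups)
  grand <- mean(all_v)
  s_t <- sum((all_v - grand)^2)
  if (s_t == 0) {
    warning("zero total sum of squares: eta^2 undefined", call. = FALSE)
    return(NA_real_)
  }
  s_b <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1)))
  s_b / s_t
}
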