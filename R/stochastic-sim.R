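#' Exact stochastic simulation of the fate scheme
#'
#' Samples one realisation of the five-reaction continuous-time Markov jump
#' process (P -> 2P, P -> D, D -> P, and the two death channels, which
#' increment the cumulative dead count N) with the Gillespie algorithm.
#' The boundary at zero living cells is absorbing: once P + D = 0 the path
#' stays at (0, 0, N).
#'
#' Randomness comes from R's global RNG, so paths are reproducible after
#' `set.seed()`.
#'
#' @inheritParams build_system_matrix
#' @param init Integer initial counts `c(P, D, N)`, non-negative.
#' @param times Increasing output times in days (for `record = "grid"`).
#' @param record `"grid"` samples the path at `times`; `"events"` returns
#'   the full jump path up to `t_max`.
#' @param t_max,max_events Limits for `record = "events"`.
#' @return For `"grid"`: data.frame `day, P, D, N`. For `"events"`:
#'   data.frame `time, P, D, N` with one row per event (first row is the
#'   initial state).
#' @export
gillespie_run <- function(params, init, times = 0:7,
                          record = c("grid", "events"),
                          t_max = max(times), max_events = 1e7) {
  record <- match.arg(record)
  p <- as_rate_params(params)
  init <- as.integer(round(init))
  if (length(init) != 3L || any(init < 0))
    stop("init must be three non-negative integer counts (P, D, N)",
         call. = FALSE)
  if (record == "events") {
    out <- ssa_fate_events(unclass(p), init, t_max, as.integer(max_events))
    return(as.data.frame(out))
  }
  m <- ssa_fate_path(unclass(p), init, as.numeric(times))
  data.frame(day = times, P = m[, 1], D = m[, 2], N = m[, 3])
}

#' Model-variant configuration for ensemble simulation
#'
#' The four variants cross two dispersal assumptions: whether the five
#' transition rates are constant across runs or drawn per run from a
#' truncated normal centred on the base rates, and whether the initial
#' counts are constant or drawn per run from a lognormal distribution.
#' Variant 1 = (constant rates, lognormal initials), 2 = (truncated-normal
#' rates, constant initials), 3 = (truncated-normal, lognormal),
#' 4 = (constant, constant).
#'
#' @param variant Integer 1-4, or `NULL` to give the modes directly.
#' @param param_mode,init_mode `"constant"`, `"truncated_normal"` /
#'   `"lognormal"`; ignored when `variant` is given.
#' @param tn_scale_frac Truncated-normal scale as a fraction of each base
#'   rate (location); default 0.2.
#' @param init_log_sd Log-scale SD of the lognormal initial-count draw;
#'   default 0.2 (a ~20% field-to-field coefficient of variation, the
#'   regime in which initial-condition dispersal and demographic noise are
#'   comparable at tens of cells per field). The log-mean is set per state
#'   so the draw's expectation equals the base initial count.
#' @return A `variant_config` list.
#' @export
variant_config <- function(variant = 1, param_mode = NULL, init_mode = NULL,
                           tn_scale_frac = 0.2, init_log_sd = 0.2) {
  if (!is.null(variant)) {
    stopifnot(variant %in% 1:4)
    param_mode <- c("constant", "truncated_normal", "truncated_normal",
                    "constant")[variant]
    init_mode <- c("lognormal", "constant", "lognormal", "constant")[variant]
  } else {
    param_mode <- match.arg(param_mode, c("constant", "truncated_normal"))
    init_mode <- match.arg(init_mode, c("constant", "lognormal"))
    variant <- if (param_mode == "constant") {
      if (init_mode == "lognormal") 1L else 4L
    } else {
      if (init_mode == "constant") 2L else 3L
    }
  }
  structure(list(variant = as.integer(variant), param_mode = param_mode,
                 init_mode = init_mode, tn_scale_frac = tn_scale_frac,
                 init_log_sd = init_log_sd),
            class = "variant_config")
}

#' Truncated-normal sampler on the non-negative reals
#'
#' Draws from a normal(location, scale) restricted to `[0, Inf)` and
#' renormalised, by inverse-CDF sampling (exact, no rejection).
#'
#' @param n Number of draws.
#' @param location,scale Location and scale of the parent normal; scale > 0.
#' @return Non-negative numeric vector of length `n`.
#' @export
sample_truncated_normal <- function(n, location, scale) {
  if (any(scale <= 0)) stop("scale must be positive", call. = FALSE)
  lo <- pnorm(0, mean = location, sd = scale)
  qnorm(lo + runif(n) * (1 - lo), mean = location, sd = scale)
}

#' Lognormal initial-condition sampler
#'
#' `exp` of a normal(log_mean, log_sd) draw; `log_sd = 0` degenerates to
#' the constant `exp(log_mean)`.
#'
#' @param n Number of draws.
#' @param log_mean,log_sd Log-scale mean and SD (`log_sd >= 0`).
#' @return Positive numeric vector.
#' @export
sample_lognormal_init <- function(n, log_mean, log_sd) {
  if (any(log_sd < 0)) stop("log_sd must be non-negative", call. = FALSE)
  exp(rnorm(n, mean = log_mean, sd = log_sd))
}

#' Closed-form lognormal mean and variance
#'
#' For `X = exp(Z)`, `Z ~ N(log_mean, log_sd^2)`:
#' `M = exp(log_mean + log_sd^2 / 2)` and
#' `V = exp(2 log_mean + log_sd^2) (exp(log_sd^2) - 1)`.
#' With constant `log_sd`, `log V` is linear in `log M` with slope exactly 2,
#' which is why a pure lognormal family sits on the Taylor-law boundary.
#'
#' @param log_mean,log_sd Log-scale parameters (`log_sd >= 0`).
#' @return Named numeric `c(M, V)`.
#' @export
lognormal_meanvar <- function(log_mean, log_sd) {
  if (any(log_sd < 0)) stop("log_sd must be non-negative", call. = FALSE)
  s2 <- log_sd^2
  c(M = exp(log_mean + s2 / 2),
    V = exp(2 * log_mean + s2) * (exp(s2) - 1))
}

#' Simulate an ensemble of stochastic fate trajectories
#'
#' Runs `n_runs` independent Gillespie paths under a model variant,
#' drawing per-run rates and/or initial counts as the variant dictates,
#' and summarises per-day cross-run means and variances of the counts.
#' A degenerate dispersal scale (zero) falls back to constant mode with a
#' warning.
#'
#' @inheritParams gillespie_run
#' @param variant A [variant_config()] (or an integer 1-4).
#' @param n_runs Number of independent runs (>= 2).
#' @param days Output day grid.
#' @param seed Optional integer seed; `NULL` continues the current RNG
#'   stream.
#' @return A `fate_ensemble` list: `counts` (array run x day x state),
#'   `meanvar` (see [mean_var_series()]), the realised `variant`, `days`,
#'   and the base parameters.
#' @export
simulate_ensemble <- function(params, init, n_runs = 1e4, days = 0:7,
                              variant = variant_config(4), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.numeric(variant)) variant <- variant_config(variant)
  stopifnot(inherits(variant, "variant_config"), n_runs >= 2)
  p <- as_rate_params(params)
  base_init <- as.numeric(init)[1:3]

  if (variant$param_mode == "truncated_normal" && variant$tn_scale_frac <= 0) {
    warning("zero truncated-normal scale: falling back to constant rates",
            call. = FALSE)
    variant$param_mode <- "constant"
  }
  if (variant$init_mode == "lognormal" && variant$init_log_sd <= 0) {
    warning("zero lognormal log-sd: falling back to constant initials",
            call. = FALSE)
    variant$init_mode <- "constant"
  }

  rates <- matrix(rep(unclass(p), each = n_runs), nrow = n_runs)
  if (variant$param_mode == "truncated_normal") {
    for (j in 1:5) {
      if (p[[j]] > 0)
        rates[, j] <- sample_truncated_normal(n_runs, p[[j]],
                                              variant$tn_scale_frac * p[[j]])
    }
  }
  inits <- matrix(rep(round(base_init), each = n_runs), nrow = n_runs)
  if (variant$init_mode == "lognormal") {
    s <- variant$init_log_sd
    for (j in 1:3) {
      if (base_init[j] > 0) {
        lm <- log(base_init[j]) - s^2 / 2  # draw expectation = base count
        inits[, j] <- round(sample_lognormal_init(n_runs, lm, s))
      }
    }
  }
  storage.mode(inits) <- "integer"

  m <- ssa_fate_ensemble(rates, inits, as.numeric(days))
  nt <- length(days)
  counts <- array(m, dim = c(n_runs, nt, 3),
                  dimnames = list(NULL, paste0("day", days), c("P", "D", "N")))
  structure(list(counts = counts, days = days,
                 meanvar = mean_var_series(counts, days),
                 variant = variant, params = p, init = base_init),
            class = "fate_ensemble")
}

#' @export
print.fate_ensemble <- function(x, ...) {
  cat(sprintf("Stochastic fate ensemble: %d runs, days %s, variant %d (%s rates, %s initials)\n",
              dim(x$counts)[1], paste(range(x$days), collapse = "-"),
              x$variant$variant, x$variant$param_mode, x$variant$init_mode))
  invisible(x)
}

#' Per-day mean-variance series of ensemble counts
#'
#' Cross-run sample mean and unbiased variance of the counts per (day,
#' state). With `exclude_zeros = TRUE` zero counts are dropped before the
#' moments are taken (the convention used before log-log fitting, since
#' sparse early days carry many empty fields); the zeros-included moments
#' are what `exclude_zeros = FALSE` (default) reports. With
#' `lognormal_correct = TRUE` the moments are instead reconstructed from
#' the log-scale mean and SD of the non-zero counts through the closed-form
#' lognormal moments ([lognormal_meanvar()]).
#'
#' @param counts Array run x day x state (as in [simulate_ensemble()]).
#' @param days Day grid labelling the second dimension.
#' @param exclude_zeros Drop zero counts before computing moments.
#' @param lognormal_correct Reconstruct moments from log-scale fits.
#' @return data.frame `day, state, M, V, n` (n = number of values used),
#'   with attribute `zero_handling`.
#' @export
mean_var_series <- function(counts, days, exclude_zeros = FALSE,
                            lognormal_correct = FALSE) {
  states <- c("P", "D", "N")
  out <- expand.grid(day = days, state = states, stringsAsFactors = FALSE)
  out$M <- NA_real_; out$V <- NA_real_; out$n <- NA_integer_
  for (k in seq_len(nrow(out))) {
    it <- match(out$day[k], days); is <- match(out$state[k], states)
    x <- counts[, it, is]
    if (exclude_zeros || lognormal_correct) x <- x[x > 0]
    out$n[k] <- length(x)
    if (length(x) >= 2) {
      if (lognormal_correct) {
        mv <- lognormal_meanvar(mean(log(x)), sd(log(x)))
        out$M[k] <- mv[["M"]]; out$V[k] <- mv[["V"]]
      } else {
        out$M[k] <- mean(x); out$V[k] <- var(x)
      }
    } else if (length(x) == 1) {
      out$M[k] <- x; out$V[k] <- 0
    }
  }
  attr(out, "zero_handling") <-
    if (exclude_zeros || lognormal_correct) "excluded" else "included"
  out
}

#' Fit Taylor's power law V = a M^b
#'
#' Ordinary least squares of `log V` on `log M` over the points with
#' positive mean and variance (zeros carry no information on the log
#' scale and are omitted). The slope b is the index of aggregation:
#' 1 for Poisson-like counts, 2 for exponential-like (or pure lognormal
#' with constant log-variance), intermediate values in between.
#'
#' @param series data.frame with columns `M` and `V` (e.g. from
#'   [mean_var_series()]), or a `fate_ensemble`.
#' @return A `powerlaw_fit` list: `a` (intercept on the natural scale),
#'   `b` (slope), `r_squared`, `n_points`.
#' @export
fit_powerlaw <- function(series) {
  if (inherits(series, "fate_ensemble")) series <- series$meanvar
  ok <- is.finite(series$M) & is.finite(series$V) & series$M > 0 & series$V > 0
  if (sum(ok) < 3)
    stop("insufficient data: need at least 3 points with M > 0 and V > 0",
         call. = FALSE)
  fit <- lm(log(V) ~ log(M), data = series[ok, ])
  lv <- log(series$V[ok])
  r2 <- 1 - sum(residuals(fit)^2) / sum((lv - mean(lv))^2)
  structure(list(a = unname(exp(coef(fit)[1])), b = unname(coef(fit)[2]),
                 r_squared = r2, n_points = sum(ok)),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("Taylor power law V = a M^b: a = %.4g, b = %.4g (R^2 = %.4f, n = %d)\n",
              x$a, x$b, x$r_squared, x$n_points))
  invisible(x)
}

#' Fit a lognormal to positive counts
#'
#' Moments of the log of the positive samples, plus a Shapiro-Wilk
#' normality statistic on the log scale (on a subsample of at most 5000
#' values, the test's supported range).
#'
#' @param samples Numeric counts; zeros and negatives are dropped.
#' @return List `log_mean`, `log_sd`, `shapiro_w`, `shapiro_p`, `n`.
#' @export
fit_lognormal <- function(samples) {
  x <- samples[is.finite(samples) & samples > 0]
  if (length(x) < 10)
    stop("need at least 10 positive samples", call. = FALSE)
  lx <- log(x)
  sub <- if (length(lx) > 5000) lx[seq(1, length(lx), length.out = 5000)] else lx
  sw <- if (sd(sub) > 0) shapiro.test(sub) else list(statistic = NA, p.value = NA)
  list(log_mean = mean(lx), log_sd = sd(lx),
       shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value,
       n = length(x))
}

#' Closed-form moments of the linear birth-death process
#'
#' For birth rate `lambda`, death rate `mu` and initial count `n0`:
#' `M(t) = n0 exp((lambda - mu) t)` and
#' `V(t) = n0 (lambda + mu)/(lambda - mu) exp((lambda - mu) t)
#' (exp((lambda - mu) t) - 1)`; the equal-rate limit is `M = n0`,
#' `V = 2 lambda n0 t`.
#'
#' @param lambda,mu Birth and death rates (1/day), non-negative.
#' @param n0 Positive integer initial count.
#' @param t Time(s) in days.
#' @return data.frame `t, M, V`.
#' @export
birthdeath_moments <- function(lambda, mu, n0, t) {
  stopifnot(lambda >= 0, mu >= 0, n0 >= 1)
  r <- lambda - mu
  if (abs(r) < 1e-12) {
    M <- rep(n0, length(t))
    V <- 2 * lambda * n0 * t
  } else {
    e <- exp(r * t)
    M <- n0 * e
    V <- n0 * (lambda + mu) / r * e * (e - 1)
  }
  data.frame(t = t, M = M, V = V)
}

#' Mean-variance slope of the birth-death process along a time sweep
#'
#' OLS slope of `log V(t)` against `log M(t)` using the closed-form
#' moments over `t_grid`. For a supercritical process (`lambda > mu`)
#' `V` is asymptotically proportional to `M^2`, so the slope tends to 2
#' at large times: a plain birth-death process cannot produce a stable
#' intermediate Taylor exponent.
#'
#' @inheritParams birthdeath_moments
#' @param t_grid At least two positive times (days).
#' @return OLS slope (dimensionless).
#' @export
birthdeath_powerlaw_slope <- function(lambda, mu, n0, t_grid) {
  if (lambda <= mu) stop("requires lambda > mu (growing population)",
                         call. = FALSE)
  if (length(t_grid) < 2)
    stop("insufficient data: need at least two time points", call. = FALSE)
  mom <- birthdeath_moments(lambda, mu, n0, t_grid)
  ok <- mom$M > 0 & mom$V > 0
  if (sum(ok) < 2) stop("insufficient positive-moment points", call. = FALSE)
  unname(coef(lm(log(V) ~ log(M), data = mom[ok, ]))[2])
}
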