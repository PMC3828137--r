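#' Observation model linking densities to image counts
#'
#' Observed counts are modelled as `C * density + noise`, where `C`
#' (cells-per-image per cells/mm^2, i.e. the effective imaged area) converts
#' the mean density into the expected count in one microscope image, and
#' the noise is i.i.d. Gaussian with SD `sigma` on the count scale, shared
#' across states and days.
#'
#' @param C Positive unit-conversion constant.
#' @param sigma Positive observation-noise SD (counts), or `NULL` to derive
#'   it from the data at fit time as 10% of the day-0 total mean count.
#' @return An `observation_model` list.
#' @export
observation_model <- function(C = 1, sigma = NULL) {
  if (!is.finite(C) || C <= 0) stop("C must be positive", call. = FALSE)
  if (!is.null(sigma) && (!is.finite(sigma) || sigma <= 0))
    stop("sigma must be positive", call. = FALSE)
  structure(list(C = C, sigma = sigma), class = "observation_model")
}

#' Independent gamma priors on the five transition rates
#'
#' Rates are non-negative by construction, so each gets an independent
#' gamma prior. The default `shape = 1`, `scale = 10` is a broad
#' exponential whose support includes zero; much larger scales leave the
#' estimates essentially unchanged.
#'
#' @param shape,scale Positive scalars or length-5 vectors (recycled),
#'   ordered `alpha, beta, gamma, d1, d2`.
#' @return A `gamma_prior` list with length-5 `shape` and `scale`.
#' @export
gamma_prior <- function(shape = 1, scale = 10) {
  shape <- rep_len(shape, 5); scale <- rep_len(scale, 5)
  if (any(shape <= 0) || any(scale <= 0))
    stop("shape and scale must be positive", call. = FALSE)
  structure(list(shape = shape, scale = scale), class = "gamma_prior")
}

#' Four-phase simulated-annealing schedule
#'
#' The tempered random-walk Metropolis sampler runs in four phases:
#' (1) cool from `T0` down to temperature 1 (geometric cooling across
#' `steps_1` temperature steps) to explore broadly; (2) hold at temperature
#' 1, which is plain Metropolis sampling of the posterior; (3) cool from 1
#' to `T_final < 1` to sharpen onto the posterior mode; (4) hold at
#' `T_final`, recording the best-likelihood parameter set in each of
#' `segments_4` equal segments. The final estimate averages those best
#' sets.
#'
#' @param T0 Initial temperature (default 100).
#' @param T_final Final temperature (< 1; default 0.1). With
#'   `auto_T_final = TRUE` it is then halved until the mean phase-4 best
#'   log-likelihood stops improving by at least 0.1 (the saturation rule).
#' @param n1,n2,n3,n4 Proposals per phase (defaults 2000/2000/2000/4000).
#' @param steps_1,steps_3 Temperature steps within the cooling phases.
#' @param segments_4 Phase-4 segments whose best-likelihood parameter sets
#'   are averaged into the estimate.
#' @param tau Fixed additive proposal SD per parameter (length 5 or
#'   scalar) for a plain symmetric random-walk kernel, or `NULL` (default)
#'   for the adaptively tuned log-scale kernel (see [run_annealed_mcmc()]).
#' @param auto_T_final Apply the saturation rule for `T_final`.
#' @return An `annealing_schedule` list.
#' @export
annealing_schedule <- function(T0 = 100, T_final = 0.1,
                               n1 = 2000, n2 = 2000, n3 = 2000, n4 = 4000,
                               steps_1 = 20, steps_3 = 20, segments_4 = 10,
                               tau = NULL, auto_T_final = TRUE) {
  stopifnot(T0 >= 1, T_final > 0, T_final < 1,
            n1 > 0, n2 > 0, n3 > 0, n4 > 0)
  if (!is.null(tau)) {
    tau <- rep_len(tau, 5)
    if (any(tau <= 0)) stop("tau must be positive", call. = FALSE)
  }
  structure(list(T0 = T0, T_final = T_final, n1 = n1, n2 = n2, n3 = n3,
                 n4 = n4, steps_1 = steps_1, steps_3 = steps_3,
                 segments_4 = segments_4, tau = tau,
                 auto_T_final = auto_T_final),
            class = "annealing_schedule")
}

# Fast closed-form densities at the observation days (numeric fallback for
# the measure-zero degenerate spectrum). Returns matrix [n_times x 3].
predict_densities <- function(params, init, times) {
  es <- eigen_system(params)
  l <- es$values
  y0 <- as.numeric(init)[1:3]
  if (abs(l[1] - l[2]) <= 1e-10 * max(1, abs(l[1]))) {
    traj <- solve_ode(as_rate_params(params), state_vector(y0[1], y0[2], y0[3]),
                      if (times[1] == 0) times else c(0, times))
    keep <- match(times, traj$day)
    return(as.matrix(traj[keep, c("P", "D", "N")]))
  }
  V <- es$vectors
  cc <- solve(V, y0[1:2])
  w <- c(params[["d1"]], params[["d2"]])
  damp <- as.numeric(crossprod(w, V)) * cc
  e1 <- exp(l[1] * times); e2 <- exp(l[2] * times)
  h1 <- if (abs(l[1]) < 1e-14) times else (e1 - 1) / l[1]
  h2 <- if (abs(l[2]) < 1e-14) times else (e2 - 1) / l[2]
  cbind(P = cc[1] * V[1, 1] * e1 + cc[2] * V[1, 2] * e2,
        D = cc[1] * V[2, 1] * e1 + cc[2] * V[2, 2] * e2,
        N = y0[3] + damp[1] * h1 + damp[2] * h2)
}

#' Estimate initial densities directly from the day-0 counts
#'
#' The initial condition is not sampled: it is the day-0 mean count of each
#' state divided by the conversion constant `C`.
#'
#' @param counts A [count_table()] including day-0 rows.
#' @param obs An [observation_model()].
#' @return A [state_vector()].
#' @export
estimate_initial_conditions <- function(counts, obs = observation_model()) {
  if (!any(counts$day == 0))
    stop("count table has no day-0 rows", call. = FALSE)
  m <- count_day_means(counts)
  y <- m["0", ] / obs$C
  state_vector(P = unname(y["P"]), D = unname(y["D"]), N = unname(y["N"]))
}

# Internal: resolve data representation for the likelihood.
likelihood_data <- function(counts, obs, mode) {
  days <- sort(unique(counts$day))
  if (days[1] != 0)
    stop("count table must include day 0", call. = FALSE)
  if (mode == "day_mean") {
    y <- count_day_means(counts)           # [n_days x 3]
    list(days = days, obs_mat = y, weights = matrix(1, nrow(y), 3))
  } else {
    # all per-field counts, grouped by (day, state)
    list(days = days, per_field = counts)
  }
}

#' Gaussian log-likelihood of a count table under the fate model
#'
#' The model densities at the observed days are converted to expected
#' counts through `C` and compared with the observed counts under i.i.d.
#' Gaussian noise of SD `sigma`. By default the data enter as per-day mean
#' counts (3 states x n days); `mode = "per_field"` uses every per-field
#' count instead.
#'
#' @inheritParams estimate_initial_conditions
#' @param params A [rate_params()] (or named numeric of the five rates).
#' @param init Initial [state_vector()]; defaults to
#'   [estimate_initial_conditions()].
#' @param mode `"day_mean"` (default) or `"per_field"`.
#' @return Log-likelihood (scalar).
#' @export
log_likelihood <- function(params, counts, obs = observation_model(),
                           init = estimate_initial_conditions(counts, obs),
                           mode = c("day_mean", "per_field")) {
  mode <- match.arg(mode)
  p <- as_rate_params(params)
  sigma <- obs$sigma
  if (is.null(sigma)) sigma <- default_sigma(counts)
  ld <- likelihood_data(counts, obs, mode)
  pred <- predict_densities(p, unclass(init), ld$days) * obs$C
  if (mode == "day_mean") {
    sum(dnorm(ld$obs_mat, mean = pred, sd = sigma, log = TRUE))
  } else {
    pf <- ld$per_field
    idx <- cbind(match(pf$day, ld$days), match(pf$state, c("P", "D", "N")))
    sum(dnorm(pf$count, mean = pred[idx], sd = sigma, log = TRUE))
  }
}

# sigma convention: 10% of the day-0 total mean count.
default_sigma <- function(counts) {
  if (!any(counts$day == 0))
    stop("count table has no day-0 rows", call. = FALSE)
  m <- count_day_means(counts)
  s <- 0.1 * sum(m["0", ])
  if (!is.finite(s) || s <= 0) s <- 1
  s
}

#' Unnormalised log-posterior of the transition rates
#'
#' Log-likelihood plus the independent gamma log-prior densities; the
#' marginal-likelihood normaliser is omitted. Any negative rate is outside
#' the prior support and returns `-Inf`.
#'
#' @inheritParams log_likelihood
#' @param prior A [gamma_prior()].
#' @return Unnormalised log-posterior (scalar, possibly `-Inf`).
#' @export
log_posterior <- function(params, counts, obs = observation_model(),
                          init = estimate_initial_conditions(counts, obs),
                          prior = gamma_prior(),
                          mode = c("day_mean", "per_field")) {
  x <- as.numeric(params)
  if (any(x < 0) || any(!is.finite(x))) return(-Inf)
  lp <- sum(dgamma(x, shape = prior$shape, scale = prior$scale, log = TRUE))
  if (!is.finite(lp)) return(-Inf)
  lp + log_likelihood(params, counts, obs, init, mode)
}

#' Symmetric random-walk proposal
#'
#' Adds independent Gaussian perturbations of SD `tau` to the current
#' parameter vector. The density is symmetric in (current, candidate), so
#' the Hastings correction cancels. Negative candidates are not reflected
#' here; they fall outside the prior support and are rejected by the
#' acceptance step.
#'
#' @param current Numeric parameter vector.
#' @param tau Positive proposal SD(s), recycled to `length(current)`.
#' @return Candidate vector of the same length.
#' @export
propose <- function(current, tau) {
  tau <- rep_len(tau, length(current))
  if (any(tau < 0)) stop("tau must be non-negative", call. = FALSE)
  current + rnorm(length(current), 0, tau)
}

#' Tempered Metropolis acceptance decision
#'
#' Accept with probability `min(1, exp((lp_candidate - lp_current) / T))`.
#' Temperature 1 recovers plain Metropolis sampling; lower temperatures
#' sharpen the target onto its mode.
#'
#' @param lp_candidate,lp_current Unnormalised log-posterior values.
#' @param temperature Positive temperature.
#' @return Logical: accept the candidate?
#' @export
annealed_accept <- function(lp_candidate, lp_current, temperature) {
  stopifnot(temperature > 0)
  if (lp_candidate == -Inf) return(FALSE)
  if (lp_candidate >= lp_current) return(TRUE)
  log(runif(1)) < (lp_candidate - lp_current) / temperature
}

#' Estimate transition rates by annealed random-walk MCMC
#'
#' Runs the four-phase tempered Metropolis sampler (see
#' [annealing_schedule()]) on the posterior of the five transition rates
#' given a count table. The point estimate averages the best-likelihood
#' parameter sets recorded in each phase-4 segment. Fully reproducible
#' given `seed`.
#'
#' By default the chain moves by a multiplicative (log-scale) random walk
#' with the Hastings factor of the asymmetric kernel included: rates span
#' orders of magnitude, must stay positive, and the fast-exchange direction
#' (large beta and gamma with a fixed ratio) is traversed efficiently on
#' the log scale. The log-step SD is tuned toward 30% acceptance by
#' diminishing adaptation during phases 1-2 and frozen afterwards. Giving
#' `schedule$tau` instead selects the plain additive symmetric walk of
#' [propose()] with that fixed step SD throughout.
#'
#' @inheritParams log_likelihood
#' @param prior A [gamma_prior()].
#' @param schedule An [annealing_schedule()].
#' @param seed Integer RNG seed.
#' @param init_params Starting rate vector (default: all rates 0.5/day).
#' @return A `posterior_result` list: `estimate` ([rate_params()]),
#'   `chain` (data.frame: step, phase, temperature, the five rates,
#'   loglik, logpost, accepted), `best_sets` (phase-4 best-likelihood
#'   parameter sets, one row per segment), `acceptance` (rate per phase),
#'   `tau` (the frozen proposal step SD: log-scale when adaptive, additive
#'   when `schedule$tau` was given), `T_final_used`, `converged`, `seed`,
#'   `init` and `sigma` used.
#' @export
run_annealed_mcmc <- function(counts, obs = observation_model(),
                              prior = gamma_prior(),
                              schedule = annealing_schedule(),
                              seed = 1L,
                              init_params = rep(0.5, 5),
                              mode = c("day_mean", "per_field")) {
  mode <- match.arg(mode)
  set.seed(seed)
  if (is.null(obs$sigma)) obs$sigma <- default_sigma(counts)
  init <- estimate_initial_conditions(counts, obs)
  ld_days <- sort(unique(counts$day))
  if (ld_days[1] != 0) stop("count table must include day 0", call. = FALSE)

  # closed-over fast posterior
  obs_stat <- likelihood_data(counts, obs, mode)
  y0 <- unclass(init)
  lpost <- function(x) {
    if (any(x < 0) || any(!is.finite(x))) return(c(-Inf, -Inf))
    lp <- sum(dgamma(x, shape = prior$shape, scale = prior$scale, log = TRUE))
    pred <- predict_densities(stats::setNames(x, c("alpha", "beta", "gamma", "d1", "d2")),
                              y0, obs_stat$days) * obs$C
    ll <- if (mode == "day_mean") {
      sum(dnorm(obs_stat$obs_mat, mean = pred, sd = obs$sigma, log = TRUE))
    } else {
      pf <- obs_stat$per_field
      idx <- cbind(match(pf$day, obs_stat$days),
                   match(pf$state, c("P", "D", "N")))
      sum(dnorm(pf$count, mean = pred[idx], sd = obs$sigma, log = TRUE))
    }
    c(ll + lp, ll)
  }

  x <- pmax(as.numeric(init_params), 1e-6)
  cur <- lpost(x)
  if (!is.finite(cur[1]))
    stop("initial parameters have zero posterior density", call. = FALSE)

  adapt <- is.null(schedule$tau)
  tau <- if (adapt) pmax(0.25 * pmax(x, 0.02), 1e-4) else schedule$tau
  target_acc <- 0.3

  n_streams <- 4L
  n1_stream <- ceiling(schedule$n1 / schedule$steps_1 / n_streams)
  total <- schedule$steps_1 * n1_stream * n_streams +
    20 * ceiling(schedule$n2 / 20) +
    schedule$steps_3 * ceiling(schedule$n3 / schedule$steps_3) +
    schedule$segments_4 * ceiling(schedule$n4 / schedule$segments_4)
  chain <- matrix(NA_real_, total, 10)
  colnames(chain) <- c("step", "phase", "temperature", "alpha", "beta",
                       "gamma", "d1", "d2", "loglik", "accepted")
  step <- 0L
  acc_by_phase <- numeric(4)

  # Default kernel: multiplicative (log-scale) random walk with the
  # Hastings factor of the asymmetric proposal. It traverses orders of
  # magnitude (rates span decades and must stay positive) and mixes along
  # the fast-exchange ridge where beta and gamma are only weakly
  # identified, which a fixed additive step cannot do. Giving schedule$tau
  # selects the plain additive symmetric walk instead.
  tau_log <- 0.5
  mh_step <- function(Ti) {
    if (adapt) {
      z <- rnorm(5, 0, tau_log * sqrt(min(Ti, 1)))
      cand <- x * exp(z)
      cl <- lpost(cand)
      ok <- is.finite(cl[1]) &&
        log(runif(1)) < (cl[1] - cur[1]) / Ti + sum(z)
    } else {
      cand <- propose(x, tau * sqrt(min(Ti, 1)))
      cl <- lpost(cand)
      ok <- annealed_accept(cl[1], cur[1], Ti)
    }
    if (ok) {
      x <<- cand; cur <<- cl
      if (cur[1] > best_lp) { best_lp <<- cur[1]; best_x <<- x }
    }
    ok
  }
  best_x <- x; best_lp <- cur[1]
  sweep_phase <- function(phase, temps, n_per_temp, tune = FALSE) {
    batch <- 0L
    for (Ti in temps) {
      n_acc <- 0L
      for (i in seq_len(n_per_temp)) {
        ok <- mh_step(Ti)
        n_acc <- n_acc + ok
        step <<- step + 1L
        chain[step, ] <<- c(step, phase, Ti, x, cur[2], as.numeric(ok))
      }
      acc_by_phase[phase] <<- acc_by_phase[phase] + n_acc
      if (adapt && tune) {
        batch <- batch + 1L
        tau_log <<- tau_log *
          exp((n_acc / n_per_temp - target_acc) / sqrt(batch))
      }
    }
  }

  geom_temps <- function(from, to, n) from * (to / from)^((seq_len(n) - 1) / (n - 1))

  # Phase 1: cool T0 -> 1 (broad exploration). The posterior has well-
  # separated basins (fast-exchange solutions trap chains started far from
  # the bulk), so exploration runs as several streams -- the caller's
  # start plus log-uniformly spread ones -- and the best posterior point
  # seen anywhere becomes the phase-2 start.
  starts <- cbind(x, matrix(exp(runif(5 * (n_streams - 1), log(1e-3),
                                      log(20))), nrow = 5))
  t1 <- geom_temps(schedule$T0, 1, schedule$steps_1)
  for (s in seq_len(n_streams)) {
    x <- starts[, s]
    cur <- lpost(x)
    if (!is.finite(cur[1])) next
    tau_log <- 0.5
    sweep_phase(1L, t1, n1_stream, tune = TRUE)
  }
  x <- best_x
  cur <- lpost(x)
  # Phase 2: Metropolis at temperature 1 (posterior sampling; batched for
  # proposal tuning)
  sweep_phase(2L, rep(1, 20), ceiling(schedule$n2 / 20), tune = TRUE)

  run_phase34 <- function(T_final) {
    t3 <- geom_temps(1, T_final, schedule$steps_3)
    sweep_phase(3L, t3, ceiling(schedule$n3 / schedule$steps_3))
    # Phase 4: hold, record best-likelihood set per segment
    seg_n <- ceiling(schedule$n4 / schedule$segments_4)
    bests <- matrix(NA_real_, schedule$segments_4, 6)
    for (s in seq_len(schedule$segments_4)) {
      best_ll <- -Inf; best_x <- x
      for (i in seq_len(seg_n)) {
        ok <- mh_step(T_final)
        if (cur[2] > best_ll) { best_ll <- cur[2]; best_x <- x }
        step <<- step + 1L
        if (step <= nrow(chain))
          chain[step, ] <<- c(step, 4, T_final, x, cur[2], as.numeric(ok))
      }
      bests[s, ] <- c(best_x, best_ll)
    }
    bests
  }

  T_use <- schedule$T_final
  bests <- run_phase34(T_use)
  if (schedule$auto_T_final) {
    # saturation rule: halve T_final while the mean best log-likelihood
    # still improves by >= 0.1
    for (k in 1:8) {
      T_try <- T_use / 2
      old_mean <- mean(bests[, 6])
      grow <- schedule$segments_4 * ceiling(schedule$n4 / schedule$segments_4) +
        schedule$steps_3 * ceiling(schedule$n3 / schedule$steps_3)
      chain <- rbind(chain, matrix(NA_real_, grow, 10))
      bests_try <- run_phase34(T_try)
      saturated <- mean(bests_try[, 6]) - old_mean < 0.1
      # the colder block is at least as good; keep it either way
      bests <- bests_try; T_use <- T_try
      if (saturated) break
    }
  }

  chain <- chain[!is.na(chain[, 1]), , drop = FALSE]
  chain <- as.data.frame(chain)
  est <- colMeans(bests[, 1:5, drop = FALSE])
  names(est) <- c("alpha", "beta", "gamma", "d1", "d2")
  est <- as_rate_params(pmax(est, 0))

  # convergence: do phase-4 best log-likelihoods of the final block still trend?
  bl <- bests[, 6]
  converged <- TRUE
  if (length(bl) >= 4 && sd(bl) > 0) {
    f <- lm(bl ~ seq_along(bl))
    sl <- summary(f)$coefficients
    if (nrow(sl) == 2 && sl[2, 1] > 0 && sl[2, 4] < 0.05) converged <- FALSE
  }

  acc <- vapply(1:4, function(ph) {
    sub <- chain$accepted[chain$phase == ph]
    if (length(sub)) mean(sub) else NA_real_
  }, numeric(1))

  structure(list(estimate = est,
                 chain = chain,
                 best_sets = stats::setNames(as.data.frame(bests),
                   c("alpha", "beta", "gamma", "d1", "d2", "loglik")),
                 acceptance = stats::setNames(acc, paste0("phase", 1:4)),
                 tau = if (adapt) c(tau_log = tau_log) else tau,
                 T_final_used = T_use, converged = converged,
                 seed = seed, init = init, sigma = obs$sigma, mode = mode),
            class = "posterior_result")
}

#' @export
print.posterior_result <- function(x, ...) {
  cat("Annealed-MCMC rate estimate (1/day):\n")
  print(round(unclass(x$estimate), 4))
  cat(sprintf("T_final = %.4g; phase acceptance: %s; converged: %s\n",
              x$T_final_used,
              paste(sprintf("%.2f", x$acceptance), collapse = "/"),
              x$converged))
  invisible(x)
}

#' Write a posterior chain as CSV / an estimate as JSON
#'
#' @param result A `posterior_result`.
#' @param chain_path,estimate_path Output files (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_posterior <- function(result, chain_path = NULL, estimate_path = NULL) {
  if (!is.null(chain_path))
    write.csv(result$chain, chain_path, row.names = FALSE)
  if (!is.null(estimate_path))
    jsonlite::write_json(list(
      estimate = as.list(unclass(result$estimate)),
      sigma = result$sigma, seed = result$seed,
      T_final = result$T_final_used, converged = result$converged
    ), estimate_path, auto_unbox = TRUE, digits = NA)
  invisible(c(chain_path, estimate_path))
}
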