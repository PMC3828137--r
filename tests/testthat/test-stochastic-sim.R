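test_that("SSA paths respect degenerate limits and the absorbing boundary", {
  set.seed(61)
  g <- gillespie_run(rate_params(0, 0, 0, 0, 0), c(7, 3, 2), 0:5)
  expect_equal(g$P, rep(7, 6)); expect_equal(g$D, rep(3, 6))
  expect_equal(g$N, rep(2, 6))
  g0 <- gillespie_run(rate_params(1, 1, 1, 1, 1), c(0, 0, 0), 0:5)
  expect_true(all(g0$P == 0) && all(g0$D == 0) && all(g0$N == 0))
  # once absorbed, paths stay at (0, 0, N)
  ev <- gillespie_run(rate_params(0, 0, 0, 5, 5), c(3, 3, 0),
                      record = "events", t_max = 100)
  expect_equal(unname(tail(ev, 1)$N), 6)
  expect_true(all(diff(ev$N) >= 0))
})

test_that("pure-birth ensemble matches the Yule-process mean", {
  set.seed(62)
  alpha <- 0.7; P0 <- 20; n_runs <- 4000
  ens <- simulate_ensemble(rate_params(alpha, 0, 0, 0, 0), c(P0, 0, 0),
                           n_runs = n_runs, days = 0:3, variant = 4)
  for (d in 1:3) {
    x <- ens$counts[, d + 1, "P"]
    se <- sd(x) / sqrt(n_runs)
    expect_lt(abs(mean(x) - P0 * exp(alpha * d)), 4 * se)
  }
})

test_that("SSA waiting times are exponential with the propensity rate", {
  set.seed(63)
  # pure birth: normalised waiting times (scaled by alpha * current P) are Exp(1)
  alpha <- 0.9
  ev <- gillespie_run(rate_params(alpha, 0, 0, 0, 0), c(10, 0, 0),
                      record = "events", t_max = 50, max_events = 3000)
  w <- diff(ev$time) * alpha * head(ev$P, -1)
  ks <- suppressWarnings(stats::ks.test(w, "pexp"))
  expect_gt(ks$p.value, 0.01)
})

test_that("truncated-normal draws have the right support and moments", {
  set.seed(64)
  x <- sample_truncated_normal(1e5, location = 10, scale = 0.5)
  expect_equal(mean(x), 10, tolerance = 1e-2)
  h <- sample_truncated_normal(1e5, location = 0, scale = 2)
  se <- sd(h) / sqrt(length(h))
  expect_lt(abs(mean(h) - 2 * sqrt(2 / pi)), 4 * se)
  expect_true(all(h >= 0))
  expect_error(sample_truncated_normal(1, 0, -1), "positive")
})

test_that("lognormal sampler and closed-form moments agree", {
  set.seed(65)
  expect_equal(sample_lognormal_init(5, log(30), 0), rep(30, 5))
  x <- sample_lognormal_init(2e5, 2, 0.6)
  expect_true(all(x > 0))
  mv <- lognormal_meanvar(2, 0.6)
  expect_lt(abs(mean(x) - mv[["M"]]), 4 * sd(x) / sqrt(length(x)))
  expect_equal(var(x), mv[["V"]], tolerance = 0.05)
  # degenerate closed form
  expect_equal(unname(lognormal_meanvar(3, 0)), c(exp(3), 0))
  # constant log-sd sweep: slope of log V vs log M is exactly 2
  lm_seq <- seq(1, 5, by = 0.5)
  mv_all <- t(sapply(lm_seq, lognormal_meanvar, log_sd = 0.4))
  b <- unname(coef(lm(log(mv_all[, "V"]) ~ log(mv_all[, "M"])))[2])
  expect_equal(b, 2, tolerance = 1e-10)
})

test_that("power-law fitting recovers exact, Poisson and exponential regimes", {
  M <- c(2, 5, 10, 40, 100)
  exact <- data.frame(M = M, V = 2 * M^1.5)
  fit <- fit_powerlaw(exact)
  expect_equal(fit$b, 1.5, tolerance = 1e-10)
  expect_equal(fit$a, 2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  set.seed(66)
  pois <- do.call(rbind, lapply(exp(seq(log(2), log(200), length.out = 12)),
    function(mu) { x <- rpois(4000, mu); data.frame(M = mean(x), V = var(x)) }))
  expect_equal(fit_powerlaw(pois)$b, 1, tolerance = 0.05)
  expo <- do.call(rbind, lapply(exp(seq(log(2), log(200), length.out = 12)),
    function(mu) { x <- rexp(4000, 1 / mu); data.frame(M = mean(x), V = var(x)) }))
  expect_equal(fit_powerlaw(expo)$b, 2, tolerance = 0.05)
  expect_error(fit_powerlaw(data.frame(M = c(1, 2), V = c(1, 2))),
               "insufficient")
})

test_that("lognormal fitting recovers parameters and flags constants", {
  set.seed(67)
  x <- sample_lognormal_init(3000, 1.2, 0.45)
  f <- fit_lognormal(x)
  expect_equal(f$log_mean, 1.2, tolerance = 3 * 0.45 / sqrt(3000) / 1.2 + 0.02)
  expect_equal(f$log_sd, 0.45, tolerance = 0.03)
  f0 <- fit_lognormal(rep(5, 50))
  expect_equal(f0$log_sd, 0)
  expect_error(fit_lognormal(c(0, 0, 1)), "at least 10")
})

test_that("birth-death closed-form moments match their limits and the SSA", {
  expect_equal(birthdeath_moments(0.5, 0, 10, 2)$V,
               10 * exp(0.5 * 2) * (exp(0.5 * 2) - 1), tolerance = 1e-12)
  m0 <- birthdeath_moments(0.4, 0.2, 7, 0)
  expect_equal(c(m0$M, m0$V), c(7, 0))
  mcrit <- birthdeath_moments(0.3, 0.3, 5, 4)
  expect_equal(c(mcrit$M, mcrit$V), c(5, 2 * 0.3 * 5 * 4))
  set.seed(68)
  lambda <- 0.6; mu <- 0.25; n0 <- 15; n_runs <- 3000
  ens <- simulate_ensemble(rate_params(lambda, 0, 0, mu, 0), c(n0, 0, 0),
                           n_runs = n_runs, days = 0:3, variant = 4)
  mom <- birthdeath_moments(lambda, mu, n0, 0:3)
  z <- vapply(1:3, function(d) {
    x <- ens$counts[, d + 1, "P"]
    (mean(x) - mom$M[d + 1]) / (sd(x) / sqrt(n_runs))
  }, numeric(1))
  expect_true(all(abs(z) < 4))
  # variance agreement (SE of the variance via 4th moments)
  for (d in 1:3) {
    x <- ens$counts[, d + 1, "P"]
    se_v <- sqrt((mean((x - mean(x))^4) - var(x)^2) / n_runs)
    expect_lt(abs(var(x) - mom$V[d + 1]), 4 * se_v)
  }
})

test_that("birth-death mean-variance slope tends to 2 and rejects single points", {
  expect_equal(birthdeath_powerlaw_slope(0.6, 0.2, 10, seq(40, 60, 2)), 2,
               tolerance = 1e-3)
  slope_small <- birthdeath_powerlaw_slope(0.6, 0.2, 10, c(0.01, 0.02))
  expect_true(is.finite(slope_small))
  expect_error(birthdeath_powerlaw_slope(0.6, 0.2, 10, 5), "insufficient")
  expect_error(birthdeath_powerlaw_slope(0.2, 0.6, 10, 1:3), "lambda > mu")
})

test_that("variant-4 ensembles are noise-free for frozen dynamics and track the ODE", {
  set.seed(69)
  ens0 <- simulate_ensemble(rate_params(0, 0, 0, 0, 0), c(12, 4, 1),
                            n_runs = 50, days = 0:3, variant = 4)
  expect_true(all(ens0$meanvar$V == 0))
  p <- rate_params(0.5, 0.2, 0.1, 0.1, 0.1)
  init <- c(30, 5, 0)
  n_runs <- 4000
  ens <- simulate_ensemble(p, init, n_runs = n_runs, days = 0:4, variant = 4)
  ode <- model_trajectory(p, state_vector(30, 5, 0), 0:4)
  z <- c()
  for (s in c("P", "D", "N")) for (d in 1:4) {
    x <- ens$counts[, d + 1, s]
    z <- c(z, (mean(x) - ode[[s]][d + 1]) / (sd(x) / sqrt(n_runs)))
  }
  expect_lt(max(abs(z)), 4.5)
})

test_that("variant dispersal modes change the mean-variance scaling as designed", {
  set.seed(70)
  p <- rate_params(0.5, 0.1, 0.05, 0.1, 0.05)
  # design-scale initial counts: a growing P pool plus sparse D and N pools
  ens1 <- simulate_ensemble(p, c(9.9, 0.6, 0.3), n_runs = 1500, days = 0:7,
                            variant = 1)
  fit1 <- fit_powerlaw(mean_var_series(ens1$counts, 0:7, exclude_zeros = TRUE))
  expect_gt(fit1$b, 1); expect_lt(fit1$b, 2)
  # zero dispersal scales degrade to the constant modes with a warning
  expect_warning(
    simulate_ensemble(p, c(5, 0, 0), n_runs = 5, days = 0:1,
                      variant = variant_config(1, init_log_sd = 0)),
    "constant")
  expect_warning(
    simulate_ensemble(p, c(5, 0, 0), n_runs = 5, days = 0:1,
                      variant = variant_config(2, tn_scale_frac = 0)),
    "constant")
})

test_that("counts drift from Poisson initials toward lognormal shape", {
  set.seed(71)
  n_runs <- 3000
  p <- rate_params(0.6, 0.1, 0.05, 0.1, 0.05)
  inits <- cbind(rpois(n_runs, 25), 0L, 0L)
  storage.mode(inits) <- "integer"
  rates <- matrix(rep(unclass(p), each = n_runs), nrow = n_runs)
  m <- cellfate:::ssa_fate_ensemble(rates, inits, as.numeric(0:7))
  P_day1 <- m[, 2]; P_day7 <- m[, 8]
  sk1 <- abs(skewness(log(P_day1[P_day1 > 0])))
  sk7 <- abs(skewness(log(P_day7[P_day7 > 0])))
  expect_lt(sk7, sk1)
})

test_that("N is non-decreasing along every sample path", {
  set.seed(72)
  for (k in 1:10) {
    p <- random_rates()
    ev <- gillespie_run(p, c(15, 5, 0), record = "events", t_max = 7,
                        max_events = 1e5)
    expect_true(all(diff(ev$N) >= 0))
  }
})
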