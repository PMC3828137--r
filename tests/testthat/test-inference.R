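test_that("count tables validate their schema and summarise day means", {
  df <- exact_count_table(rate_params(0.4, 0.1, 0.05, 0.1, 0.1),
                          state_vector(30, 2, 1), days = 0:3)
  ct <- count_table(df)
  m <- cellfate:::count_day_means(ct)
  expect_equal(dim(m), c(4L, 3L))
  expect_error(count_table(df[, -1]), "missing columns")
  bad <- df; bad$state[1] <- "X"
  expect_error(count_table(bad), "P, D, N")
  path <- tempfile(fileext = ".csv")
  write_count_table(ct, path)
  expect_equal(cellfate:::count_day_means(read_count_table(path)), m)
  unlink(path)
})

test_that("initial conditions come from day-0 means scaled by C", {
  df <- data.frame(day = 0, state = rep(c("P", "D", "N"), each = 2),
                   count = c(30, 30, 3, 3, 1, 1), field_id = rep(1:2, 3))
  ic <- estimate_initial_conditions(count_table(df), observation_model(C = 1))
  expect_equal(unclass(ic), c(P = 30, D = 3, N = 1))
  ic2 <- estimate_initial_conditions(count_table(df), observation_model(C = 2))
  expect_equal(unclass(ic2), c(P = 15, D = 1.5, N = 0.5))
  # uneven per-field counts average by hand
  df$count[1:2] <- c(28, 34)
  ic3 <- estimate_initial_conditions(count_table(df))
  expect_equal(ic3[["P"]], 31)
  expect_error(estimate_initial_conditions(
    count_table(transform(df, day = 1))), "day-0")
})

test_that("log-likelihood matches Gaussian algebra and a brute-force sum", {
  p <- rate_params(0.4, 0.15, 0.1, 0.1, 0.05)
  init <- state_vector(30, 2, 1)
  obs <- observation_model(C = 1, sigma = 2)
  ct <- count_table(exact_count_table(p, init, days = 0:7))
  n_total <- 3 * 8
  expect_equal(log_likelihood(p, ct, obs, init),
               -n_total * log(2 * sqrt(2 * pi)), tolerance = 1e-10)
  # single-point perturbation lowers the log-likelihood by delta^2 / (2 s^2)
  delta <- 1.7
  ct2 <- ct; ct2$count[5] <- ct2$count[5] + delta
  expect_equal(log_likelihood(p, ct, obs, init) -
                 log_likelihood(p, count_table(ct2), obs, init),
               delta^2 / (2 * 2^2), tolerance = 1e-10)
  # brute-force per-point Gaussian density sum on noisy data
  set.seed(81)
  ct3 <- ct; ct3$count <- pmax(ct3$count + rnorm(nrow(ct3), 0, 2), 0)
  ct3 <- count_table(ct3)
  pred <- cellfate:::predict_densities(p, unclass(init), 0:7)
  brute <- 0
  for (i in seq_len(nrow(ct3))) {
    mu <- pred[ct3$day[i] + 1, ct3$state[i]]
    brute <- brute + log(dnorm(ct3$count[i], mu, 2))
  }
  expect_equal(log_likelihood(p, ct3, obs, init, mode = "per_field"), brute,
               tolerance = 1e-8)
})

test_that("log-posterior respects the gamma prior support", {
  p <- rate_params(0.4, 0.15, 0.1, 0.1, 0.05)
  ct <- count_table(exact_count_table(p, state_vector(30, 2, 1)))
  obs <- observation_model(C = 1, sigma = 2)
  expect_identical(log_posterior(c(-0.1, 0.1, 0.1, 0.1, 0.1), ct, obs), -Inf)
  # k = 1 prior is exponential: finite density at zero rates
  lp0 <- log_posterior(c(0, 0, 0, 0, 0), ct, obs,
                       init = estimate_initial_conditions(ct, obs),
                       prior = gamma_prior(shape = 1, scale = 10))
  expect_true(is.finite(lp0))
  # broad prior: posterior and likelihood argmax coincide on a coarse grid
  alphas <- seq(0.1, 0.8, by = 0.05)
  betas <- seq(0.02, 0.4, by = 0.02)
  init <- state_vector(30, 2, 1)
  ll <- lp <- matrix(NA, length(alphas), length(betas))
  for (i in seq_along(alphas)) for (j in seq_along(betas)) {
    pj <- rate_params(alphas[i], betas[j], 0.1, 0.1, 0.05)
    ll[i, j] <- log_likelihood(pj, ct, obs, init)
    lp[i, j] <- log_posterior(pj, ct, obs, init, prior = gamma_prior(1, 100))
  }
  expect_equal(which(lp == max(lp)), which(ll == max(ll)))
  expect_equal(alphas[which(ll == max(ll), arr.ind = TRUE)[1]], 0.4)
})

test_that("random-walk proposals are centred and symmetric", {
  expect_equal(propose(c(1, 2, 3), 0), c(1, 2, 3))
  set.seed(82)
  cur <- c(0.5, 0.2, 0.1, 0.4, 0.3)
  prop <- t(replicate(1e4, propose(cur, 0.1)))
  se <- 0.1 / sqrt(1e4)
  expect_true(all(abs(colMeans(prop) - cur) < 4 * se))
  # symmetric kernel: density(a -> b) equals density(b -> a)
  a <- c(0.5, 0.2); b <- c(0.45, 0.31)
  expect_equal(prod(dnorm(b, a, 0.1)), prod(dnorm(a, b, 0.1)))
})

test_that("tempered acceptance reproduces the Metropolis rule", {
  set.seed(83)
  expect_true(annealed_accept(-10, -20, 1))
  expect_true(annealed_accept(-5, -5, 1))
  g <- -1.2; Temp <- 0.7
  acc <- mean(replicate(2e4, annealed_accept(-10 + g, -10, Temp)))
  p_true <- exp(g / Temp)
  se <- sqrt(p_true * (1 - p_true) / 2e4)
  expect_lt(abs(acc - p_true), 4 * se)
  expect_false(annealed_accept(-Inf, -10, 1))
})

test_that("fixed-temperature chain samples the posterior on a coarse grid", {
  # 2-parameter problem with an enumerable discretisation: empirical visit
  # frequencies of the Metropolis chain (temperature 1) match the
  # normalised posterior within sampling error
  p_true <- rate_params(0.5, 0.2, 0.1, 0.1, 0.05)
  init <- state_vector(30, 2, 1)
  obs <- observation_model(C = 1, sigma = 8)
  ct <- count_table(exact_count_table(p_true, init, days = 0:7))
  lpost <- function(a, b) log_posterior(rate_params(a, b, 0.1, 0.1, 0.05),
                                        ct, obs, init)
  set.seed(84)
  x <- c(0.5, 0.2); lcur <- lpost(x[1], x[2])
  n_iter <- 20000
  samp <- matrix(NA, n_iter, 2)
  for (i in seq_len(n_iter)) {
    cand <- propose(x, 0.08)
    lcand <- if (any(cand < 0)) -Inf else lpost(cand[1], cand[2])
    if (annealed_accept(lcand, lcur, 1)) { x <- cand; lcur <- lcand }
    samp[i, ] <- x
  }
  samp <- samp[-(1:2000), ]
  # coarse 5 x 5 cell grid over the bulk of the posterior; cell
  # probabilities integrated on a subgrid (the enumerable-state oracle)
  ea <- seq(quantile(samp[, 1], 0.02), quantile(samp[, 1], 0.98),
            length.out = 6)
  eb <- seq(quantile(samp[, 2], 0.02), quantile(samp[, 2], 0.98),
            length.out = 6)
  lg <- array(NA_real_, c(5, 5, 25))
  for (i in 1:5) for (j in 1:5) {
    sa <- seq(ea[i], ea[i + 1], length.out = 5)
    sb <- seq(eb[j], eb[j + 1], length.out = 5)
    lg[i, j, ] <- as.vector(outer(sa, sb, Vectorize(lpost)))
  }
  cell_prob <- apply(exp(lg - max(lg)), c(1, 2), mean)
  pg <- cell_prob / sum(cell_prob)
  ia <- findInterval(samp[, 1], ea); ib <- findInterval(samp[, 2], eb)
  keep <- ia >= 1 & ia <= 5 & ib >= 1 & ib <= 5
  emp <- table(factor(ia[keep], 1:5), factor(ib[keep], 1:5))
  emp <- emp / sum(emp)
  # chain autocorrelation inflates the sampling error, so the band is loose
  expect_lt(max(abs(emp - pg)), 0.04)
  expect_gt(cor(as.vector(emp), as.vector(pg)), 0.97)
})

test_that("annealed MCMC is reproducible and honours the prior support", {
  p_true <- rate_params(0.5, 0.2, 0.1, 0.2, 0.1)
  truth <- ground_truth(p_true)
  des <- study_design(conditions = data.frame(serum = "high",
                                              stimulus = "control"),
                      replicates = 1)
  ds <- generate_dataset(des, truth, mode = "ode_noise", seed = 91)
  sched <- annealing_schedule(n1 = 600, n2 = 600, n3 = 600, n4 = 1200,
                              steps_1 = 10, steps_3 = 10, segments_4 = 6,
                              auto_T_final = FALSE)
  f1 <- run_annealed_mcmc(ds$counts, obs = observation_model(C = ds$C),
                          schedule = sched, seed = 7, mode = "per_field")
  f2 <- run_annealed_mcmc(ds$counts, obs = observation_model(C = ds$C),
                          schedule = sched, seed = 7, mode = "per_field")
  expect_identical(f1$chain, f2$chain)
  expect_identical(unclass(f1$estimate), unclass(f2$estimate))
  rates_cols <- c("alpha", "beta", "gamma", "d1", "d2")
  expect_true(all(as.matrix(f1$chain[rates_cols]) >= 0))
  # phase-4 exploitation should not lose the phase-2 likelihood level
  ll2 <- max(f1$chain$loglik[f1$chain$phase == 2])
  ll4 <- max(f1$chain$loglik[f1$chain$phase == 4])
  expect_gte(ll4, ll2 - 0.5)
  # estimate equals the mean of the recorded phase-4 best sets
  expect_equal(unname(unclass(f1$estimate)),
               unname(colMeans(f1$best_sets[, 1:5])), tolerance = 1e-12)
})

test_that("rates are recovered from a well-conditioned synthetic dataset", {
  p_true <- rate_params(0.5, 0.25, 0.1, 0.2, 0.1)
  truth <- ground_truth(p_true)
  des <- study_design(conditions = data.frame(serum = "high",
                                              stimulus = "control"),
                      replicates = 1)
  ds <- generate_dataset(des, truth, mode = "ode_noise", seed = 92)
  fit <- run_annealed_mcmc(ds$counts, obs = observation_model(C = ds$C),
                           seed = 8, mode = "per_field")
  rel <- abs(unclass(fit$estimate) - unclass(p_true)) / unclass(p_true)
  expect_lt(median(rel), 0.2)
  expect_lt(rel[["alpha"]], 0.2)
})

test_that("estimates do not depend on the starting point across four orders of magnitude", {
  p_true <- rate_params(0.45, 0.2, 0.1, 0.15, 0.1)
  truth <- ground_truth(p_true)
  des <- study_design(conditions = data.frame(serum = "high",
                                              stimulus = "control"),
                      replicates = 1)
  ds <- generate_dataset(des, truth, mode = "ode_noise", seed = 93)
  fits <- lapply(c(0.005, 50), function(x0)
    run_annealed_mcmc(ds$counts, obs = observation_model(C = ds$C),
                      seed = 9, init_params = rep(x0, 5),
                      mode = "per_field"))
  e1 <- unclass(fits[[1]]$estimate); e2 <- unclass(fits[[2]]$estimate)
  # agreement in absolute rate units (rates are O(1)/day at most); the
  # weakly identified de-differentiation direction precludes a tight
  # relative comparison
  expect_lt(max(abs(e1 - e2)), 0.1)
})

test_that("posterior results serialise to CSV and JSON", {
  p_true <- rate_params(0.5, 0.2, 0.1, 0.2, 0.1)
  ds <- generate_dataset(
    study_design(conditions = data.frame(serum = "high", stimulus = "control"),
                 replicates = 1),
    ground_truth(p_true), mode = "ode_noise", seed = 94)
  sched <- annealing_schedule(n1 = 200, n2 = 200, n3 = 200, n4 = 400,
                              steps_1 = 5, steps_3 = 5, segments_4 = 4,
                              auto_T_final = FALSE)
  fit <- run_annealed_mcmc(ds$counts, obs = observation_model(C = ds$C),
                           schedule = sched, seed = 10)
  cp <- tempfile(fileext = ".csv"); ep <- tempfile(fileext = ".json")
  write_posterior(fit, cp, ep)
  chain <- read.csv(cp)
  expect_true(all(c("phase", "temperature", "alpha", "loglik") %in%
                    names(chain)))
  est <- jsonlite::read_json(ep)
  expect_equal(est$estimate$alpha, fit$estimate[["alpha"]], tolerance = 1e-12)
  expect_identical(est$seed, 10L)
  unlink(c(cp, ep))
})
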