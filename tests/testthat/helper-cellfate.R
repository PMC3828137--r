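# shared fixtures and independent oracles

# random non-negative rate vector; rejects near-degenerate spectra when asked
random_rates <- function(max_rate = 1, min_gap = 0) {
  repeat {
    r <- runif(5, 0, max_rate)
    p <- rate_params(r[1], r[2], r[3], r[4], r[5])
    if (min_gap == 0) return(p)
    ev <- sort(eigen(build_system_matrix(p))$values)
    if (diff(ev) > min_gap) return(p)
  }
}

# characteristic-polynomial eigenvalue oracle (quadratic formula on tr/det)
eig_quadratic <- function(A) {
  tr <- A[1, 1] + A[2, 2]
  det <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  s <- sqrt(tr^2 - 4 * det + 0i)
  sort(Re(c((tr + s) / 2, (tr - s) / 2)))
}

# long-time log-slope of the total living density, from the numeric ODE
# only: integrates in segments, renormalising (P, D) to unit total at each
# restart (linearity leaves the slope unchanged, avoids under/overflow)
ode_log_slope <- function(params, init = state_vector(1, 0.5, 0),
                          t_settle = 160, seg = 10) {
  y <- unclass(init)[1:2]
  n_seg <- ceiling(t_settle / seg)
  growth <- NA_real_
  for (i in seq_len(n_seg)) {
    tot0 <- sum(y)
    tr <- solve_ode(params, state_vector(y[1] / tot0, y[2] / tot0, 0),
                    times = c(0, seg))
    y <- c(tr$P[2], tr$D[2])
    growth <- log(sum(y))  # log growth over the last segment
  }
  growth / seg
}

# sample skewness
skewness <- function(x) {
  m <- mean(x); s <- sd(x)
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

# small count table built by hand around exact model predictions
exact_count_table <- function(params, init, days = 0:7, C = 1, n_fields = 1) {
  pred <- cellfate:::predict_densities(params, unclass(init), days) * C
  do.call(rbind, lapply(1:3, function(s) data.frame(
    day = rep(days, each = n_fields),
    state = c("P", "D", "N")[s],
    count = rep(pred[, s], each = n_fields),
    field_id = rep(seq_len(n_fields), times = length(days)))))
}
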