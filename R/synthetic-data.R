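#' Study design for synthetic count datasets
#'
#' Mirrors the design of a daily cell-counting experiment: a set of
#' conditions (serum level crossed with stimulus), daily observations,
#' thirty randomly sampled microscope fields per dish per day, and four
#' independent replicate experiments.
#'
#' @param conditions data.frame with columns `serum`
#'   (`"high"`, `"low"`, `"free"`) and `stimulus` (`"control"`, `"EGF"`,
#'   `"NGF"`); default: all nine combinations.
#' @param days Observation days (default 0:7).
#' @param fields_per_day Sampled fields per dish per day (default 30).
#' @param replicates Independent experiments (default 4).
#' @param field_area Imaged area per field in mm^2 (default 0.3); together
#'   with a density in cells/mm^2 it sets the expected count per image.
#' @return A `study_design` list.
#' @export
study_design <- function(conditions = NULL, days = 0:7, fields_per_day = 30,
                         replicates = 4, field_area = 0.3) {
  if (is.null(conditions))
    conditions <- expand.grid(serum = c("high", "low", "free"),
                              stimulus = c("control", "EGF", "NGF"),
                              stringsAsFactors = FALSE)
  stopifnot(fields_per_day >= 1, replicates >= 1, days[1] == 0,
            field_area > 0)
  structure(list(conditions = conditions, days = days,
                 fields_per_day = fields_per_day, replicates = replicates,
                 field_area = field_area),
            class = "study_design")
}

#' Named rate presets for the nine serum x stimulus conditions
#'
#' Synthetic parameter sets (labelled as such; they are not measured
#' values) encoding the qualitative pattern of the serum and growth-factor
#' effects: high serum keeps cells proliferating (large alpha, small beta
#' and death rates, positive Malthus coefficient, doubling time ~1.5 days);
#' serum starvation slows proliferation and promotes differentiation and
#' death (negative Malthus coefficient); EGF raises the proliferation rate
#' (and somewhat the differentiation rate) in every serum condition; NGF
#' raises the differentiation rate and lowers the asymptotic growth rate.
#'
#' @return Named list of nine [rate_params()], keys `"<serum>_<stimulus>"`.
#' @export
preset_conditions <- function() {
  ctl <- list(
    high = rate_params(alpha = 0.60, beta = 0.05, gamma = 0.20,
                       d1 = 0.05, d2 = 0.05),
    low  = rate_params(alpha = 0.40, beta = 0.12, gamma = 0.15,
                       d1 = 0.15, d2 = 0.10),
    free = rate_params(alpha = 0.18, beta = 0.22, gamma = 0.10,
                       d1 = 0.12, d2 = 0.08)
  )
  out <- list()
  for (s in names(ctl)) {
    p <- unclass(ctl[[s]])
    out[[paste0(s, "_control")]] <- ctl[[s]]
    # EGF: proliferation up (x1.6), differentiation mildly up (x1.2)
    out[[paste0(s, "_EGF")]] <- rate_params(
      alpha = 1.6 * p[["alpha"]], beta = 1.2 * p[["beta"]],
      gamma = p[["gamma"]], d1 = 0.8 * p[["d1"]], d2 = p[["d2"]])
    # NGF: differentiation up (x2.5), proliferation down (x0.6),
    # de-differentiation down; asymptotic growth rate drops
    out[[paste0(s, "_NGF")]] <- rate_params(
      alpha = 0.6 * p[["alpha"]], beta = 2.5 * p[["beta"]],
      gamma = 0.6 * p[["gamma"]], d1 = p[["d1"]], d2 = 0.8 * p[["d2"]])
  }
  out
}

#' Ground truth for a synthetic dataset
#'
#' @param params A [rate_params()] (or a preset name from
#'   [preset_conditions()]).
#' @param init Initial densities ([state_vector()]), cells/mm^2. The
#'   default puts ~10 proliferating cells in a 0.3 mm^2 field at day 0,
#'   with sub-unity expected counts for the differentiated and dead
#'   states, so early-day tables carry many zero counts as sparse plating
#'   does.
#' @param sigma Observation-noise SD on the count scale, or `NULL` for the
#'   10%-of-day-0-count convention.
#' @param init_log_sd Log-scale SD of the per-field lognormal initial-count
#'   dispersion (Gillespie mode).
#' @return A `ground_truth` list.
#' @export
ground_truth <- function(params, init = state_vector(P = 33, D = 2, N = 1),
                         sigma = NULL, init_log_sd = 0.2) {
  if (is.character(params)) params <- preset_conditions()[[params]]
  params <- as_rate_params(params)
  structure(list(params = params, init = init, sigma = sigma,
                 init_log_sd = init_log_sd),
            class = "ground_truth")
}

#' Generate a study-shaped synthetic count table
#'
#' `mode = "ode_noise"`: per-field counts are the deterministic model
#' densities converted to expected per-image counts
#' (`density * field_area`) plus i.i.d. Gaussian observation noise, floored
#' at zero and rounded to integers. `mode = "gillespie"`: every field is an
#' independent exact stochastic realisation started from a lognormal
#' per-field initial count, so field-to-field dispersion carries both
#' demographic noise and initial-condition dispersal.
#'
#' @param design A [study_design()]. Each (condition, replicate) uses the
#'   matching preset from `truths` (or a single shared truth).
#' @param truths Either one [ground_truth()] applied to every condition, or
#'   a named list keyed `"<serum>_<stimulus>"`.
#' @param mode `"ode_noise"` or `"gillespie"`.
#' @param seed Integer seed; the table is reproducible given (design,
#'   truths, mode, seed).
#' @return A list: `counts` (a [count_table()]), `truths`, `design`,
#'   `mode`, `seed`, and `C` (the density-to-count conversion, equal to
#'   `design$field_area`).
#' @export
generate_dataset <- function(design = study_design(), truths = NULL,
                             mode = c("ode_noise", "gillespie"), seed = 1L) {
  mode <- match.arg(mode)
  set.seed(seed)
  if (is.null(truths)) {
    pre <- preset_conditions()
    truths <- lapply(pre, ground_truth)
  }
  single <- inherits(truths, "ground_truth")
  C <- design$field_area
  rows <- list()
  for (ci in seq_len(nrow(design$conditions))) {
    serum <- design$conditions$serum[ci]
    stim <- design$conditions$stimulus[ci]
    key <- paste0(serum, "_", stim)
    tr <- if (single) truths else truths[[key]]
    if (is.null(tr)) stop("no ground truth for condition ", key, call. = FALSE)
    dens <- predict_densities(tr$params, unclass(tr$init), design$days)
    expected <- dens * C  # expected counts per image, [day x state]
    sigma <- tr$sigma
    if (is.null(sigma)) sigma <- max(0.1 * sum(expected[1, ]), 1e-12)
    for (rep_i in seq_len(design$replicates)) {
      if (mode == "ode_noise") {
        nf <- design$fields_per_day
        for (s in 1:3) {
          mu <- rep(expected[, s], each = nf)
          cnt <- round(pmax(mu + rnorm(length(mu), 0, sigma), 0))
          rows[[length(rows) + 1L]] <- data.frame(
            day = rep(design$days, each = nf),
            state = c("P", "D", "N")[s], count = cnt,
            field_id = rep(seq_len(nf), times = length(design$days)),
            condition = serum, stimulus = stim, replicate = rep_i)
        }
      } else {
        # each field = one SSA path from a lognormal initial count
        nf <- design$fields_per_day
        s_log <- tr$init_log_sd
        base <- expected[1, ]  # expected initial counts per field
        inits <- sapply(1:3, function(j) {
          if (base[j] <= 0) rep(0L, nf)
          else as.integer(round(sample_lognormal_init(
            nf, log(base[j]) - s_log^2 / 2, s_log)))
        })
        storage.mode(inits) <- "integer"
        rates <- matrix(rep(unclass(tr$params), each = nf), nrow = nf)
        m <- ssa_fate_ensemble(rates, inits, as.numeric(design$days))
        nt <- length(design$days)
        for (s in 1:3) {
          block <- m[, ((s - 1) * nt + 1):(s * nt), drop = FALSE]
          rows[[length(rows) + 1L]] <- data.frame(
            day = rep(design$days, each = nf),
            state = c("P", "D", "N")[s],
            count = as.vector(block),
            field_id = rep(seq_len(nf), times = nt),
            condition = serum, stimulus = stim, replicate = rep_i)
        }
      }
    }
  }
  counts <- count_table(do.call(rbind, rows))
  list(counts = counts, truths = truths, design = design, mode = mode,
       seed = seed, C = C)
}
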