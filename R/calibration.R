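#' In-vitro culture conditions used for parameter fitting
#'
#' @return Character vector: LNCaP-style tumor monoculture, fibroblast
#'   monoculture, tumor + fibroblast + M1 (or M2) coculture at a 4:1:1
#'   seeding ratio, and the Caspase-3/7-style apoptosis readout.
#' @export
culture_conditions <- function() {
  c("tumor_mono", "fibroblast_mono", "tumor_fib_m1", "tumor_fib_m2",
    "apoptosis")
}

culture_seeding <- function(condition, n_total) {
  switch(condition,
    tumor_mono = ,
    apoptosis = c(tumor = n_total),
    fibroblast_mono = c(fibroblast = n_total),
    tumor_fib_m1 = c(tumor = round(n_total * 4 / 6),
                     fibroblast = round(n_total / 6),
                     m1 = round(n_total / 6)),
    tumor_fib_m2 = c(tumor = round(n_total * 4 / 6),
                     fibroblast = round(n_total / 6),
                     m2 = round(n_total / 6)),
    stop("unknown culture condition: ", condition))
}

#' Simulate a 7-day in-vitro culture
#'
#' Cells are seeded uniformly at random on an empty lattice and iterated
#' for 14 steps (12 h per step, 7 days). In culture mode fibroblasts
#' proliferate (with `Fpprol`, `Fpmax`, `Fpdeath`) instead of idling, and
#' tumor cells do not mutate. The growth signal is the tumor (or
#' fibroblast) cell count; the apoptosis signal is the cumulative number
#' of tumor-cell deaths (a Caspase-3/7-style cumulative readout).
#'
#' @param condition one of [culture_conditions()].
#' @param params an `abm_params` list.
#' @param n_total total cells seeded (cocultures use a 4:1:1 ratio).
#' @param dim culture lattice dimensions.
#' @param n_steps number of 12-h steps (default 14 = 7 days).
#' @return Data frame `time_h`, `signal`.
#' @export
simulate_culture <- function(condition, params = default_parameters(),
                             n_total = 600L, dim = c(80L, 80L),
                             n_steps = 14L) {
  condition <- match.arg(condition, culture_conditions())
  seeding <- culture_seeding(condition, n_total)
  n <- sum(seeding)
  if (n > prod(dim)) stop("seeding exceeds culture lattice capacity")
  p <- params
  p$TUpmut <- 0  # no mutation acquisition over 7 days in vitro
  pos <- sample.int(prod(dim), n) - 1L
  kind <- rep(names(seeding), seeding)
  agents <- data.frame(
    id = seq_len(n), kind = kind, row = pos %/% dim[2],
    col = pos %% dim[2], mutations = 0L,
    divisions_left = ifelse(kind == "tumor", p$TUpmax,
                     ifelse(kind == "fibroblast", p$Fpmax, Inf)),
    kills_left = ifelse(kind %in% c("m1", "m2"), p$M1kmax, 0L),
    emt = FALSE, age = 0L, stringsAsFactors = FALSE)
  agents$divisions_left[kind == "m1" | kind == "m2"] <- Inf
  agents$kills_left[kind == "m2"] <- p$M2kmax
  state <- new_grid_state(width = dim[2], height = dim[1], agents = agents)
  res <- simulate_steps(state, p, n_steps, model = "culture",
                        record_every = 1L)
  ts <- res$timeseries
  signal <- switch(condition,
    fibroblast_mono = ts$n_fibroblast,
    apoptosis = ts$cum_tumor_deaths,
    ts$n_tumor)
  data.frame(time_h = ts$step * 12, signal = signal)
}

#' Generate synthetic growth and apoptosis curves
#'
#' Stands in for IncuCyte-style confluence and Caspase-3/7 curves:
#' simulates each culture condition with `true_params` and adds
#' multiplicative Gaussian noise. Growth conditions are emitted in
#' triplicate, the apoptosis readout in duplicate.
#'
#' @param true_params generating parameter set.
#' @param noise_sd standard deviation of the multiplicative noise
#'   (fraction of the signal); 0 gives identical replicates.
#' @param conditions which conditions to emit.
#' @param seed integer seed.
#' @inheritParams simulate_culture
#' @return Data frame `condition`, `replicate`, `time_h`, `signal`.
#' @export
generate_synthetic_curves <- function(true_params = default_parameters(),
                                      noise_sd = 0.05,
                                      conditions = culture_conditions(),
                                      seed = NULL, n_total = 600L,
                                      dim = c(80L, 80L), n_steps = 14L) {
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (cond in conditions) {
    n_rep <- if (cond == "apoptosis") 2L else 3L
    base_curve <- simulate_culture(cond, true_params, n_total = n_total,
                                   dim = dim, n_steps = n_steps)
    for (r in seq_len(n_rep)) {
      cur <- base_curve
      noisy <- cur$signal * (1 + rnorm(nrow(cur), 0, noise_sd))
      cur$signal <- pmax(0, noisy)
      cur$condition <- cond
      cur$replicate <- r
      out[[length(out) + 1L]] <- cur
    }
  }
  do.call(rbind, out)[, c("condition", "replicate", "time_h", "signal")]
}

#' Particle swarm optimization settings
#'
#' @param swarm_size particles per restart.
#' @param iterations velocity/position updates per restart.
#' @param inertia,cognitive,social standard PSO coefficients.
#' @param restarts independent optimizations whose best parameters are
#'   averaged (the fitting protocol uses 50 to absorb stochasticity).
#' @param seed integer seed for reproducible trajectories.
#' @return A list of class `pso_config`.
#' @export
pso_config <- function(swarm_size = 16L, iterations = 40L, inertia = 0.7,
                       cognitive = 1.5, social = 1.5, restarts = 50L,
                       seed = NULL) {
  stopifnot(restarts >= 1)
  structure(list(swarm_size = as.integer(swarm_size),
                 iterations = as.integer(iterations), inertia = inertia,
                 cognitive = cognitive, social = social,
                 restarts = as.integer(restarts), seed = seed),
            class = "pso_config")
}

#' Minimize an objective with particle swarm optimization
#'
#' Global-best PSO with absorbing bound clamping (positions are clipped to
#' the box and the offending velocity component zeroed). Integer dimensions are
#' optimized on the continuous relaxation and rounded at evaluation time
#' and in the reported optimum. The final value of each parameter is the
#' mean of the per-restart best positions; the inter-restart standard
#' deviation measures the robustness of the estimate.
#'
#' @param objective function of a numeric vector returning a scalar to
#'   minimize; must be evaluable everywhere within the bounds.
#' @param lower,upper numeric bounds (finite).
#' @param integer logical vector marking dimensions rounded to integers.
#' @param config a [pso_config()].
#' @return List with `par` (averaged best), `value` (mean best objective),
#'   `restarts` (data frame of per-restart optima), `par_sd`.
#' @export
pso_fit <- function(objective, lower, upper, integer = NULL,
                    config = pso_config()) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(is.finite(lower)),
            all(is.finite(upper)), all(upper > lower))
  if (is.null(integer)) integer <- rep(FALSE, d)
  if (!is.null(config$seed)) set.seed(config$seed)
  evalx <- function(x) {
    x[integer] <- round(x[integer])
    objective(x)
  }
  span <- upper - lower
  best_rows <- matrix(NA_real_, config$restarts, d)
  best_vals <- numeric(config$restarts)
  init_best <- numeric(config$restarts)
  for (r in seq_len(config$restarts)) {
    X <- matrix(runif(config$swarm_size * d), config$swarm_size, d)
    X <- sweep(sweep(X, 2, span, "*"), 2, lower, "+")
    V <- matrix(0, config$swarm_size, d)
    fit <- apply(X, 1, evalx)
    P <- X
    pf <- fit
    g <- which.min(pf)
    gx <- P[g, ]
    gf <- pf[g]
    init_best[r] <- gf
    for (it in seq_len(config$iterations)) {
      r1 <- matrix(runif(config$swarm_size * d), config$swarm_size, d)
      r2 <- matrix(runif(config$swarm_size * d), config$swarm_size, d)
      V <- config$inertia * V +
        config$cognitive * r1 * (P - X) +
        config$social * r2 * sweep(-X, 2, gx, "+")
      X <- X + V
      for (j in seq_len(d)) {  # clamp to bounds, zero the velocity there
        lo <- X[, j] < lower[j]
        hi <- X[, j] > upper[j]
        X[lo, j] <- lower[j]
        X[hi, j] <- upper[j]
        V[lo | hi, j] <- 0
      }
      fit <- apply(X, 1, evalx)
      imp <- fit < pf
      P[imp, ] <- X[imp, , drop = FALSE]
      pf[imp] <- fit[imp]
      g <- which.min(pf)
      if (pf[g] < gf) {
        gf <- pf[g]
        gx <- P[g, ]
      }
    }
    gx[integer] <- round(gx[integer])
    best_rows[r, ] <- gx
    best_vals[r] <- gf
  }
  if (!any(is.finite(best_vals)))
    stop("PSO failed: no restart produced a finite objective value ",
         "(initial best values: ",
         paste(signif(init_best, 4), collapse = ", "), ")")
  par <- colMeans(best_rows)
  par[integer] <- round(par[integer])
  list(par = par, value = mean(best_vals),
       restarts = data.frame(best_rows, value = best_vals),
       par_sd = apply(best_rows, 2, sd))
}

# deterministic curve-mismatch objective: mean squared error between the
# observed replicate-mean curve and the simulated mean curve under common
# random numbers (fixed evaluation seeds)
curve_objective <- function(curves, condition, setter,
                            base, n_sim = 2L, eval_seed = 7151L,
                            n_total = 600L, dim = c(80L, 80L)) {
  obs <- curves[curves$condition == condition, ]
  if (nrow(obs) == 0) stop("calibration curves lack condition: ", condition)
  obs_mean <- tapply(obs$signal, obs$time_h, mean)
  times <- as.numeric(names(obs_mean))
  n_steps <- max(times) / 12
  function(x) {
    p <- setter(base, x)
    tot <- 0
    for (k in seq_len(n_sim)) {
      set.seed(eval_seed + k)
      sim <- simulate_culture(condition, p, n_total = n_total, dim = dim,
                              n_steps = n_steps)
      tot <- tot + sum((sim$signal[match(times, sim$time_h)] -
                          obs_mean)^2)
    }
    tot / (n_sim * length(times))
  }
}

#' Sequential PSO calibration of cell parameters
#'
#' Reproduces the staged fitting protocol: (1) `TUpprol` and `TUpmax` are
#' fitted to the tumor monoculture growth curve; (2) `TUpdeath` to the
#' apoptosis readout; (3) `Fpprol`, `Fpmax` and `Fpdeath` to the
#' fibroblast growth curve; (4) `M1pkill` and `M1kmax` to the tumor +
#' fibroblast + M1 coculture; (5) `M2pkill` to the M2 coculture.
#' `M2kmax` is set equal to the fitted `M1kmax`. Each stage fixes the
#' parameters estimated upstream; already-fixed fields are never revised.
#'
#' @param curves data frame of calibration curves (`condition`,
#'   `replicate`, `time_h`, `signal`), e.g. from
#'   [generate_synthetic_curves()]; all five conditions must be present
#'   before their stage runs.
#' @param base parameter set providing every non-fitted field.
#' @param pso a [pso_config()].
#' @param n_sim simulator replicates averaged inside the objective.
#' @param n_total,dim culture seeding and lattice, matched to the curves.
#' @return The assembled `abm_params`, with a `provenance` attribute
#'   naming the stage that produced each fitted field and a `fits`
#'   attribute holding the per-stage [pso_fit()] results.
#' @export
sequential_calibration <- function(curves, base = default_parameters(),
                                   pso = pso_config(), n_sim = 2L,
                                   n_total = 600L, dim = c(80L, 80L)) {
  need <- c("condition", "replicate", "time_h", "signal")
  if (!all(need %in% names(curves)))
    stop("curves must have columns ", paste(need, collapse = ", "))
  p <- base
  prov <- setNames(rep("base", length(p)), names(p))
  fits <- list()
  if (!is.null(pso$seed)) set.seed(pso$seed)

  stage <- function(condition, fields, lower, upper, integer, setter) {
    if (!condition %in% curves$condition)
      stop("calibration curves lack condition: ", condition)
    obj <- curve_objective(curves, condition, setter, p, n_sim = n_sim,
                           n_total = n_total, dim = dim)
    fit <- pso_fit(obj, lower, upper, integer,
                   pso_config(swarm_size = pso$swarm_size,
                              iterations = pso$iterations,
                              inertia = pso$inertia,
                              cognitive = pso$cognitive,
                              social = pso$social,
                              restarts = pso$restarts, seed = NULL))
    p <<- setter(p, fit$par)
    prov[fields] <<- paste0("fitted:", condition)
    fits[[condition]] <<- fit
    invisible(fit)
  }

  stage("tumor_mono", c("TUpprol", "TUpmax"),
        lower = c(0.05, 2), upper = c(0.8, 12), integer = c(FALSE, TRUE),
        setter = function(p, x) {
          p$TUpprol <- x[1]
          p$TUpmax <- as.integer(round(x[2]))
          p
        })
  stage("apoptosis", "TUpdeath",
        lower = 0.005, upper = 0.4, integer = FALSE,
        setter = function(p, x) {
          p$TUpdeath <- x[1]
          p
        })
  stage("fibroblast_mono", c("Fpprol", "Fpmax", "Fpdeath"),
        lower = c(0.02, 2, 0.001), upper = c(0.6, 12, 0.2),
        integer = c(FALSE, TRUE, FALSE),
        setter = function(p, x) {
          p$Fpprol <- x[1]
          p$Fpmax <- as.integer(round(x[2]))
          p$Fpdeath <- x[3]
          p
        })
  stage("tumor_fib_m1", c("M1pkill", "M1kmax"),
        lower = c(0.05, 1), upper = c(1, 12), integer = c(FALSE, TRUE),
        setter = function(p, x) {
          p$M1pkill <- x[1]
          p$M1kmax <- as.integer(round(x[2]))
          p
        })
  stage("tumor_fib_m2", "M2pkill",
        lower = 0.01, upper = 1, integer = FALSE,
        setter = function(p, x) {
          p$M2pkill <- x[1]
          p
        })
  p$M2kmax <- p$M1kmax  # assumed equivalent to M1kmax
  prov["M2kmax"] <- "assumed:M1kmax"
  p <- normalize_parameters(p)
  validate_parameters(p)
  class(p) <- "abm_params"
  attr(p, "provenance") <- prov
  attr(p, "fits") <- fits
  p
}
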