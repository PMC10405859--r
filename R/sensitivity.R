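#' Parameters screened by the sensitivity analysis
#'
#' All individual action parameters of the model: probabilities, additive
#' increments, integer caps and mutation thresholds. Structural settings
#' (geometry, interaction ranges, switches) are excluded.
#'
#' @return Character vector of parameter names.
#' @export
perturbable_parameters <- function() {
  c(setdiff(param_prob_fields(), character()), param_bonus_fields(),
    c("TUpmax", "TUaddedMax", "TUthrshBM", "TUthrshM", "TUthrshMMP",
      "Fpmax", "M1kmax", "M2kmax"))
}

# +10% perturbation with the documented integer rule: round half away
# from zero; integers unchanged by rounding step by +1. Returns NA when
# the parameter cannot be increased (probability at 1, or value 0).
perturb_value <- function(params, name) {
  v <- params[[name]]
  if (v == 0) return(NA_real_)
  if (name %in% param_int_fields()) {
    nv <- floor(abs(v) * 1.1 + 0.5) * sign(v)
    if (nv == v) nv <- v + 1L
    return(as.integer(nv))
  }
  nv <- v * 1.1
  if (name %in% param_prob_fields()) {
    if (v >= 1) return(NA_real_)
    nv <- min(1, nv)
  }
  nv
}

# tumor load (mutated cells at the final step) of one acinus run
acinus_tumor_load <- function(params, config, seed) {
  cfg <- config
  cfg$params <- params
  run_acinus(cfg, seed = seed)$tumor_load_400d
}

#' One-at-a-time +10% parameter sensitivity screen
#'
#' Each parameter is increased individually by 10% (integer caps and
#' thresholds are rounded half away from zero and bumped by one when
#' rounding leaves them unchanged) and the percentage change in tumor load
#' at 400 days is recorded, averaged over `reps` paired replicates.
#' Baseline replicate `i` and every perturbed replicate `i` share the
#' child seed `base_seed + i` (common random numbers), so a parameter with
#' no pathway to the output yields exactly 0% change. A parameter is
#' flagged sensitive when its mean absolute change exceeds 10%.
#'
#' @param base base parameter set.
#' @param reps replicates per condition (default 10).
#' @param config an [acinus_config()] (its `params` are replaced).
#' @param base_seed integer; replicate seeds are `base_seed + 1:reps`.
#' @param parameters which parameters to screen (default all
#'   [perturbable_parameters()]).
#' @return A `sensitivity_table` data frame: `parameter`,
#'   `baseline_value`, `perturbed_value`, `mean_baseline`,
#'   `mean_perturbed`, `pct_change`, `flag_sensitive`, plus a list column
#'   `loads` of per-replicate perturbed tumor loads. Parameters that
#'   cannot be increased are reported with `perturbed_value = NA` and
#'   excluded from flagging. Baseline per-replicate loads are stored in
#'   the `baseline_loads` attribute.
#' @export
oat_sensitivity <- function(base = default_parameters(), reps = 10L,
                            config = acinus_config(), base_seed = 0L,
                            parameters = perturbable_parameters()) {
  stopifnot(reps >= 2)
  seeds <- base_seed + seq_len(reps)
  baseline <- vapply(seeds, function(s) acinus_tumor_load(base, config, s),
                     numeric(1))
  mb <- mean(baseline)
  rows <- lapply(parameters, function(nm) {
    pv <- perturb_value(base, nm)
    if (is.na(pv)) {
      return(data.frame(parameter = nm, baseline_value = base[[nm]],
                        perturbed_value = NA_real_, mean_baseline = mb,
                        mean_perturbed = NA_real_, pct_change = NA_real_,
                        flag_sensitive = NA, stringsAsFactors = FALSE))
    }
    p2 <- base
    p2[[nm]] <- pv
    loads <- vapply(seeds, function(s) acinus_tumor_load(p2, config, s),
                    numeric(1))
    pct <- if (mb > 0) (mean(loads) - mb) / mb * 100 else NA_real_
    df <- data.frame(parameter = nm, baseline_value = base[[nm]],
                     perturbed_value = as.numeric(pv), mean_baseline = mb,
                     mean_perturbed = mean(loads), pct_change = pct,
                     flag_sensitive = !is.na(pct) && abs(pct) > 10,
                     stringsAsFactors = FALSE)
    df$loads <- I(list(loads))
    df
  })
  rows <- lapply(rows, function(d) {
    if (is.null(d$loads)) d$loads <- I(list(NULL))
    d
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline_loads") <- baseline
  attr(out, "reps") <- reps
  class(out) <- c("sensitivity_table", class(out))
  out
}

#' Sweep one parameter over a set of values
#'
#' For each value, the parameter is fixed and `reps` paired replicates are
#' run; the tumor load at 400 days is reported relative to the baseline
#' mean (same seeds, unmodified parameters).
#'
#' @param param parameter name.
#' @param values numeric vector of values (the follow-up analyses use 10
#'   intermediate values in the region of interest).
#' @inheritParams oat_sensitivity
#' @return Data frame `value`, `mean_load`, `sd_load`, `mean_rel`,
#'   `sd_rel` (relative to baseline mean).
#' @export
sweep_parameter <- function(param, values, reps = 10L,
                            base = default_parameters(),
                            config = acinus_config(), base_seed = 0L) {
  if (!param %in% names(base)) stop("unknown parameter: ", param)
  seeds <- base_seed + seq_len(reps)
  baseline <- vapply(seeds, function(s) acinus_tumor_load(base, config, s),
                     numeric(1))
  mb <- mean(baseline)
  rows <- lapply(values, function(v) {
    p2 <- base
    p2[[param]] <- if (param %in% param_int_fields()) as.integer(round(v))
                   else v
    loads <- vapply(seeds, function(s) acinus_tumor_load(p2, config, s),
                    numeric(1))
    data.frame(value = v, mean_load = mean(loads), sd_load = sd(loads),
               mean_rel = mean(loads) / mb, sd_rel = sd(loads) / mb)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline_mean") <- mb
  attr(out, "parameter") <- param
  out
}

#' Pairwise sweep of two parameters
#'
#' Runs the model on the full grid of `values1` x `values2` (five values
#' each in the follow-up protocol) and reports mean tumor load at 400 days
#' relative to the baseline mean, exposing synergistic or antagonistic
#' interactions between sensitive parameters.
#'
#' @param p1,p2 distinct parameter names.
#' @param values1,values2 value grids for `p1` and `p2`.
#' @inheritParams oat_sensitivity
#' @return Numeric matrix (`length(values1)` x `length(values2)`) of mean
#'   relative tumor loads, with the values as dimnames.
#' @export
pairwise_sweep <- function(p1, p2, values1, values2, reps = 10L,
                           base = default_parameters(),
                           config = acinus_config(), base_seed = 0L) {
  if (identical(p1, p2)) stop("p1 and p2 must be distinct parameters")
  if (!p1 %in% names(base)) stop("unknown parameter: ", p1)
  if (!p2 %in% names(base)) stop("unknown parameter: ", p2)
  seeds <- base_seed + seq_len(reps)
  baseline <- vapply(seeds, function(s) acinus_tumor_load(base, config, s),
                     numeric(1))
  mb <- mean(baseline)
  m <- matrix(NA_real_, length(values1), length(values2),
              dimnames = list(format(values1), format(values2)))
  for (i in seq_along(values1)) for (j in seq_along(values2)) {
    pp <- base
    pp[[p1]] <- if (p1 %in% param_int_fields())
      as.integer(round(values1[i])) else values1[i]
    pp[[p2]] <- if (p2 %in% param_int_fields())
      as.integer(round(values2[j])) else values2[j]
    loads <- vapply(seeds, function(s) acinus_tumor_load(pp, config, s),
                    numeric(1))
    m[i, j] <- mean(loads) / mb
  }
  attr(m, "baseline_mean") <- mb
  m
}
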