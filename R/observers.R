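#' Disease stages of the acinus model
#'
#' @return Character vector of the cumulative stage sequence, from healthy
#'   acinus to invasive cancer.
#' @export
stage_levels <- function() {
  c("healthy", "mutated", "pin", "basal_breach", "caf_present",
    "m2_present", "bm_breakdown", "emt", "invasive_cancer")
}

#' Detect the disease stage of an acinus state
#'
#' Stages are cumulative; the most advanced stage whose defining predicate
#' holds is returned: `mutated` (any mutated cell), `pin` (mutated cells
#' growing into the lumen), `basal_breach` (mutated cells occupying the
#' basal layer), `caf_present`, `m2_present`, `bm_breakdown` (at least one
#' destroyed basement-membrane position), `emt` (any cell past
#' epithelial-mesenchymal transition) and `invasive_cancer` (a mutated
#' cell strictly outside the original basement-membrane ring).
#'
#' @param state a `grid_state` carrying acinus metadata (`region_code`,
#'   `bm_initial`).
#' @return A single character stage, one of [stage_levels()].
#' @export
detect_stage <- function(state) {
  if (is.null(state$region_code))
    stop("state carries no region_code; stages are defined for the acinus model")
  a <- state$agents
  rc <- region_codes()
  mut <- a[a$kind == "tumor" | (a$kind == "stem" & a$mutations > 0), ,
           drop = FALSE]
  code_at <- function(df) state$region_code[cbind(df$row + 1L, df$col + 1L)]
  pred <- c(
    healthy = TRUE,
    mutated = nrow(mut) > 0,
    pin = nrow(mut) > 0 && any(code_at(mut) == rc[["lumen"]]),
    basal_breach = nrow(mut) > 0 && any(code_at(mut) == rc[["basal"]]),
    caf_present = any(a$kind == "caf"),
    m2_present = any(a$kind == "m2"),
    bm_breakdown = sum(state$passive == 1L) < state$bm_initial,
    emt = any(a$emt),
    invasive_cancer = nrow(mut) > 0 && any(code_at(mut) >= rc[["fibroblast"]])
  )
  stage_levels()[max(which(pred))]
}

#' Per-run and batch summaries of acinus simulations
#'
#' Turns a batch of `abm_result` objects into the model's endpoints: per
#' run, whether the basement membrane was breached (`developed_cancer`,
#' the cancer marker), the invasion time, the tumor load at 400 days
#' (mutated cells at the final step) and the covariates recorded at the
#' moment of breakdown (CAF count, mean mutation load, M2:M1 ratio).
#'
#' @param batch a list of `abm_result` objects (e.g. from
#'   [run_acinus_batch()]).
#' @return A data frame with one row per run; attributes
#'   `cancer_fraction` (fraction of all runs that broke the membrane) and
#'   `n_runs`.
#' @export
summarize_batch <- function(batch) {
  rows <- lapply(seq_along(batch), function(i) {
    r <- batch[[i]]
    ms <- r$milestones
    inv <- r$invasion_covariates
    last <- r$timeseries[nrow(r$timeseries), ]
    data.frame(
      run = i,
      seed = if (is.null(r$seed)) NA_integer_ else r$seed,
      developed_cancer = !is.na(ms[["bm_breakdown"]]),
      invasion_step = ms[["bm_breakdown"]],
      invasion_days = ms[["bm_breakdown"]] / 2,
      tumor_load = last$n_mutated,
      n_caf_final = last$n_caf,
      caf_at_invasion = inv[["n_caf"]],
      mutation_load_at_invasion = inv[["mean_mutations"]],
      m2_m1_at_invasion = inv[["m2_m1_ratio"]],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "cancer_fraction") <- mean(out$developed_cancer)
  attr(out, "n_runs") <- nrow(out)
  out
}

#' Rank-sum comparison of two invasion-time samples
#'
#' One-sided Wilcoxon rank-sum test that the first sample of invasion
#' times is stochastically smaller (earlier invasion) than the second.
#'
#' @param t1,t2 numeric vectors of invasion times (steps or days).
#' @param alternative passed to [stats::wilcox.test()] (default `"less"`).
#' @return The `htest` object.
#' @export
invasion_time_test <- function(t1, t2, alternative = "less") {
  t1 <- t1[!is.na(t1)]
  t2 <- t2[!is.na(t2)]
  wilcox.test(t1, t2, alternative = alternative, exact = FALSE)
}
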