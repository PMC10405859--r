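#' High/low parameter values of the eight in-silico patient groups
#'
#' The cohort varies the four most sensitive parameters along three axes:
#' CAF tumor promotion (`CFprom`), macrophage phenotype (merged axis:
#' protumor = high `M1pmig` with low `TUthrshM`, antitumor = low `M1pmig`
#' with high `TUthrshM`) and tumor mutation probability (`TUpmut`). The
#' shipped numbers are surrogate values chosen from the sensitivity
#' sweeps' region of interest (see the package vignette); override them to
#' explore other stratifications.
#'
#' @return Named list of two-value vectors (`low`, `high`) per parameter.
#' @export
default_group_values <- function() {
  list(CFprom = c(low = 0.1, high = 0.4),
       M1pmig = c(low = 0.6, high = 0.95),
       TUthrshM = c(low = 2L, high = 5L),
       TUpmut = c(low = 1.2e-03, high = 6.5e-03))
}

#' The eight in-silico patient groups
#'
#' All 2 x 2 x 2 combinations of the three axes (CAF promotion, macrophage
#' phenotype, mutation probability).
#'
#' @param values a [default_group_values()]-style list.
#' @return Data frame with one row per group: axis levels, the four
#'   parameter values, and a `label`.
#' @export
group_definitions <- function(values = default_group_values()) {
  g <- expand.grid(caf_axis = c("low", "high"),
                   mac_axis = c("antitumor", "protumor"),
                   mut_axis = c("low", "high"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$CFprom <- values$CFprom[g$caf_axis]
  g$M1pmig <- ifelse(g$mac_axis == "protumor", values$M1pmig[["high"]],
                     values$M1pmig[["low"]])
  g$TUthrshM <- ifelse(g$mac_axis == "protumor",
                       values$TUthrshM[["low"]], values$TUthrshM[["high"]])
  g$TUpmut <- values$TUpmut[g$mut_axis]
  g$label <- sprintf("CAF%s_MAC%s_MUT%s", g$caf_axis,
                     ifelse(g$mac_axis == "protumor", "pro", "anti"),
                     g$mut_axis)
  stopifnot(nrow(g) == 8, !anyDuplicated(g$label))
  g
}

#' Apply a group definition to a base parameter set
#'
#' Overrides exactly the four designated parameters (`CFprom`, `M1pmig`,
#' `TUthrshM`, `TUpmut`); every other field is untouched. Applying the
#' same group twice is idempotent.
#'
#' @param base an `abm_params` list.
#' @param group one row of [group_definitions()] (data frame or list).
#' @return The modified `abm_params`.
#' @export
build_group_params <- function(base, group) {
  p <- base
  p$CFprom <- as.numeric(group$CFprom)
  p$M1pmig <- as.numeric(group$M1pmig)
  p$TUthrshM <- as.integer(group$TUthrshM)
  p$TUpmut <- as.numeric(group$TUpmut)
  validate_parameters(p)
  p
}

#' Simulate the in-silico patient cohort
#'
#' For each group, acinus simulations are run (child seeds derived from
#' `base_seed`) until `target_cancer_runs` runs reach basement-membrane
#' breakdown or `max_attempts` is exhausted. The cancer fraction is
#' recorded over all attempts; tumor-load trajectories are averaged over
#' the cancer-developing runs only, matching how developed tumors are
#' compared with clinical cohorts.
#'
#' @param groups data frame from [group_definitions()].
#' @param base base parameter set the group values override.
#' @param config an [acinus_config()] (its `params` are replaced per
#'   group).
#' @param target_cancer_runs cancer-developing runs wanted per group.
#' @param max_attempts simulation budget per group.
#' @param base_seed integer; group `g`, attempt `k` uses seed
#'   `base_seed + 10000 * g + k`.
#' @return A list of class `cohort_result`: `summary` (per-group data
#'   frame with attempts, cancer fraction, mean tumor load), `runs`
#'   (per-group per-run data), `trajectories` (per-group matrix of
#'   mutated-cell counts over time for cancer runs), `invasion_times`
#'   (per-group numeric vectors, in days).
#' @export
run_cohort <- function(groups = group_definitions(),
                       base = default_parameters(),
                       config = acinus_config(),
                       target_cancer_runs = 40L, max_attempts = 200L,
                       base_seed = 0L) {
  res_summary <- list()
  res_runs <- list()
  res_traj <- list()
  res_inv <- list()
  for (g in seq_len(nrow(groups))) {
    grp <- groups[g, ]
    cfg <- config
    cfg$params <- build_group_params(base, grp)
    n_cancer <- 0L
    attempts <- 0L
    runs <- list()
    traj <- list()
    while (n_cancer < target_cancer_runs && attempts < max_attempts) {
      attempts <- attempts + 1L
      seed <- base_seed + 10000L * g + attempts
      r <- run_acinus(cfg, seed = seed)
      runs[[attempts]] <- data.frame(
        group = grp$label, attempt = attempts, seed = seed,
        developed_cancer = r$developed_cancer,
        invasion_days = r$milestones[["bm_breakdown"]] / 2,
        tumor_load = r$tumor_load_400d, stringsAsFactors = FALSE)
      if (r$developed_cancer) {
        n_cancer <- n_cancer + 1L
        traj[[n_cancer]] <- r$timeseries$n_mutated
      }
    }
    runs <- do.call(rbind, runs)
    res_runs[[grp$label]] <- runs
    res_inv[[grp$label]] <-
      runs$invasion_days[runs$developed_cancer]
    res_traj[[grp$label]] <- if (n_cancer > 0)
      do.call(rbind, traj) else NULL
    cancer_loads <- runs$tumor_load[runs$developed_cancer]
    res_summary[[g]] <- data.frame(
      group = grp$label, caf_axis = grp$caf_axis,
      mac_axis = grp$mac_axis, mut_axis = grp$mut_axis,
      attempts = attempts, n_cancer = n_cancer,
      cancer_fraction = n_cancer / attempts,
      mean_tumor_load = if (n_cancer > 0) mean(cancer_loads) else NA_real_,
      median_invasion_days = if (n_cancer > 0)
        median(runs$invasion_days[runs$developed_cancer]) else NA_real_,
      stringsAsFactors = FALSE)
  }
  structure(list(summary = do.call(rbind, res_summary),
                 runs = res_runs, trajectories = res_traj,
                 invasion_times = res_inv, groups = groups),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result> ", nrow(x$summary), " groups\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Default molecular-marker specification of the three axes
#'
#' Three markers per axis, each with a sign giving the direction of the
#' high phenotype: tumor aggressiveness from tumor mutational burden and
#' TP53 / CDKN1B expression; protumor macrophage characterization from
#' the M2:M1 ratio and CXCL2 / STAT3 expression; CAF promotion from the
#' deconvolved CAF fraction and TGFBR2 / IGF1 expression, IGF1 entering
#' with an inverse relationship.
#'
#' @return Named list of axes, each a list with `markers` and `signs`.
#' @export
default_axis_specs <- function() {
  list(
    caf = list(markers = c("CAF", "TGFBR2", "IGF1"), signs = c(1, 1, -1)),
    mac = list(markers = c("M2M1_ratio", "CXCL2", "STAT3"),
               signs = c(1, 1, 1)),
    mut = list(markers = c("TMB", "TP53", "CDKN1B"), signs = c(1, 1, 1))
  )
}

#' Assign patients to the eight groups by the 2-of-3 median rule
#'
#' Per axis, each marker is binarized at the cohort median (markers with
#' sign -1 vote "high" when below the median); a patient is "high" on the
#' axis when at least two of its three markers vote high. Values equal to
#' the median never count as above it. The rule is invariant to any
#' monotone transform of a marker column.
#'
#' @param markers data frame: one row per patient, marker columns, plus an
#'   optional `patient_id` column.
#' @param axis_specs a [default_axis_specs()]-style list with exactly
#'   three markers (and signs) per axis.
#' @return Data frame `patient_id`, `caf_axis`, `mac_axis`, `mut_axis`,
#'   `group` (a label matching [group_definitions()]).
#' @export
classify_patients <- function(markers, axis_specs = default_axis_specs()) {
  id <- if ("patient_id" %in% names(markers)) markers$patient_id
        else seq_len(nrow(markers))
  axis_level <- function(spec) {
    if (length(spec$markers) != 3 || length(spec$signs) != 3)
      stop("each axis needs exactly 3 markers with signs")
    votes <- matrix(FALSE, nrow(markers), 3)
    for (j in 1:3) {
      mk <- spec$markers[j]
      if (!mk %in% names(markers)) stop("marker column missing: ", mk)
      v <- markers[[mk]]
      if (anyNA(v)) stop("marker has missing values: ", mk)
      med <- median(v)
      if (all(v == med))
        stop("marker is constant across the cohort (median split undefined): ",
             mk)
      votes[, j] <- if (spec$signs[j] >= 0) v > med else v < med
    }
    ifelse(rowSums(votes) >= 2, "high", "low")
  }
  caf <- axis_level(axis_specs$caf)
  mac <- axis_level(axis_specs$mac)
  mut <- axis_level(axis_specs$mut)
  data.frame(
    patient_id = id, caf_axis = caf,
    mac_axis = ifelse(mac == "high", "protumor", "antitumor"),
    mut_axis = mut,
    group = sprintf("CAF%s_MAC%s_MUT%s", caf,
                    ifelse(mac == "high", "pro", "anti"), mut),
    stringsAsFactors = FALSE)
}
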