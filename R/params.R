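#' Default model parameter set
#'
#' Returns the full named parameter set of the agent-based model. All
#' action parameters are probabilities per 12-hour step unless they are
#' integer caps (`*max`), mutation thresholds (`TUthrsh*`), additive
#' probability increments (`TUaddedProl`, `CFprom`, `M2TUadd`,
#' `M1influxadd`) or geometry ranges (grid spaces).
#'
#' Tumor-cell parameters (`TUpprol`, `TUpmax`, `TUpdeath`, fibroblast and
#' macrophage kill parameters) carry defaults of the kind obtained by
#' fitting LNCaP / BJ-fibroblast / THP-1 style growth and apoptosis curves
#' (see [sequential_calibration()]); the remaining values are qualitative
#' defaults chosen so that the model reproduces the canonical behaviors
#' documented in the package vignette (tumor-maintenance plateaus,
#' basement-membrane breakdown in a minority of runs). They can all be
#' overridden via [load_config()] or by editing the returned list.
#'
#' @param ... named overrides of individual parameters.
#' @return A named list of class `abm_params`.
#' @examples
#' p <- default_parameters(TUpmut = 0)
#' p$TUpmut
#' @export
default_parameters <- function(...) {
  p <- list(
    # tumor cells
    TUpprol = 0.55,       # proliferation probability
    TUpmig = 0.4,         # migration probability (EMT cells only)
    TUpdeath = 0.06,      # spontaneous death probability
    TUpmut = 2.1e-03,     # mutation probability (also luminal -> tumor)
    TUpmax = 5L,          # division budget of a new tumor lineage
    TUaddedProl = 0.015,  # proliferation bonus per mutation
    TUaddedMax = 1L,      # division-budget bonus per mutation
    TUmutEscalation = 0.75,  # relative increase of TUpmut per mutation
    TUthrshBM = 5L,       # mutations needed to attack the basement membrane
    TUthrshM = 3L,        # mutations needed to polarize macrophages
    TUthrshMMP = 6L,      # mutations needed to cleave ECM
    TUpkill = 0.3,        # BM breakdown probability (above TUthrshBM)
    TUpMdiff = 0.4,       # M1 -> M2 polarization probability (above TUthrshM)
    TUpMMP = 0.2,         # ECM breakdown probability (above TUthrshMMP)
    # luminal / basal epithelium
    LCpprol = 0.01,
    LCpdeath = 0.001,
    BCpprol = 0.01,
    BCpdeath = 0.002,
    # fibroblasts
    Fdiff = 0.05,         # CAF differentiation when tumor within range 2
    Fpprol = 0.1,         # in vitro proliferation (culture model)
    Fpmax = 6L,
    Fpdeath = 0.005,
    # cancer-associated fibroblasts
    CFpprol = 0.25,
    CFpdeath = 0.005,
    CFmmp = 0.1,          # ECM breakdown
    CFmdiff = 0.2,        # M1 -> M2 polarization
    CFemt = 0.05,         # EMT induction in adjacent tumor cells
    CFprom = 0.25,        # proliferation bonus for adjacent tumor cells
    # macrophages
    M1influxProb = 0.3,
    M1influxadd = 0.4,    # influx bonus once tumor cells are detected
    M1pkill = 0.5,
    M1pdeath = 0.002,
    M1pmig = 0.9,
    M1kmax = 4L,
    M2pkill = 0.05,
    M2kmax = 4L,
    M2TUadd = 0.15,       # proliferation bonus for adjacent tumor cells
    M2emt = 0.05,         # EMT induction in adjacent tumor cells
    # stem cells
    SCrenew = 0.25,       # probability a stem division yields two stem cells
    SCpdeath = 0.03,      # spontaneous death of (mutated) stem cells
    # geometry / ranges (grid spaces)
    sensing_radius = 17L,
    caf_induction_range = 2L,
    macrophage_move_range = 2L,
    lumen_radius = 13L,
    # switches
    sticky_detection = TRUE,
    stem_mutation = TRUE
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  p <- normalize_parameters(p)
  validate_parameters(p)
  class(p) <- "abm_params"
  p
}

# names of parameters by storage type
param_prob_fields <- function() {
  c("TUpprol", "TUpmig", "TUpdeath", "TUpmut", "TUpkill", "TUpMdiff",
    "TUpMMP", "LCpprol", "LCpdeath", "BCpprol", "BCpdeath", "Fdiff",
    "Fpprol", "Fpdeath", "CFpprol", "CFpdeath", "CFmmp", "CFmdiff",
    "CFemt", "M1influxProb", "M1pkill", "M1pdeath", "M1pmig", "M2pkill",
    "M2emt", "SCrenew", "SCpdeath")
}
param_bonus_fields <- function() {
  # additive probability increments; effective probabilities clamp at 1
  c("TUaddedProl", "TUmutEscalation", "CFprom", "M1influxadd", "M2TUadd")
}
param_int_fields <- function() {
  c("TUpmax", "TUaddedMax", "TUthrshBM", "TUthrshM", "TUthrshMMP", "Fpmax",
    "M1kmax", "M2kmax", "sensing_radius", "caf_induction_range",
    "macrophage_move_range", "lumen_radius")
}

normalize_parameters <- function(p) {
  for (f in param_int_fields()) p[[f]] <- as.integer(round(p[[f]]))
  for (f in c(param_prob_fields(), param_bonus_fields())) {
    p[[f]] <- as.numeric(p[[f]])
  }
  p$sticky_detection <- isTRUE(p$sticky_detection)
  p$stem_mutation <- isTRUE(p$stem_mutation)
  p
}

#' Validate a parameter set
#'
#' Checks that every probability lies in \[0, 1\], that integer caps and
#' thresholds are non-negative, and that no unknown field is present.
#'
#' @param p a parameter list as returned by [default_parameters()].
#' @return `p`, invisibly; errors name the offending field.
#' @export
validate_parameters <- function(p) {
  ref <- c(param_prob_fields(), param_bonus_fields(), param_int_fields(),
           "sticky_detection", "stem_mutation")
  missing <- setdiff(ref, names(p))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  unknown <- setdiff(names(p), ref)
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  for (f in param_prob_fields()) {
    v <- p[[f]]
    if (!is.finite(v) || v < 0 || v > 1)
      stop(sprintf("parameter %s = %s is not a probability in [0, 1]", f, v))
  }
  for (f in param_bonus_fields()) {
    v <- p[[f]]
    if (!is.finite(v) || v < 0)
      stop(sprintf("parameter %s = %s must be a non-negative increment", f, v))
  }
  for (f in param_int_fields()) {
    v <- p[[f]]
    if (is.na(v) || v < 0)
      stop(sprintf("parameter %s = %s must be a non-negative integer", f, v))
  }
  invisible(p)
}

#' @export
print.abm_params <- function(x, ...) {
  cat("<abm_params> ", length(x), " parameters\n", sep = "")
  flat <- vapply(x, function(v) format(v), character(1))
  print(noquote(flat))
  invisible(x)
}
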