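#' Configuration of the minimal tumor-maintenance model
#'
#' The minimal model seeds tumor cells and cancer stem cells uniformly at
#' random on an otherwise empty lattice and lets them proliferate, die and
#' (optionally) mutate. It exists to test three tumor-maintenance
#' scenarios: stem cells only (`"stem_only"`, no mutations allowed),
#' mutations only (`"mutation_only"`, no stem cells) and the combination
#' (`"combined"`).
#'
#' @param scenario one of `"stem_only"`, `"mutation_only"`, `"combined"`.
#' @param n_seed number of cells seeded at step 0 (default 1500).
#' @param sc_start fraction of seeded cells that are stem cells; must be 0
#'   for `"mutation_only"` and positive otherwise.
#' @param pmut per-step mutation probability; 0 disables mutation and is
#'   required for `"stem_only"`.
#' @param n_steps simulated steps (default 800 = 400 days).
#' @param params base parameter set; `TUpmut` is overridden by `pmut`.
#' @param width,height grid dimensions.
#' @param record_every,record_events see [simulate_steps()].
#' @return A list of class `minimal_config`.
#' @export
minimal_config <- function(scenario = c("combined", "stem_only",
                                        "mutation_only"),
                           n_seed = 1500L, sc_start = NULL, pmut = NULL,
                           n_steps = 800L, params = default_parameters(),
                           width = 125L, height = 125L, record_every = 4L,
                           record_events = FALSE) {
  scenario <- match.arg(scenario)
  if (is.null(sc_start))
    sc_start <- switch(scenario, stem_only = 0.05, mutation_only = 0,
                       combined = 0.05)
  if (is.null(pmut))
    pmut <- switch(scenario, stem_only = 0, mutation_only = 0.005,
                   combined = 0.005)
  if (sc_start < 0 || sc_start > 1) stop("sc_start must be in [0, 1]")
  if (scenario == "stem_only" && pmut != 0)
    stop("stem_only scenario requires pmut = 0")
  if (scenario == "mutation_only" && sc_start != 0)
    stop("mutation_only scenario requires sc_start = 0")
  if (scenario == "mutation_only" && pmut <= 0)
    stop("mutation_only scenario requires pmut > 0")
  if (scenario == "combined" && (sc_start <= 0 || pmut <= 0))
    stop("combined scenario requires sc_start > 0 and pmut > 0")
  structure(list(scenario = scenario, n_seed = as.integer(n_seed),
                 sc_start = sc_start, pmut = pmut,
                 n_steps = as.integer(n_steps), params = params,
                 width = as.integer(width), height = as.integer(height),
                 record_every = as.integer(record_every),
                 record_events = isTRUE(record_events)),
            class = "minimal_config")
}

#' Seed the minimal model grid
#'
#' Places exactly `n_seed` cells uniformly at random on distinct grid
#' positions; `round(n_seed * sc_start)` of them are stem cells with
#' unlimited division budget, the rest tumor cells with a division budget
#' of `TUpmax`.
#'
#' @param config a [minimal_config()].
#' @return A `grid_state`.
#' @export
init_minimal <- function(config) {
  w <- config$width
  h <- config$height
  if (config$n_seed > w * h)
    stop(sprintf("n_seed = %d exceeds grid capacity %d", config$n_seed,
                 w * h))
  pos <- sample.int(w * h, config$n_seed) - 1L
  row <- pos %/% w
  col <- pos %% w
  n_stem <- round(config$n_seed * config$sc_start)
  kind <- rep("tumor", config$n_seed)
  if (n_stem > 0) kind[seq_len(n_stem)] <- "stem"
  agents <- data.frame(
    id = seq_len(config$n_seed), kind = kind, row = row, col = col,
    mutations = 0L,
    divisions_left = ifelse(kind == "stem", Inf,
                            config$params$TUpmax),
    kills_left = 0L, emt = FALSE, age = 0L, stringsAsFactors = FALSE)
  new_grid_state(width = w, height = h, agents = agents)
}

#' Run a tumor-maintenance scenario of the minimal model
#'
#' Returns per-step tumor-cell counts and stem-cell percentages (stem /
#' (stem + tumor) x 100; 0 when no cells remain). The run stops early at
#' extinction.
#'
#' @param config a [minimal_config()]; alternatively pass a scenario name
#'   plus overrides through `...`.
#' @param seed integer seed making the run reproducible.
#' @return An `abm_result`, with `$extinction_step` set when the
#'   population died out.
#' @examples
#' \donttest{
#' res <- run_minimal(minimal_config("mutation_only", n_steps = 100),
#'                    seed = 1)
#' res$extinction_step  # all tumor cells dead well before day 40
#' }
#' @export
run_minimal <- function(config = minimal_config(), seed = NULL) {
  stopifnot(inherits(config, "minimal_config"))
  if (!is.null(seed)) set.seed(seed)
  params <- config$params
  params$TUpmut <- config$pmut
  validate_parameters(params)
  state <- init_minimal(config)
  res <- simulate_steps(state, params, config$n_steps, model = "minimal",
                        record_every = config$record_every,
                        record_events = config$record_events)
  res$scenario <- config$scenario
  res$config <- config
  res
}

#' @rdname run_minimal
#' @param scenario scenario name, see [minimal_config()].
#' @param ... overrides passed to [minimal_config()].
#' @export
run_scenario <- function(scenario, ..., seed = NULL) {
  run_minimal(minimal_config(scenario, ...), seed = seed)
}

#' Plateau statistics of a minimal-model run
#'
#' Mean tumor count and stem percentage over the final fraction of the
#' recorded time series ("almost full grid" plateau detection).
#'
#' @param result an `abm_result` from [run_minimal()].
#' @param frac fraction of the trajectory tail to average (default 0.1).
#' @return Named numeric vector `tumor_count`, `stem_pct`, `total`.
#' @export
plateau_stats <- function(result, frac = 0.1) {
  ts <- result$timeseries
  n <- nrow(ts)
  tail_rows <- ts[seq.int(max(1L, ceiling(n * (1 - frac))), n), ]
  c(tumor_count = mean(tail_rows$n_tumor),
    stem_pct = mean(tail_rows$stem_pct),
    total = mean(tail_rows$n_tumor + tail_rows$n_stem))
}
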