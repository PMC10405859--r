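#' @useDynLib prostasim, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rnorm median wilcox.test setNames sd quantile
#' @importFrom utils write.csv read.csv modifyList
NULL

#' Agent kinds, event types and passive-layer codes
#'
#' The engine stores agent kinds and event types as character strings in
#' all R-facing tables; these helpers give the canonical orderings used by
#' the integer codes of the compiled core and of grid snapshots.
#'
#' @return A character vector of level names.
#' @export
kind_levels <- function() {
  c("luminal", "basal", "stem", "tumor", "fibroblast", "caf", "m1", "m2")
}

#' @rdname kind_levels
#' @export
event_levels <- function() {
  c("birth", "death", "mutation", "differentiation", "breakdown",
    "migration", "kill", "influx", "emt")
}

#' @rdname kind_levels
#' @export
passive_levels <- function() c("empty", "basement_membrane", "ecm")

kind_code <- function(kind) {
  i <- match(kind, kind_levels())
  if (anyNA(i)) stop("unknown agent kind: ",
                     paste(unique(kind[is.na(i)]), collapse = ", "))
  i - 1L
}

empty_agents <- function() {
  data.frame(id = integer(), kind = character(), row = integer(),
             col = integer(), mutations = integer(),
             divisions_left = numeric(), kills_left = integer(),
             emt = logical(), age = integer(), stringsAsFactors = FALSE)
}

#' Construct a grid state
#'
#' A `grid_state` bundles the occupancy of a rectangular lattice: a passive
#' layer matrix (`"empty"`, `"basement_membrane"` or `"ecm"` per position),
#' a data frame of agents, and optional acinus metadata (physiologic region
#' masks, initial ring codes, macrophage entry positions). Coordinates are
#' 0-based `(row, col)`; a position holds at most one agent and an agent
#' never sits on a basement-membrane or ECM position.
#'
#' @param width,height grid dimensions in grid spaces (default 125 x 125).
#' @param agents data frame with columns `id`, `kind`, `row`, `col`,
#'   `mutations`, `divisions_left` (`Inf` for stem cells), `kills_left`,
#'   `emt`, `age`.
#' @param passive integer or character matrix of passive layer content;
#'   defaults to all-empty.
#' @param luminal_region,basal_region logical matrices marking the
#'   physiologic regions of luminal and basal cells (acinus model).
#' @param region_code integer matrix of initial ring codes
#'   (0 lumen, 1 luminal, 2 basal, 3 basement membrane, 4 fibroblast
#'   layer, 5 ECM); required by the acinus model.
#' @param entry integer matrix (0-based `row`, `col`) of macrophage entry
#'   positions.
#' @param detection logical; whether macrophages have already detected
#'   tumor cells.
#' @param step_index current step counter (1 step = 12 h).
#' @return A list of class `grid_state`.
#' @export
new_grid_state <- function(width = 125L, height = 125L,
                           agents = empty_agents(), passive = NULL,
                           luminal_region = NULL, basal_region = NULL,
                           region_code = NULL, entry = NULL,
                           detection = FALSE, step_index = 0L) {
  width <- as.integer(width)
  height <- as.integer(height)
  if (is.null(passive)) {
    passive <- matrix(0L, height, width)
  } else if (is.character(passive)) {
    passive <- matrix(match(passive, passive_levels()) - 1L, nrow(passive),
                      ncol(passive))
  }
  storage.mode(passive) <- "integer"
  st <- structure(list(width = width, height = height, agents = agents,
                       passive = passive, luminal_region = luminal_region,
                       basal_region = basal_region,
                       region_code = region_code, entry = entry,
                       detection = isTRUE(detection),
                       step_index = as.integer(step_index),
                       bm_initial = sum(passive == 1L),
                       next_id = if (nrow(agents)) max(agents$id) + 1L else 1L),
                  class = "grid_state")
  check_state(st)
  st
}

check_state <- function(state) {
  a <- state$agents
  if (nrow(a)) {
    if (any(a$row < 0 | a$row >= state$height | a$col < 0 |
            a$col >= state$width))
      stop("agent position outside the grid")
    pos <- a$row * state$width + a$col
    if (anyDuplicated(pos)) stop("two agents share a grid position")
    if (any(state$passive[cbind(a$row + 1L, a$col + 1L)] != 0L))
      stop("agent placed on a basement-membrane or ECM position")
  }
  invisible(state)
}

#' @export
print.grid_state <- function(x, ...) {
  cat(sprintf("<grid_state> %d x %d, step %d, %d agents\n", x$width,
              x$height, x$step_index, nrow(x$agents)))
  if (nrow(x$agents)) print(table(x$agents$kind))
  invisible(x)
}

#' Occupancy matrix of a grid state
#'
#' @param state a `grid_state`.
#' @return Integer matrix (`height` x `width`): row number of the occupying
#'   agent in `state$agents`, or 0 when the position holds no agent.
#' @export
occupancy_matrix <- function(state) {
  occ <- matrix(0L, state$height, state$width)
  a <- state$agents
  if (nrow(a)) occ[cbind(a$row + 1L, a$col + 1L)] <- seq_len(nrow(a))
  occ
}

#' Moore neighborhood of a lattice position
#'
#' All positions at Chebyshev distance 1..`range` from `pos`, clipped at
#' the grid borders (no wraparound), in deterministic row-major order.
#'
#' @param pos integer vector `c(row, col)`, 0-based.
#' @param range neighborhood range (1 gives the 8 surrounding spaces,
#'   2 gives 24).
#' @param dim grid dimensions `c(height, width)`.
#' @return Integer matrix with columns `row`, `col`.
#' @examples
#' nrow(neighborhood(c(5, 5), 1, c(125, 125)))  # 8
#' nrow(neighborhood(c(0, 0), 1, c(125, 125)))  # 3 (corner)
#' @export
neighborhood <- function(pos, range = 1L, dim = c(125L, 125L)) {
  cpp_neighborhood(as.integer(pos[1]), as.integer(pos[2]),
                   as.integer(range), as.integer(dim[1]),
                   as.integer(dim[2]))
}

#' Bernoulli action draw
#'
#' Samples a single action outcome with success probability `p`, consuming
#' exactly one draw from R's random number stream.
#'
#' @param p success probability in \[0, 1\].
#' @return `TRUE` with probability `p`.
#' @export
bernoulli <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("p must be a single probability in [0, 1]")
  runif(1L) < p
}

#' Choose a uniformly random empty neighboring position
#'
#' Candidate positions must be agent-free and passive-free ("empty space":
#' lumen or cleaved ECM).
#'
#' @param state a `grid_state`.
#' @param pos 0-based `c(row, col)`.
#' @param range Chebyshev range.
#' @return A 0-based `c(row, col)` vector, or `NULL` when no neighboring
#'   position is empty.
#' @export
choose_empty_neighbor <- function(state, pos, range = 1L) {
  nb <- neighborhood(pos, range, c(state$height, state$width))
  occ <- occupancy_matrix(state)
  free <- occ[cbind(nb[, 1] + 1L, nb[, 2] + 1L)] == 0L &
    state$passive[cbind(nb[, 1] + 1L, nb[, 2] + 1L)] == 0L
  nb <- nb[free, , drop = FALSE]
  if (nrow(nb) == 0L) return(NULL)
  nb[sample.int(nrow(nb), 1L), ]
}

state_to_cpp <- function(state) {
  a <- state$agents
  div <- a$divisions_left
  div[is.infinite(div)] <- -1
  list(width = state$width, height = state$height,
       step_index = state$step_index, passive = state$passive,
       agents = list(id = as.integer(a$id), kind = kind_code(a$kind),
                     row = as.integer(a$row), col = as.integer(a$col),
                     mutations = as.integer(a$mutations),
                     divisions_left = as.integer(div),
                     kills_left = as.integer(a$kills_left),
                     emt = as.logical(a$emt), age = as.integer(a$age)),
       luminal_region = state$luminal_region,
       basal_region = state$basal_region,
       region_code = state$region_code, entry = state$entry,
       detection = state$detection, next_id = state$next_id)
}

cpp_to_state <- function(out, template) {
  a <- as.data.frame(out$agents)
  a$kind <- kind_levels()[a$kind + 1L]
  a$divisions_left <- as.numeric(a$divisions_left)
  a$divisions_left[a$divisions_left < 0] <- Inf
  st <- template
  st$agents <- a
  st$passive <- out$passive
  st$detection <- out$detection
  st$next_id <- out$next_id
  st$step_index <- out$step_index
  st$bm_initial <- template$bm_initial
  st
}

decode_events <- function(ev) {
  if (is.null(ev)) return(NULL)
  ev <- as.data.frame(ev)
  ev$type <- event_levels()[ev$type]
  ev$kind <- kind_levels()[ev$kind + 1L]
  ev
}

#' Run the simulation engine for a number of steps
#'
#' Low-level driver shared by both models: applies the per-step scheduler
#' (luminal/stem/tumor round, basal round, fibroblast/CAF round, macrophage
#' influx and round, in that order; agents are visited in uniformly
#' shuffled order within a round) `n_steps` times.
#'
#' @param state a `grid_state`.
#' @param params an `abm_params` list.
#' @param n_steps number of 12-hour steps.
#' @param model `"minimal"`, `"acinus"` or `"culture"`.
#' @param record_every record a time-series row every this many steps.
#' @param record_events keep the full per-event log (memory-heavy on long
#'   runs; intended for diagnostics and tests).
#' @return An `abm_result` list: `timeseries` (data frame), `state` (final
#'   `grid_state`), `events` (data frame or `NULL`), `milestones` (named
#'   steps, `NA` when not reached), `invasion_covariates`,
#'   `extinction_step`, `model`.
#' @export
simulate_steps <- function(state, params, n_steps, model = "minimal",
                           record_every = 1L, record_events = FALSE) {
  stopifnot(n_steps >= 1)
  validate_parameters(params)
  mcode <- match(match.arg(model, c("minimal", "acinus", "culture")),
                 c("minimal", "acinus", "culture")) - 1L
  out <- cpp_simulate(state_to_cpp(state), params, as.integer(n_steps),
                      mcode, as.integer(record_every), record_events)
  ts <- as.data.frame(out$timeseries)
  ms <- out$milestones
  res <- structure(list(
    timeseries = ts,
    state = cpp_to_state(out, state),
    events = decode_events(out$events),
    milestones = ms,
    invasion_covariates = out$invasion_covariates,
    extinction_step = out$extinction_step,
    bm_initial = out$bm_initial,
    model = model,
    params = params
  ), class = "abm_result")
  res
}

#' Advance a grid state by one scheduler step
#'
#' Applies the four agent rounds once and returns both the new state and
#' the full event log of the step (one event per state change: birth,
#' death, mutation, differentiation, breakdown, migration, kill, influx,
#' EMT).
#'
#' @inheritParams simulate_steps
#' @return A list with elements `state` and `events`.
#' @export
advance_step <- function(state, params, model = "minimal") {
  res <- simulate_steps(state, params, 1L, model = model,
                        record_every = 1L, record_events = TRUE)
  list(state = res$state, events = res$events)
}

#' @export
print.abm_result <- function(x, ...) {
  last <- x$timeseries[nrow(x$timeseries), ]
  cat(sprintf("<abm_result: %s model> %d steps (%.0f days)\n", x$model,
              last$step, last$days))
  cat(sprintf("  final counts: %d tumor, %d stem, %d mutated total\n",
              last$n_tumor, last$n_stem, last$n_mutated))
  reached <- x$milestones[!is.na(x$milestones)]
  if (length(reached))
    cat("  milestones (steps): ",
        paste(names(reached), reached, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
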