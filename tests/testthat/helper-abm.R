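# shared fixtures: all fixtures are built in code at test time

# a parameter set in which nothing ever happens
zero_params <- function(...) {
  p <- default_parameters()
  for (f in c("TUpprol", "TUpmig", "TUpdeath", "TUpmut", "TUpkill",
              "TUpMdiff", "TUpMMP", "LCpprol", "LCpdeath", "BCpprol",
              "BCpdeath", "Fdiff", "Fpprol", "Fpdeath", "CFpprol",
              "CFpdeath", "CFmmp", "CFmdiff", "CFemt", "M1influxProb",
              "M1influxadd", "M1pkill", "M1pdeath", "M1pmig", "M2pkill",
              "M2emt", "SCrenew", "SCpdeath", "M2TUadd", "CFprom"))
    p[[f]] <- 0
  dots <- list(...)
  p[names(dots)] <- dots
  normalize_parameters_for_test(p)
}

normalize_parameters_for_test <- function(p) {
  validate_parameters(p)
  class(p) <- "abm_params"
  p
}

# build a bare grid state from an agent spec list
make_state <- function(agents, width = 25L, height = 25L, passive = NULL,
                       ...) {
  df <- do.call(rbind, lapply(seq_along(agents), function(i) {
    a <- agents[[i]]
    data.frame(id = i, kind = a$kind, row = a$row, col = a$col,
               mutations = a$mutations %||% 0L,
               divisions_left = a$divisions_left %||%
                 (if (a$kind == "stem") Inf else 5),
               kills_left = a$kills_left %||% 0L,
               emt = isTRUE(a$emt), age = 0L, stringsAsFactors = FALSE)
  }))
  if (is.null(df)) df <- prostasim:::empty_agents()
  new_grid_state(width = width, height = height, agents = df,
                 passive = passive, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cell <- function(kind, row, col, ...) {
  c(list(kind = kind, row = row, col = col), list(...))
}

# exact event-log bookkeeping: per step and kind,
# count(t) - count(t-1) = births + influx + diff_in - deaths - diff_out
check_conservation <- function(result) {
  ts <- result$timeseries
  ev <- result$events
  kinds <- kind_levels()
  cols <- paste0("n_", c("luminal", "basal", "stem", "tumor", "fibroblast",
                         "caf", "m1", "m2"))
  for (i in 2:nrow(ts)) {
    step <- ts$step[i]
    e <- ev[ev$step == step, ]
    for (k in seq_along(kinds)) {
      kn <- kinds[k]
      births <- sum(e$type == "birth" & e$kind == kn)
      influx <- sum(e$type == "influx" & e$kind == kn)
      deaths <- sum(e$type == "death" & e$kind == kn)
      diff_in <- sum(e$type == "differentiation" & e$kind == kn)
      diff_out <- sum(e$type == "differentiation" &
                        kinds[e$detail + 1L] == kn)
      delta <- ts[[cols[k]]][i] - ts[[cols[k]]][i - 1]
      expect_identical(as.integer(delta),
                       as.integer(births + influx + diff_in - deaths -
                                    diff_out),
                       label = sprintf("conservation of %s at step %d", kn,
                                       step))
    }
  }
  invisible(TRUE)
}

# occupancy invariants of a grid state
check_occupancy <- function(state) {
  a <- state$agents
  if (nrow(a) == 0) return(invisible(TRUE))
  pos <- a$row * state$width + a$col
  expect_false(anyDuplicated(pos) > 0, label = "one agent per position")
  expect_true(all(a$row >= 0 & a$row < state$height &
                    a$col >= 0 & a$col < state$width))
  expect_true(all(state$passive[cbind(a$row + 1L, a$col + 1L)] == 0L),
              label = "no agent on a passive position")
  invisible(TRUE)
}
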