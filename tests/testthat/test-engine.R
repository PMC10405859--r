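test_that("Moore neighborhood matches the canonical sizes and clips at borders", {
  expect_equal(nrow(neighborhood(c(60, 60), 1)), 8)
  expect_equal(nrow(neighborhood(c(60, 60), 2)), 24)
  expect_equal(nrow(neighborhood(c(0, 0), 1)), 3)
  expect_equal(nrow(neighborhood(c(0, 0), 2)), 8)
  expect_error(neighborhood(c(-1, 5), 1), "outside")
  expect_error(neighborhood(c(200, 5), 1, c(125, 125)), "outside")
})

test_that("neighborhood agrees with a brute-force double loop", {
  set.seed(42)
  for (i in 1:25) {
    h <- sample(3:40, 1)
    w <- sample(3:40, 1)
    pos <- c(sample(0:(h - 1), 1), sample(0:(w - 1), 1))
    rg <- sample(1:3, 1)
    nb <- neighborhood(pos, rg, c(h, w))
    brute <- NULL
    for (r in 0:(h - 1)) for (c_ in 0:(w - 1)) {
      d <- max(abs(r - pos[1]), abs(c_ - pos[2]))
      if (d >= 1 && d <= rg) brute <- rbind(brute, c(r, c_))
    }
    expect_equal(nrow(nb), nrow(brute))
    expect_true(all(nb[order(nb[, 1], nb[, 2]), ] ==
                      brute[order(brute[, 1], brute[, 2]), ]))
    # row-major enumeration order is deterministic
    expect_true(!is.unsorted(nb[, 1]))
  }
})

test_that("bernoulli respects degenerate probabilities and its sampling law", {
  set.seed(1)
  expect_false(any(vapply(1:50, function(i) bernoulli(0), logical(1))))
  expect_true(all(vapply(1:50, function(i) bernoulli(1), logical(1))))
  expect_error(bernoulli(1.2), "probability")
  expect_error(bernoulli(-0.1), "probability")
  n <- 10000
  hits <- sum(vapply(1:n, function(i) bernoulli(0.3), logical(1)))
  sigma <- sqrt(n * 0.3 * 0.7)
  expect_lt(abs(hits - n * 0.3), 3 * sigma)
})

test_that("choose_empty_neighbor samples uniformly among empty positions", {
  # fully surrounded -> no move available
  ring <- lapply(seq_len(8), function(i) {
    off <- neighborhood(c(5, 5), 1, c(25, 25))[i, ]
    cell("tumor", off[1], off[2])
  })
  st <- make_state(c(list(cell("tumor", 5, 5)), ring))
  expect_null(choose_empty_neighbor(st, c(5, 5)))

  # exactly one empty neighbor -> chosen with probability 1
  st7 <- make_state(c(list(cell("tumor", 5, 5)), ring[-1]))
  free <- neighborhood(c(5, 5), 1, c(25, 25))[1, ]
  for (i in 1:10)
    expect_equal(unname(choose_empty_neighbor(st7, c(5, 5))), unname(free))

  # passive layers block: ECM is not empty space
  pas <- matrix(0L, 25, 25)
  pas[cbind(free[1] + 1L, free[2] + 1L)] <- 2L
  st_blocked <- make_state(c(list(cell("tumor", 5, 5)), ring[-1]),
                           passive = pas)
  expect_null(choose_empty_neighbor(st_blocked, c(5, 5)))

  # 4 empty neighbors -> each chosen about a quarter of the time
  st4 <- make_state(c(list(cell("tumor", 5, 5)), ring[1:4]))
  set.seed(7)
  n <- 20000
  draws <- t(vapply(1:n, function(i) choose_empty_neighbor(st4, c(5, 5)),
                    numeric(2)))
  tab <- table(paste(draws[, 1], draws[, 2]))
  expect_equal(length(tab), 4)
  sigma <- sqrt(n * 0.25 * 0.75)
  expect_true(all(abs(tab - n / 4) < 3 * sigma))
})

test_that("a step with all probabilities zero changes nothing but the clock", {
  st <- make_state(list(cell("tumor", 3, 3), cell("stem", 10, 10),
                        cell("tumor", 20, 4)))
  set.seed(1)
  out <- advance_step(st, zero_params(), model = "minimal")
  expect_equal(out$state$step_index, 1L)
  expect_equal(nrow(out$events), 0)
  expect_equal(out$state$agents[names(out$state$agents) != "age"],
               st$agents[names(st$agents) != "age"])
})

test_that("a forced division yields exactly two tumor cells sharing the lineage budget", {
  st <- make_state(list(cell("tumor", 5, 5, divisions_left = 5)))
  set.seed(1)
  out <- advance_step(st, zero_params(TUpprol = 1), model = "minimal")
  a <- out$state$agents
  expect_equal(nrow(a), 2)
  expect_true(all(a$kind == "tumor"))
  # decrement-inheritance: both cells carry the decremented budget
  expect_equal(sort(a$divisions_left), c(4, 4))
  expect_equal(sum(out$events$type == "birth"), 1)
})

test_that("sparse low-rate growth matches the branching-process mean", {
  # independent oracle: with death probability d sampled before division
  # probability p, the per-step multiplier is exactly (1 - d) * (1 + p)
  p <- 0.03
  d <- 0.01
  k <- 10
  n0 <- 300
  expected <- n0 * ((1 - d) * (1 + p))^k
  reps <- 200
  finals <- numeric(reps)
  params <- zero_params(TUpprol = p, TUpdeath = d, TUpmax = 30)
  for (r in seq_len(reps)) {
    set.seed(1000 + r)
    pos <- sample.int(125 * 125, n0) - 1L
    agents <- data.frame(id = seq_len(n0), kind = "tumor",
                         row = pos %/% 125L, col = pos %% 125L,
                         mutations = 0L, divisions_left = 30,
                         kills_left = 0L, emt = FALSE, age = 0L,
                         stringsAsFactors = FALSE)
    st <- new_grid_state(width = 125L, height = 125L, agents = agents)
    res <- simulate_steps(st, params, k, model = "minimal",
                          record_every = k)
    finals[r] <- res$timeseries$n_tumor[nrow(res$timeseries)]
  }
  se <- sd(finals) / sqrt(reps)
  expect_lt(abs(mean(finals) - expected), 3 * se + 1e-9)
})

test_that("identical configuration and seed give bit-identical event logs", {
  cfg <- minimal_config("combined", n_seed = 400, n_steps = 40,
                        record_events = TRUE)
  r1 <- run_minimal(cfg, seed = 99)
  r2 <- run_minimal(cfg, seed = 99)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$timeseries, r2$timeseries)
  r3 <- run_minimal(cfg, seed = 100)
  expect_false(identical(r1$events, r3$events))
})

test_that("occupancy invariant and event-log conservation hold under random stress", {
  set.seed(5)
  for (trial in 1:3) {
    n0 <- 300
    p <- default_parameters(TUpprol = runif(1, 0.2, 0.6),
                            TUpdeath = runif(1, 0.02, 0.1),
                            TUpmut = 0.02, SCrenew = 0.3, SCpdeath = 0.02)
    pos <- sample.int(60 * 60, n0) - 1L
    kind <- sample(c("tumor", "stem"), n0, replace = TRUE, prob = c(.9, .1))
    agents <- data.frame(id = seq_len(n0), kind = kind, row = pos %/% 60L,
                         col = pos %% 60L, mutations = 0L,
                         divisions_left = ifelse(kind == "stem", Inf, 5),
                         kills_left = 0L, emt = FALSE, age = 0L,
                         stringsAsFactors = FALSE)
    st <- new_grid_state(width = 60L, height = 60L, agents = agents)
    res <- simulate_steps(st, p, 30, model = "minimal", record_every = 1,
                          record_events = TRUE)
    check_occupancy(res$state)
    check_conservation(res)
  }
})

test_that("unknown agent kinds and malformed states are rejected", {
  bad <- make_state(list(cell("tumor", 1, 1)))
  bad$agents$kind <- "granulocyte"
  expect_error(simulate_steps(bad, default_parameters(), 1), "kind")
  expect_error(make_state(list(cell("tumor", 1, 1), cell("stem", 1, 1))),
               "share")
})
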