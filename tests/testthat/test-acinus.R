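# an all-ECM ring-code matrix lets small custom states run under the
# acinus scheduler without the full starting geometry
ecm_code <- function(h, w) matrix(5L, h, w)

test_that("the rasterized acinus has disjoint concentric rings around a disk lumen", {
  geo <- acinus_geometry()
  code <- acinus_region_code(geo)
  expect_equal(dim(code), c(125, 125))
  # brute-force Euclidean disk oracle for the lumen
  d2 <- outer(0:124, 0:124, function(r, c_) (r - 62)^2 + (c_ - 62)^2)
  expect_equal(sum(code == 0L), sum(d2 < 13^2))
  # rings are one-space Chebyshev dilations: every ring position touches
  # the previous ring, and rings are disjoint by construction of the codes
  for (ring in 1:4) {
    pos <- which(code == ring, arr.ind = TRUE)
    expect_gt(nrow(pos), 0)
    touches <- vapply(seq_len(nrow(pos)), function(i) {
      nb <- neighborhood(pos[i, ] - 1L, 1, c(125, 125))
      any(code[cbind(nb[, 1] + 1L, nb[, 2] + 1L)] == ring - 1L)
    }, logical(1))
    expect_true(all(touches))
  }
  expect_error(acinus_region_code(acinus_geometry(width = 30, height = 30,
                                                  lumen_radius = 12)),
               "exceed|too")
})

test_that("the healthy starting state contains no tumor, CAF or macrophage", {
  set.seed(10)
  st <- build_acinus()
  a <- st$agents
  expect_equal(sum(a$kind %in% c("tumor", "caf", "m1", "m2")), 0)
  expect_true(all(a$mutations == 0))
  # closed luminal and basal rings
  code <- st$region_code
  occ <- occupancy_matrix(st)
  lum_ring <- which(code == 1L)
  expect_true(all(occ[lum_ring] > 0))
  expect_true(all(a$kind[occ[lum_ring]] %in% c("luminal", "stem")))
  bas_ring <- which(code == 2L)
  expect_true(all(a$kind[occ[bas_ring]] == "basal"))
  # every basal cell touches the basement membrane
  bas <- a[a$kind == "basal", ]
  touch <- vapply(seq_len(nrow(bas)), function(i) {
    nb <- neighborhood(c(bas$row[i], bas$col[i]), 1, c(125, 125))
    any(st$passive[cbind(nb[, 1] + 1L, nb[, 2] + 1L)] == 1L)
  }, logical(1))
  expect_true(all(touch))
  # lumen is empty space
  expect_true(all(occ[code == 0L] == 0 & st$passive[code == 0L] == 0L))
})

test_that("an acinus with all action probabilities zero is frozen for 800 steps", {
  set.seed(2)
  st <- build_acinus()
  res <- simulate_steps(st, zero_params(), 800, model = "acinus",
                        record_every = 100)
  ts <- res$timeseries
  expect_true(all(ts$n_luminal == ts$n_luminal[1]))
  expect_true(all(ts$n_basal == ts$n_basal[1]))
  expect_true(all(ts$bm_count == ts$bm_count[1]))
  expect_equal(nrow(res$state$agents), nrow(st$agents))
})

test_that("without the initiating mutation no tumor, CAF or M2 ever appears", {
  set.seed(3)
  cfg <- acinus_config(params = default_parameters(TUpmut = 0),
                       n_steps = 200, record_every = 1)
  r <- run_acinus(cfg, seed = 3)
  ts <- r$timeseries
  expect_true(all(ts$n_tumor == 0))
  expect_true(all(ts$n_caf == 0))
  expect_true(all(ts$n_m2 == 0))
  expect_true(is.na(r$milestones[["first_mutation"]]))
})

test_that("basement-membrane attack is gated by the mutation threshold", {
  h <- 15L
  pas <- matrix(0L, h, h)
  pas[8, 9] <- 1L  # one BM position next to the tumor cell
  base <- zero_params(TUpkill = 1)
  below <- make_state(list(cell("tumor", 7, 7,
                                mutations = base$TUthrshBM - 1L)),
                      width = h, height = h, passive = pas,
                      region_code = ecm_code(h, h))
  set.seed(1)
  out <- advance_step(below, base, model = "acinus")
  expect_equal(sum(out$state$passive == 1L), 1L)  # gate holds, BM intact

  above <- make_state(list(cell("tumor", 7, 7,
                                mutations = base$TUthrshBM)),
                      width = h, height = h, passive = pas,
                      region_code = ecm_code(h, h))
  set.seed(1)
  out2 <- advance_step(above, base, model = "acinus")
  expect_equal(sum(out2$state$passive == 1L), 0L)  # forced breakdown
  expect_true(any(out2$events$type == "breakdown"))
})

test_that("tumor cells migrate only after EMT", {
  p <- zero_params(TUpmig = 1)
  st <- make_state(list(cell("tumor", 7, 7, mutations = 1)),
                   region_code = ecm_code(25, 25))
  set.seed(1)
  out <- advance_step(st, p, model = "acinus")
  expect_equal(c(out$state$agents$row, out$state$agents$col), c(7, 7))
  expect_false(any(out$events$type == "migration"))

  st_emt <- make_state(list(cell("tumor", 7, 7, mutations = 1, emt = TRUE)),
                       region_code = ecm_code(25, 25))
  set.seed(1)
  out2 <- advance_step(st_emt, p, model = "acinus")
  expect_true(any(out2$events$type == "migration"))
  expect_false(all(c(out2$state$agents$row, out2$state$agents$col) ==
                     c(7, 7)))
})

test_that("basal cells die when detached from the basement membrane", {
  h <- 15L
  pas <- matrix(0L, h, h)
  pas[3, 3] <- 1L                   # BM at 0-based (2, 2)
  attached <- cell("basal", 3, 3)   # Chebyshev distance 1 from the BM
  detached <- cell("basal", 10, 10)
  st <- make_state(list(attached, detached), width = h, height = h,
                   passive = pas, region_code = ecm_code(h, h))
  set.seed(1)
  out <- advance_step(st, zero_params(), model = "acinus")
  a <- out$state$agents
  expect_equal(nrow(a), 1)
  expect_equal(c(a$row, a$col), c(3, 3))
  dth <- out$events[out$events$type == "death", ]
  expect_equal(nrow(dth), 1)
})

test_that("basal proliferation is confined to the basal physiologic region", {
  h <- 15L
  pas <- matrix(0L, h, h)
  pas[8, 7] <- 1L  # BM at 0-based (7, 6): keeps the basal cell attached
  bas_region <- matrix(FALSE, h, h)
  bas_region[9, 9] <- TRUE  # 0-based (8, 8): the only legal target
  st <- make_state(list(cell("basal", 7, 7)), width = h, height = h,
                   passive = pas, region_code = ecm_code(h, h),
                   basal_region = bas_region)
  set.seed(1)
  out <- advance_step(st, zero_params(BCpprol = 1), model = "acinus")
  a <- out$state$agents
  expect_equal(nrow(a), 2)
  expect_true(any(a$row == 7 & a$col == 7))
  expect_true(any(a$row == 8 & a$col == 8))

  # no legal target at all -> no proliferation
  st2 <- make_state(list(cell("basal", 7, 7)), width = h, height = h,
                    passive = pas, region_code = ecm_code(h, h),
                    basal_region = matrix(FALSE, h, h))
  set.seed(1)
  out2 <- advance_step(st2, zero_params(BCpprol = 1), model = "acinus")
  expect_equal(nrow(out2$state$agents), 1)
})

test_that("fibroblast-to-CAF conversion requires tumor within two grid spaces", {
  h <- 21L
  # distance 3: never converts even at Fdiff = 1
  far <- make_state(list(cell("tumor", 10, 10, mutations = 1),
                         cell("fibroblast", 10, 13, divisions_left = Inf)),
                    width = h, height = h, region_code = ecm_code(h, h))
  p <- zero_params(Fdiff = 1)
  set.seed(1)
  st <- far
  for (i in 1:10) st <- advance_step(st, p, model = "acinus")$state
  expect_equal(sum(st$agents$kind == "caf"), 0)

  # distance 2 across an intervening basement membrane: converts
  pas <- matrix(0L, h, h)
  pas[11, 12] <- 1L  # BM at 0-based (10, 11), between tumor and fibroblast
  near <- make_state(list(cell("tumor", 10, 10, mutations = 1),
                          cell("fibroblast", 10, 12,
                               divisions_left = Inf)),
                     width = h, height = h, passive = pas,
                     region_code = ecm_code(h, h))
  set.seed(1)
  out <- advance_step(near, p, model = "acinus")
  expect_equal(sum(out$state$agents$kind == "caf"), 1)
  caf <- out$state$agents[out$state$agents$kind == "caf", ]
  expect_equal(caf$divisions_left, p$Fpmax)
})

test_that("CAF conversions follow the binomial law", {
  h <- 121L
  cells <- list()
  rows <- seq(0, 118, by = 3)
  cols <- seq(0, 115, by = 5)
  for (r in rows) for (c_ in cols) {
    cells[[length(cells) + 1L]] <- cell("tumor", r, c_, mutations = 1)
    cells[[length(cells) + 1L]] <- cell("fibroblast", r, c_ + 2,
                                        divisions_left = Inf)
  }
  n <- length(rows) * length(cols)
  st <- make_state(cells, width = h, height = h,
                   region_code = ecm_code(h, h))
  set.seed(12)
  out <- advance_step(st, zero_params(Fdiff = 0.3), model = "acinus")
  converted <- sum(out$state$agents$kind == "caf")
  sigma <- sqrt(n * 0.3 * 0.7)
  expect_lt(abs(converted - 0.3 * n), 3 * sigma)
})

test_that("macrophages chemotax toward the nearest sensed tumor cell", {
  h <- 41L
  p <- zero_params(M1pmig = 1)
  for (trial in 1:25) {
    set.seed(300 + trial)
    st <- make_state(list(cell("tumor", 20, 30, mutations = 1),
                          cell("m1", 20, 20, kills_left = 4,
                               divisions_left = Inf)),
                     width = h, height = h, region_code = ecm_code(h, h))
    out <- advance_step(st, p, model = "acinus")
    m <- out$state$agents[out$state$agents$kind == "m1", ]
    d_pre <- 10
    d_post <- max(abs(m$row - 20), abs(m$col - 30))
    # an improving free position always exists here
    expect_lte(d_post, d_pre - 1)
    expect_gte(d_post, d_pre - 2)
  }
  # out of sensing range: the move is unbiased, so over many trials the
  # macrophage must sometimes move away from the remote tumor cell
  p2 <- zero_params(M1pmig = 1)
  p2$sensing_radius <- 5L
  moved_away <- 0
  for (trial in 1:40) {
    set.seed(600 + trial)
    st <- make_state(list(cell("tumor", 20, 39, mutations = 1),
                          cell("m1", 20, 10, kills_left = 4,
                               divisions_left = Inf)),
                     width = h, height = h, region_code = ecm_code(h, h))
    out <- advance_step(st, p2, model = "acinus")
    m <- out$state$agents[out$state$agents$kind == "m1", ]
    if (max(abs(m$row - 20), abs(m$col - 39)) > 29) moved_away <- moved_away + 1
  }
  expect_gt(moved_away, 0)
})

test_that("macrophage kills are capped and exhaustion kills the killer", {
  h <- 15L
  st <- make_state(list(cell("tumor", 7, 8, mutations = 1),
                        cell("tumor", 7, 6, mutations = 1),
                        cell("m1", 7, 7, kills_left = 1,
                             divisions_left = Inf)),
                   width = h, height = h, region_code = ecm_code(h, h))
  p <- zero_params(M1pkill = 1)
  set.seed(1)
  out <- advance_step(st, p, model = "acinus")
  a <- out$state$agents
  expect_equal(sum(a$kind == "tumor"), 1)  # one kill, cap reached
  expect_equal(a$kills_left[a$kind == "m1"], 0)
  out2 <- advance_step(out$state, p, model = "acinus")
  expect_equal(sum(out2$state$agents$kind == "m1"), 0)  # exhausted
  expect_equal(sum(out2$state$agents$kind == "tumor"), 1)
})

test_that("influx is skipped while all entry positions are occupied", {
  h <- 15L
  blockers <- list(cell("fibroblast", 0, 0, divisions_left = Inf),
                   cell("fibroblast", 0, 1, divisions_left = Inf),
                   cell("fibroblast", 1, 0, divisions_left = Inf),
                   cell("fibroblast", 1, 1, divisions_left = Inf))
  entry <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  p <- zero_params(M1influxProb = 1)
  st <- make_state(blockers, width = h, height = h,
                   region_code = ecm_code(h, h), entry = entry)
  set.seed(1)
  out <- advance_step(st, p, model = "acinus")
  expect_equal(sum(out$state$agents$kind == "m1"), 0)

  st2 <- make_state(blockers[1:3], width = h, height = h,
                    region_code = ecm_code(h, h), entry = entry)
  set.seed(1)
  out2 <- advance_step(st2, p, model = "acinus")
  a <- out2$state$agents
  expect_equal(sum(a$kind == "m1"), 1)
  expect_equal(a$kills_left[a$kind == "m1"], p$M1kmax)
  expect_true(any(out2$events$type == "influx"))
})

test_that("full runs keep the basement membrane monotone and order milestones", {
  for (seed in c(1, 3, 6)) {
    r <- run_acinus(acinus_config(record_every = 1), seed = seed)
    bm <- r$timeseries$bm_count
    expect_true(all(diff(bm) <= 0))
    ms <- r$milestones
    if (!is.na(ms[["first_invasion"]])) {
      # no mutated cell leaves the acinus before the membrane is breached
      expect_true(!is.na(ms[["bm_breakdown"]]))
      expect_gte(ms[["first_invasion"]], ms[["bm_breakdown"]])
    }
    if (r$developed_cancer) {
      expect_gte(r$tumor_load_400d, 0)
    }
    # M2:M1 ratio is undefined (NA) while no macrophage has entered
    expect_true(is.na(r$timeseries$m2_m1_ratio[1]))
  }
})

test_that("kill events per macrophage never exceed the kill cap", {
  cfg <- acinus_config(params = default_parameters(TUpmut = 5e-3),
                       n_steps = 500, record_events = TRUE)
  r <- run_acinus(cfg, seed = 11)
  ev <- r$events
  kills <- ev[ev$type == "kill", ]
  if (nrow(kills)) {
    per_mac <- table(kills$id)
    expect_true(all(per_mac <= default_parameters()$M1kmax))
  }
  # conversions are irreversible: no m2 -> m1 or caf -> fibroblast event
  diffs <- ev[ev$type == "differentiation", ]
  expect_false(any(diffs$kind == "m1" | diffs$kind == "fibroblast"))
})
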