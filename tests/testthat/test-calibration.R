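test_that("cocultures are seeded at the 4:1:1 ratio", {
  s <- prostasim:::culture_seeding("tumor_fib_m1", 600)
  expect_equal(unname(s), c(400, 100, 100))
  expect_equal(names(s), c("tumor", "fibroblast", "m1"))
  s2 <- prostasim:::culture_seeding("tumor_fib_m2", 600)
  expect_equal(names(s2)[3], "m2")
  expect_equal(unname(prostasim:::culture_seeding("tumor_mono", 500)), 500)
})

test_that("synthetic curves honor the noise model and replicate design", {
  # noiseless replicates of one condition are identical
  cv <- generate_synthetic_curves(noise_sd = 0,
                                  conditions = c("tumor_mono", "apoptosis"),
                                  seed = 2, n_total = 200,
                                  dim = c(40L, 40L), n_steps = 6)
  tm <- cv[cv$condition == "tumor_mono", ]
  expect_equal(length(unique(tm$replicate)), 3)  # growth in triplicate
  ap <- cv[cv$condition == "apoptosis", ]
  expect_equal(length(unique(ap$replicate)), 2)  # apoptosis in duplicate
  for (r in 2:3)
    expect_equal(tm$signal[tm$replicate == r],
                 tm$signal[tm$replicate == 1])
  # apoptosis readout is cumulative, hence non-decreasing
  expect_true(all(diff(ap$signal[ap$replicate == 1]) >= 0))

  # without proliferation the growth curve cannot increase
  p0 <- default_parameters(TUpprol = 0)
  cv0 <- generate_synthetic_curves(p0, noise_sd = 0,
                                   conditions = "tumor_mono", seed = 3,
                                   n_total = 200, dim = c(40L, 40L),
                                   n_steps = 6)
  expect_true(all(diff(cv0$signal[cv0$replicate == 1]) <= 0))
})

test_that("multiplicative noise is unbiased around the clean curve", {
  set.seed(4)
  clean <- simulate_culture("tumor_mono", n_total = 200, dim = c(40L, 40L),
                            n_steps = 6)
  reps <- 100
  sims <- replicate(reps, {
    x <- clean$signal * (1 + rnorm(nrow(clean), 0, 0.05))
    mean(x / clean$signal)
  })
  se <- sd(sims) / sqrt(reps)
  expect_lt(abs(mean(sims) - 1), 3 * se + 1e-6)
})

test_that("particle swarm optimization solves convex test problems", {
  f1 <- function(x) (x - 0.37)^2
  fit1 <- pso_fit(f1, lower = 0, upper = 1,
                  config = pso_config(swarm_size = 10, iterations = 30,
                                      restarts = 3, seed = 1))
  expect_lt(abs(fit1$par - 0.37), 1e-3)

  sphere <- function(x) sum(x^2)
  fit3 <- pso_fit(sphere, lower = rep(-2, 3), upper = rep(2, 3),
                  config = pso_config(swarm_size = 20, iterations = 60,
                                      restarts = 2, seed = 2))
  expect_lt(sqrt(sum(fit3$par^2)), 1e-2)

  # integer dimensions are rounded in the reported optimum
  fint <- function(x) (x[1] - 0.5)^2 + (round(x[2]) - 4)^2
  fit2 <- pso_fit(fint, lower = c(0, 1), upper = c(1, 9),
                  integer = c(FALSE, TRUE),
                  config = pso_config(swarm_size = 12, iterations = 30,
                                      restarts = 2, seed = 3))
  expect_equal(fit2$par[2], 4)

  # same seed, same trajectories
  fa <- pso_fit(sphere, lower = rep(-1, 2), upper = rep(1, 2),
                config = pso_config(swarm_size = 8, iterations = 10,
                                    restarts = 2, seed = 9))
  fb <- pso_fit(sphere, lower = rep(-1, 2), upper = rep(1, 2),
                config = pso_config(swarm_size = 8, iterations = 10,
                                    restarts = 2, seed = 9))
  expect_identical(fa$restarts, fb$restarts)
})

test_that("the staged calibration enforces its preconditions and identities", {
  cv <- generate_synthetic_curves(noise_sd = 0, seed = 5, n_total = 200,
                                  dim = c(40L, 40L), n_steps = 6)
  # a missing condition is reported by name at its stage
  expect_error(
    sequential_calibration(cv[cv$condition != "fibroblast_mono", ],
                           pso = pso_config(swarm_size = 4,
                                            iterations = 2, restarts = 1,
                                            seed = 1),
                           n_sim = 1, n_total = 200, dim = c(40L, 40L)),
    "fibroblast_mono")
  expect_error(sequential_calibration(data.frame(x = 1)), "columns")

  fitted <- sequential_calibration(
    cv, pso = pso_config(swarm_size = 5, iterations = 4, restarts = 2,
                         seed = 2),
    n_sim = 1, n_total = 200, dim = c(40L, 40L))
  # the M2 kill cap is assumed equivalent to the fitted M1 cap
  expect_identical(fitted$M2kmax, fitted$M1kmax)
  prov <- attr(fitted, "provenance")
  expect_equal(unname(prov["M2kmax"]), "assumed:M1kmax")
  expect_match(unname(prov["TUpprol"]), "tumor_mono")
  # fitted probabilities respect their bounds
  expect_true(fitted$TUpprol >= 0.05 && fitted$TUpprol <= 0.8)
  expect_true(fitted$M1kmax >= 1 && fitted$M1kmax <= 12)
  # untouched fields keep their base values
  expect_identical(fitted$TUpmut, default_parameters()$TUpmut)
})
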