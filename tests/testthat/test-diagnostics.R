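test_that("spin overlap arithmetic", {
  expect_equal(spin_overlap(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(spin_overlap(c(1, 0, 1), c(0, 1, 0)), -1)
  expect_equal(spin_overlap(c(1, 1, 1, 1), c(1, 1, 1, 0)), 0.5)
  expect_equal(spin_overlap(c(-1, 1), c(1, 1)), 0)
  expect_error(spin_overlap(c(1, 0), c(1, 0, 1)), "different variables")
  expect_error(spin_overlap(c(2, 0), c(1, 0)), "0/1")
})

test_that("SOD estimation: normalization, range, discreteness", {
  enc <- encode_coordinate("HPPH", lattice_spec("cartesian", 2),
                           penalties = default_penalties("HPPH", hp_interaction(),
                                                         "worst_case"))
  cfg <- pt_config(n_replicas = 8, t_min = 0.05, t_max = 3, sweeps = 3000,
                   thermalization = 2000)
  d <- estimate_sod(enc, cfg, seeds = c(5, 6))
  expect_equal(sum(d$masses), 1)
  expect_true(all(d$q >= -1 & d$q <= 1))
  expect_equal(d$n_olap, 1000L)
  # one-hot block structure: q only takes the discrete grid values
  # (n - 2m)/n, and far fewer distinct values than samples
  grid <- (16 - 2 * (0:16)) / 16
  expect_true(all(vapply(d$q, function(x) any(abs(x - grid) < 1e-9), logical(1))))
  expect_lt(length(unique(round(d$q, 9))), d$n_olap / 10)
  expect_error(estimate_sod(enc, cfg, seeds = c(1, 1)), "distinct")
})

test_that("zero-field models give a symmetric overlap distribution", {
  n <- 10
  im <- ising_model(paste0("s", 1:n), h = rep(0, n),
                    ji = 1:(n - 1), jj = 2:n, jv = rep(-1, n - 1))
  d <- estimate_sod(ising_to_qubo(im),
                    pt_config(n_replicas = 8, t_min = 0.2, t_max = 5,
                              sweeps = 4000, thermalization = 1000),
                    seeds = c(1, 2))
  expect_lt(abs(mean(d$q)), 0.25)  # P(q) = P(-q) within sampling error
})

test_that("barrier classification follows the |q| > 0.5 rule", {
  m <- numeric(100)
  m[100] <- 1  # all mass at q = 1
  expect_equal(classify_barriers(fake_sod(m)), "thin")
  m0 <- numeric(100); m0[50] <- 1  # single peak at q ~ 0
  expect_equal(classify_barriers(fake_sod(m0)), "thick")
  m2 <- numeric(100); m2[5] <- 0.5; m2[96] <- 0.5  # peaks at -0.9 and 0.9
  expect_equal(classify_barriers(fake_sod(m2)), "thin")
  # sub-prominence wiggles near 0 do not flip the classification
  m3 <- numeric(100); m3[98] <- 1; m3[50] <- 0.02
  expect_equal(classify_barriers(fake_sod(m3)), "thin")
  expect_error(classify_barriers(fake_sod(numeric(100))), "empty")
})

test_that("TTS closed form, limits and monotonicity", {
  expect_equal(time_to_solution(10, 0.99), 10)
  expect_equal(time_to_solution(10, 0.5), 10 * log(0.01) / log(0.5))
  expect_equal(time_to_solution(5, 0), Inf)
  expect_error(time_to_solution(-1, 0.5), "tau")
  expect_error(time_to_solution(1, 1.5), "p_ground")
  p <- seq(0.01, 0.99, by = 0.01)
  tts <- time_to_solution(1, p)
  expect_true(all(diff(tts) <= 1e-12))  # non-increasing in p_ground
  expect_gte(time_to_solution(1, 0.5), 1)
})

test_that("TTS optimisation over a schedule grid", {
  m1 <- quadratic_model("v1", linear = -1)
  grid <- list(anneal_schedule(t0 = 1, sweeps = 10),
               anneal_schedule(t0 = 1, sweeps = 50))
  tr <- optimize_tts(m1, -1, grid, n_repeats = 10, seed = 1)
  expect_equal(tr$table$p_ground, c(1, 1))  # trivial model: every run succeeds
  expect_equal(tr$best, 1L)                 # cheapest schedule wins
  expect_equal(tr$table$tts[1], 10 * 1)
  # reported p_ground matches a direct recount of the sample set
  qm <- random_qubo(8, seed = 77)
  ex <- exact_solve(qm)
  sch <- anneal_schedule(zeta = 0.98, sweeps = 100)
  tr2 <- optimize_tts(qm, ex$energy, list(sch), n_repeats = 25, seed = 9)
  ss <- simulated_annealing(qm, sch, 25, seed = 9)
  expect_equal(tr2$table$p_ground, mean(ss$energies <= ex$energy + 1e-9))
  expect_error(optimize_tts(qm, 0, list()), "empty")
})

test_that("QUBO resource metrics", {
  diag_only <- quadratic_model(paste0("v", 1:4), linear = c(1, -1, 2, 0))
  m <- qubo_metrics(diag_only)
  expect_equal(m$density, 0)
  expect_equal(m$couplers_per_qubit, 0)
  expect_equal(m$resolution, 1)

  qi <- c(1L, 1L, 1L, 2L, 2L, 3L); qj <- c(2L, 3L, 4L, 3L, 4L, 4L)
  full <- quadratic_model(paste0("v", 1:4), qi = qi, qj = qj, qv = rep(1, 6))
  expect_equal(qubo_metrics(full)$density, 1)
  expect_equal(qubo_metrics(full)$couplers_per_qubit, 3)

  mix <- quadratic_model(paste0("v", 1:3), qi = c(1L, 1L, 2L), qj = c(2L, 3L, 3L),
                         qv = c(1, -4, 0.5))
  expect_equal(qubo_metrics(mix)$resolution, 8)
})
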