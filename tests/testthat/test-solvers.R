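test_that("Metropolis rule: always downhill, Boltzmann uphill", {
  expect_true(metropolis_accept(-1, 0.5))
  expect_error(metropolis_accept(1, 0), "temperature")
  set.seed(8)
  # acceptance frequency at dE = T approaches exp(-1)
  acc <- mean(replicate(4000, metropolis_accept(1, 1)))
  expect_lt(abs(acc - exp(-1)), 0.03)
  expect_equal(mean(metropolis_accept(rep(1e6, 100), 1)), 0)
})

test_that("auto start temperature is deterministic and sane", {
  qm <- random_qubo(12, seed = 9)
  t1 <- auto_start_temperature(qm, seed = 3)
  t2 <- auto_start_temperature(qm, seed = 3)
  expect_identical(t1, t2)
  expect_gt(t1, 0)
  # degenerate flat model falls back to T0 = 1
  flat <- quadratic_model(paste0("v", 1:4))
  expect_equal(auto_start_temperature(flat, seed = 1), 1)
  expect_error(auto_start_temperature(qm, n_probe = 10), "n_probe")
})

test_that("greedy coloring is proper and deterministic", {
  expect_equal(greedy_coloring(list(integer(), integer(), integer())),
               c(1L, 1L, 1L))
  k4 <- lapply(1:4, function(i) setdiff(1:4, i))
  expect_setequal(greedy_coloring(k4), 1:4)
  set.seed(10)
  for (k in 1:5) {
    n <- 12
    adj <- lapply(1:n, function(i) integer())
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < 0.3) { adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i) }
    }
    col <- greedy_coloring(adj)
    for (i in 1:n) expect_true(all(col[adj[[i]]] != col[i]))
  }
})

test_that("SA solves trivial and random instances to optimality", {
  # single-variable model with a negative linear term
  m1 <- quadratic_model("v1", linear = -1)
  ss <- simulated_annealing(m1, anneal_schedule(t0 = 1, sweeps = 10), 3, seed = 1)
  expect_equal(ss$best_energy, -1)
  expect_equal(unname(ss$best_assignment), 1L)

  # random 12-var QUBOs: SA with a slow schedule matches the exact minimum
  for (seed in c(31, 32)) {
    qm <- random_qubo(12, seed)
    ex <- exact_solve(qm)
    sa <- simulated_annealing(qm, anneal_schedule(zeta = 0.995, sweeps = 600),
                              n_repeats = 30, seed = 7)
    expect_equal(sa$best_energy, ex$energy)
    expect_gte(sa$best_energy, ex$energy - 1e-9)  # never below exact
  }
})

test_that("SA handles HUBOs via sequential sweeps", {
  h <- random_hubo(8, seed = 41, n_terms = 14, max_deg = 4)
  ex <- exact_solve(h, allow_large = TRUE)
  sa <- simulated_annealing(h, anneal_schedule(zeta = 0.99, sweeps = 400),
                            n_repeats = 20, seed = 2)
  expect_equal(sa$best_energy, ex$energy)
})

test_that("sample sets are reproducible and internally consistent", {
  qm <- random_qubo(10, seed = 33)
  sch <- anneal_schedule(zeta = 0.99, sweeps = 200)
  a <- simulated_annealing(qm, sch, 8, seed = 5)
  b <- simulated_annealing(qm, sch, 8, seed = 5)
  expect_identical(a$energies, b$energies)
  expect_identical(a$assignments, b$assignments)
  # stored energies match exact re-evaluation
  for (r in seq_len(nrow(a$assignments))) {
    expect_equal(evaluate_energy(qm, a$assignments[r, ]), a$energies[r])
  }
})

test_that("parallel tempering matches the exact optimum and swap rules", {
  qm <- random_qubo(12, seed = 55)
  ex <- exact_solve(qm)
  pt <- parallel_tempering(qm, pt_config(n_replicas = 8, t_min = 0.05,
                                         t_max = 5, sweeps = 800), seed = 3)
  expect_equal(pt$best$best_energy, ex$energy)
  expect_gte(pt$best$best_energy, ex$energy - 1e-9)
  expect_equal(length(pt$replica_energies), 8L)
  # near-identical temperatures: the swap exponent ~ 0, acceptance ~ 1
  pt2 <- parallel_tempering(qm, pt_config(n_replicas = 4, t_min = 1,
                                          t_max = 1 + 1e-9, sweeps = 100),
                            seed = 4)
  expect_true(all(pt2$swap_rates > 0.999))
  expect_error(pt_config(n_replicas = 1), "replicas")
  expect_error(pt_config(t_min = 2, t_max = 1), "t_min")
})

test_that("exact solver enumerates minima correctly", {
  qm <- quadratic_model(c("x", "y"), linear = c(-1, -1), qi = 1L, qj = 2L, qv = 2)
  ex <- exact_solve(qm)
  expect_equal(ex$energy, -1)
  expect_equal(ex$argmin_count, 2)
  expect_setequal(apply(ex$states, 1, paste, collapse = ""), c("10", "01"))
  z <- exact_solve(quadratic_model(c("a", "b")))
  expect_equal(z$energy, 0)
  expect_equal(z$argmin_count, 4)
  expect_error(exact_solve(random_qubo(25, 1)), "guard")
})

test_that("turn-space oracle bounds and guards", {
  enc <- encode_turn_tetrahedral("PPPPPP", flavor = "dense")
  expect_equal(turn_space_exact(enc)$energy, 0)
  # feasible space is a superset of valid folds, so its minimum cannot exceed
  # the SAW-oracle minimum
  s <- "HPPPPHP"
  enc2 <- encode_turn_tetrahedral(s, flavor = "dense")
  expect_lte(turn_space_exact(enc2)$energy,
             ground_truth_minimum(s, "diamond")$energy + 1e-9)
  expect_error(turn_space_exact(encode_coordinate("HPPH", lattice_spec("cartesian", 2))),
               "turn-based")
})

test_that("schedule and config validation", {
  expect_error(anneal_schedule(zeta = 1.2), "zeta")
  expect_error(anneal_schedule(t0 = -1), "t0")
  expect_error(anneal_schedule(sweeps = 0), "sweeps")
})
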