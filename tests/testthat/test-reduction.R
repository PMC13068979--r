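test_that("Rosenberg penalty arithmetic", {
  rp <- rosenberg_penalty(c(2L, 3L), 4L, 1)
  expect_equal(evaluate_energy(rp, c(0, 1, 1, 1)), 0)  # consistent
  expect_equal(evaluate_energy(rp, c(0, 1, 1, 0)), 1)  # alpha
  expect_equal(evaluate_energy(rp, c(0, 0, 0, 1)), 3)  # 3 alpha
  # value is 0 iff b4 = b2 b3, else >= alpha, for every state
  for (r in seq_len(8)) {
    st <- c(0, all_states(3)[r, ])
    v <- evaluate_energy(rp, st)
    if (st[4] == st[2] * st[3]) expect_equal(v, 0) else expect_gte(v, 1)
  }
  expect_error(rosenberg_penalty(c(1L, 2L), 3L, 0), "positive")
})

test_that("worst-case alpha sums all coefficient magnitudes", {
  expect_equal(worst_case_alpha(binary_polynomial(c("a", "b"))), 1)
  p <- binary_polynomial(c("a", "b", "c"), list(1L, c(1L, 2L, 3L)), c(2, -3))
  expect_equal(worst_case_alpha(p), 6)
  # alpha exceeds any single-state gain from violating one ancilla: brute force
  for (seed in 1:3) {
    h <- random_hubo(5, seed, n_terms = 8, max_deg = 3)
    red <- reduce_to_quadratic(h)
    expect_true(reduction_is_exact(h, red))
  }
})

test_that("already-quadratic input passes through with zero ancillas", {
  qm <- random_qubo(6, seed = 5)
  red <- reduce_to_quadratic(as_binary_polynomial(qm))
  expect_equal(nrow(red$record$ancillas), 0L)
  sts <- all_states(6)
  for (r in seq(1, 64, by = 7)) {
    expect_equal(evaluate_energy(red$model, sts[r, ]),
                 evaluate_energy(qm, sts[r, ]))
  }
})

test_that("cubic monomial reduces with one ancilla, exactly", {
  p <- binary_polynomial(paste0("b", 1:3), list(1:3), 1)
  red <- reduce_to_quadratic(p, alpha = 10)
  expect_equal(nrow(red$record$ancillas), 1L)
  expect_equal(red$record$final_degree, 2L)
  expect_true(reduction_is_exact(p, red))
})

test_that("random degree-4 HUBOs reduce exactly and map ground states", {
  for (seed in c(21, 22)) {
    h <- random_hubo(6, seed, n_terms = 10, max_deg = 4)
    red <- reduce_to_quadratic(h)
    expect_lte(red$record$final_degree, 2L)
    expect_true(reduction_is_exact(h, red))
    # argmin of the reduced model restricted to original variables equals the
    # argmin of the original HUBO
    sts <- all_states(6)
    orig_vals <- apply(sts, 1, function(b) evaluate_energy(h, b))
    ex <- exact_solve(red$model, allow_large = TRUE, keep = 4096)
    restr <- unique(ex$states[, 1:6, drop = FALSE])
    expect_equal(ex$energy, min(orig_vals))
    best_orig <- sts[abs(orig_vals - min(orig_vals)) < 1e-9, , drop = FALSE]
    expect_setequal(apply(restr, 1, paste, collapse = ""),
                    apply(best_orig, 1, paste, collapse = ""))
  }
})

test_that("ancilla count equals substitutions; shared pairs substituted once", {
  # two monomials sharing the pair (1,2): one ancilla suffices for both
  p <- binary_polynomial(paste0("b", 1:4),
                         list(c(1L, 2L, 3L), c(1L, 2L, 4L)), c(1, 1))
  red <- reduce_to_quadratic(p, alpha = 5)
  expect_equal(nrow(red$record$ancillas), 1L)
  expect_true(reduction_is_exact(p, red))
})

test_that("turn-model HUBOs reduce to solvable QUBOs", {
  enc <- encode_turn_tetrahedral("HPPPPH", flavor = "dense")
  red <- reduce_to_quadratic(enc)
  expect_lte(red$record$final_degree, 2L)
  ex_red <- exact_solve(red$model, allow_large = TRUE)
  ex_orig <- exact_solve(enc)
  expect_equal(ex_red$energy, ex_orig$energy)
})
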