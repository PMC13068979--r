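test_that("coordinate encodings have the advertised size and degree", {
  enc <- encode_coordinate("HPPHPPHPPH", min_grid(10, "cartesian"))
  expect_equal(n_variables(enc), 320L)  # 10 beads x 32 parity-class sites
  expect_equal(bp_degree(enc), 2L)

  encd <- encode_coordinate("HPPHPP", min_grid(6, "diamond"))
  expect_equal(sum(encd$decoder$bead == 1), 27L)  # per-bead register = sublattice
  expect_equal(bp_degree(encd), 2L)

  # capacity precondition
  expect_error(encode_coordinate("HPPHPPHPPH", lattice_spec("cartesian", 2)),
               "too small")
  # anchoring trims bead 1's register
  enca <- encode_coordinate("HPPH", lattice_spec("cartesian", 2), anchor = TRUE)
  expect_equal(sum(enca$decoder$bead == 1), 1L)
})

test_that("turn-based encodings have the printed bit counts and degrees", {
  seq11 <- "HPPPPHPPPPH"
  td <- encode_turn_tetrahedral(seq11, flavor = "dense")
  ts <- encode_turn_tetrahedral(seq11, flavor = "sparse")
  # 2 bits per free turn, first two turns fixed: 2 * (10 - 2) = 16
  expect_equal(sum(td$decoder$role == "turn_bit"), 16L)
  expect_equal(sum(ts$decoder$role == "turn_dir"), 32L)  # 4 one-hot bits/turn
  expect_equal(bp_degree(td), 5L)
  expect_equal(bp_degree(ts), 3L)

  cd <- encode_turn_cartesian("HPPHPPH", flavor = "dense")
  cs <- encode_turn_cartesian("HPPHPPH", flavor = "sparse")
  # 3 bits (dense) / 6 one-hot bits (sparse) per free turn
  expect_equal(sum(cd$decoder$role == "turn_bit"), 3L * 4L)
  expect_equal(sum(cs$decoder$role == "turn_dir"), 6L * 4L)
  expect_equal(bp_degree(cd), 8L)
  expect_equal(bp_degree(cs), 4L)
})

test_that("interaction variables appear exactly for eligible pairs", {
  td <- encode_turn_tetrahedral("HPPPPHPPPPH", flavor = "dense")
  qrows <- td$decoder[td$decoder$role == "interaction", ]
  expect_equal(nrow(qrows), 2L)
  expect_equal(paste(qrows$i, qrows$j), c("1 6", "6 11"))
  # even or short separations and P-involving pairs get no q variable
  t2 <- encode_turn_tetrahedral("HHPPHH", flavor = "dense")
  q2 <- t2$decoder[t2$decoder$role == "interaction", ]
  expect_equal(paste(q2$i, q2$j), "1 6")  # only (1,6) is odd >= 5
})

test_that("default penalties follow the worst-case rule and stay positive", {
  im <- hp_interaction()
  pw <- default_penalties("PPPPPP", im, "worst_case")
  expect_equal(pw$lambda_onehot, 1)  # no eligible pairs: base = 1
  expect_equal(pw$lambda2, 1)
  # HPPHPH has eligible H-H pairs (1,4) and (1,6): base = 1 + 2
  pk <- default_penalties("HPPHPH", im, "worst_case")
  expect_equal(pk$lambda_onehot, 3)
  expect_equal(pk$lambda_conn, 3)
  expect_true(all(unlist(default_penalties("HPPH", im, "tuned")) > 0))
  expect_error(penalty_config(lambda1 = 0), "strictly positive")
})

test_that("Eq.-style interaction bracket vanishes on clean contacts", {
  # feasible minimiser of HPPPPH: q = 1, D(i,j) = 1, guard distances 2,
  # so the bracket contributes exactly eps = -1
  enc <- encode_turn_tetrahedral("HPPPPH", flavor = "dense")
  ts <- turn_space_exact(enc)
  expect_equal(ts$energy, -1)
  m <- ts$minimizers[[which(vapply(ts$minimizers, function(x) x$valid, logical(1)))[1]]]
  a <- numeric(n_variables(enc))
  dec <- enc$decoder
  for (k in 3:5) {
    d <- m$turns[k] - 1
    rows <- dec[dec$role == "turn_bit" & dec$turn == k, ]
    rows <- rows[order(rows$bit), ]
    a[rows$var] <- c(d %% 2, d %/% 2)
  }
  qvar <- dec$var[dec$role == "interaction"]
  a[qvar] <- 1
  expect_equal(evaluate_energy(enc, a), -1)
  # with the interaction variable off the same conformation scores 0
  a[qvar] <- 0
  expect_equal(evaluate_energy(enc, a), 0)
})

test_that("tiny coordinate model: full exhaustive minimum equals the oracle", {
  # N = 4 on the 2-cube gives a 16-variable QUBO: enumerate everything
  pen <- default_penalties("HPPH", hp_interaction(), "worst_case")
  enc <- encode_coordinate("HPPH", lattice_spec("cartesian", 2), penalties = pen)
  expect_equal(n_variables(enc), 16L)
  ex <- exact_solve(enc)
  expect_equal(ex$energy, ground_truth_minimum("HPPH", "cartesian")$energy)
  expect_equal(ex$energy, lattice_fold_minimum("HPPH", lattice_spec("cartesian", 2))$energy)
})

test_that("feasible fold assignments reproduce contact energies exactly", {
  im <- hp_interaction()
  for (kind in c("cartesian", "diamond")) {
    s <- if (kind == "cartesian") "HPPHPH" else "HPPPPH"
    spec <- min_grid(nchar(s), kind)
    enc <- encode_coordinate(s, spec, im)
    lf <- lattice_fold_minimum(s, spec, im, keep = 5)
    for (f in lf$folds) {
      a <- encode_fold_assignment(f, enc)
      expect_equal(evaluate_energy(enc, a), contact_energy(f, s, im))
    }
  }
})

test_that("straight all-P chains are penalty-free in the turn models", {
  enc <- encode_turn_cartesian("PPPP", flavor = "dense")
  expect_equal(turn_space_exact(enc)$energy, 0)
  # the fully-fixed-plus-straight assignment evaluates to zero: all overlap
  # slacks can be satisfied
  ex <- exact_solve(enc, allow_large = TRUE)
  expect_equal(ex$energy, 0)
})
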