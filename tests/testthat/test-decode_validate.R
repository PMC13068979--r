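test_that("hand-built feasible coordinate assignment decodes to a valid fold", {
  im <- hp_interaction()
  enc <- encode_coordinate("HPPH", lattice_spec("cartesian", 2), im)
  lat <- build_lattice(lattice_spec("cartesian", 2))
  # unit square 0,0,0 -> 1,0,0 -> 1,1,0 -> 0,1,0
  f <- fold(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)), "cartesian")
  a <- encode_fold_assignment(f, enc)
  sol <- decode_solution(a, enc)
  expect_true(sol$flags$onehot_ok)
  expect_true(sol$flags$connectivity_ok)
  expect_true(sol$flags$self_avoiding)
  expect_equal(sol$contact_energy, -1)
  # clean flags: model energy equals the contact energy (penalties vanish)
  expect_equal(sol$model_energy, sol$contact_energy)
  expect_equal(unclass(sol$fold), unclass(f), ignore_attr = TRUE)
})

test_that("empty and overfull one-hot registers are flagged, not fatal", {
  enc <- encode_coordinate("HPPH", lattice_spec("cartesian", 2))
  f <- lattice_fold_minimum("HPPH", lattice_spec("cartesian", 2))$folds[[1]]
  a <- encode_fold_assignment(f, enc)
  a[enc$decoder$var[enc$decoder$bead == 2]] <- 0  # empty bead-2 register
  sol <- decode_solution(a, enc)
  expect_false(sol$flags$onehot_ok)
  expect_true(anyNA(sol$fold[2, ]))
  b <- encode_fold_assignment(f, enc)
  b[enc$decoder$var[enc$decoder$bead == 3]] <- 1  # overfull register
  expect_false(decode_solution(b, enc)$flags$onehot_ok)
})

test_that("feasible assignments are in bijection with lattice folds", {
  # all-P chain: the model is pure penalties, so zero-energy states are
  # exactly the feasible assignments; their count must equal the number of
  # chain placements with bead 1 on a parity-0 site
  pen <- default_penalties("PPPP", hp_interaction(), "worst_case")
  enc <- encode_coordinate("PPPP", lattice_spec("cartesian", 2), penalties = pen)
  ex <- exact_solve(enc, keep = 4096)
  lf <- lattice_fold_minimum("PPPP", lattice_spec("cartesian", 2))
  expect_equal(ex$energy, 0)
  expect_equal(ex$argmin_count, lf$n_folds)
})

test_that("turn-model decoding integrates turns and flags invalid codes", {
  enc <- encode_turn_tetrahedral("HPPPPH", flavor = "dense")
  ts <- turn_space_exact(enc)
  m <- ts$minimizers[[1]]
  a <- numeric(n_variables(enc))
  dec <- enc$decoder
  for (k in 3:5) {
    d <- m$turns[k] - 1
    rows <- dec[dec$role == "turn_bit" & dec$turn == k, ]
    rows <- rows[order(rows$bit), ]
    a[rows$var] <- c(d %% 2, d %/% 2)
  }
  a[dec$var[dec$role == "interaction"]] <- m$q
  sol <- decode_solution(a, enc)
  expect_true(sol$flags$connectivity_ok)
  expect_equal(sol$model_energy, ts$energy)
  expect_equal(unclass(sol$fold), unclass(m$fold), ignore_attr = TRUE)

  # dense Cartesian invalid code
  encc <- encode_turn_cartesian("PPPP", flavor = "dense")
  b <- numeric(n_variables(encc))
  tb <- encc$decoder[encc$decoder$role == "turn_bit", ]
  b[tb$var[order(tb$bit)]] <- c(0, 0, 1)  # null-step code (0,0,1)
  solc <- decode_solution(b, encc)
  expect_true(solc$flags$invalid_turn_codes)
})

test_that("ancilla consistency is checked when decoding reduced models", {
  enc <- encode_turn_tetrahedral("HPPPPH", flavor = "sparse")
  red <- reduce_to_quadratic(enc)
  ex <- exact_solve(red$model, allow_large = TRUE)
  a <- ex$states[1, ]
  sol <- decode_solution(a, enc, red$record)
  expect_true(sol$flags$ancilla_consistent)
  expect_equal(sol$model_energy, ex$energy)  # ground state is feasible
  # corrupt one ancilla
  bad <- a
  idx <- red$record$ancillas$ancilla_index[1]
  bad[idx] <- 1 - bad[idx]
  expect_false(decode_solution(bad, enc, red$record)$flags$ancilla_consistent)
})

test_that("decode-then-reencode reproduces the assignment and energy", {
  im <- hp_interaction()
  enc <- encode_coordinate("HPPHPH", min_grid(6, "cartesian"), im)
  lf <- lattice_fold_minimum("HPPHPH", min_grid(6, "cartesian"), im)
  a <- encode_fold_assignment(lf$folds[[1]], enc)
  sol <- decode_solution(a, enc)
  a2 <- encode_fold_assignment(sol$fold, enc)
  expect_identical(a, a2)
  expect_equal(evaluate_energy(enc, a2), sol$model_energy)
})

test_that("the overlap-flaw demonstration behaves per model structure", {
  # all-P chains short enough to exclude non-backtracking self-intersection:
  # only valid minimisers at zero energy
  rep0 <- demonstrate_overlap_flaw("PPPPPP")
  expect_equal(rep0$energy, 0)
  expect_equal(rep0$n_overlapping, 0L)
  expect_gt(rep0$n_valid, 0L)
})
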