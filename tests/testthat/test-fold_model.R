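test_that("sequences and interaction matrices validate", {
  s <- as_protein_sequence("HPPH")
  expect_equal(attr(s, "alphabet"), "HP")
  expect_equal(seq_length(s), 4L)
  expect_warning(as_protein_sequence("hpph"), "uppercase")
  expect_error(as_protein_sequence("H"), "at least 2")
  expect_error(as_protein_sequence("HXZH", alphabet = "HP"), "invalid residues")

  im <- hp_interaction()
  expect_equal(im$eps["H", "H"], -1)
  expect_equal(sum(im$eps != 0), 1)

  bad <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("H", "P"), c("H", "P")))
  expect_error(interaction_matrix(bad), "not symmetric")

  expect_equal(unclass(hp_collapse("ACDEFG"))[1], "HHPPHP")
})

test_that("contact energy follows the |i-j| >= 3 adjacency rule", {
  im <- hp_interaction()
  # straight chains have no non-bonded contacts
  straight <- fold(cbind(0:5, 0, 0), "cartesian")
  expect_equal(contact_energy(straight, "HHHHHH", im), 0)
  # any 3-bead fold scores 0 (|i-j| >= 3 impossible)
  f3 <- fold(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), "cartesian")
  expect_equal(contact_energy(f3, "HHH", im), 0)
  # HPPH on a unit square: one H-H contact
  sq <- fold(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)), "cartesian")
  expect_equal(contact_energy(sq, "HPPH", im), -1)
  expect_true(fold_valid(sq))
  # overlapping beads contribute no contact but energy is still defined
  ov <- fold(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 0, 0)), "cartesian")
  expect_false(fold_is_self_avoiding(ov))
  expect_equal(contact_energy(ov, "HPPH", im), 0)
  expect_error(contact_energy(sq, "HPPHH", im), "lengths differ")
})

test_that("contact energy is invariant under lattice symmetries", {
  im <- hp_interaction()
  gt <- ground_truth_minimum("HPPHPH", "cartesian", keep = 5)
  f <- gt$folds[[1]]
  e0 <- contact_energy(f, "HPPHPH", im)
  set.seed(4)
  for (k in 1:5) {
    perm <- sample(3)
    signs <- sample(c(-1, 1), 3, replace = TRUE)
    shift <- sample(-3:3, 3, replace = TRUE)
    g <- fold(sweep(f[, perm] %*% diag(signs), 2, shift, "+"), "cartesian")
    expect_equal(contact_energy(g, "HPPHPH", im), e0)
  }
  # diamond: translation by a sublattice-A vector preserves the structure
  gtd <- ground_truth_minimum("HPPPPH", "diamond", keep = 2)
  fd <- gtd$folds[[1]]
  gd <- fold(sweep(unclass(fd), 2, c(0, 2, 2), "+"), "diamond")
  expect_equal(contact_energy(gd, "HPPPPH", im),
               contact_energy(fd, "HPPPPH", im))
})

test_that("SAW enumeration matches known counts and a naive oracle", {
  expect_length(enumerate_saws(2, "cartesian"), 6)
  expect_length(enumerate_saws(2, "diamond"), 4)
  expect_length(enumerate_saws(3, "diamond"), 12)  # 4 * 3, no reversal
  for (n in 2:5) {
    expect_equal(length(enumerate_saws(n, "cartesian")), naive_cubic_saw_count(n))
  }
  # symmetry reduction divides the first-step degeneracy out
  expect_length(enumerate_saws(3, "cartesian", reduce_symmetry = TRUE), 5)
  expect_error(enumerate_saws(12, "cartesian"), "guard")
  # every enumerated walk is a valid fold
  expect_true(all(vapply(enumerate_saws(5, "diamond"), fold_valid, logical(1))))
})

test_that("minimal contact lengths are 4 (cubic) and 6 (diamond)", {
  expect_equal(min_contact_length("cartesian"), 4L)
  expect_equal(min_contact_length("diamond"), 6L)
  # below the threshold every SAW scores zero even for all-H sequences
  im <- hp_interaction()
  for (n in 3:5) {
    seqn <- paste(rep("H", n), collapse = "")
    es <- vapply(enumerate_saws(n, "diamond"), contact_energy, numeric(1),
                 seq = seqn, im = im)
    expect_true(all(es == 0))
  }
})

test_that("ground-truth minima from exhaustive enumeration", {
  expect_equal(ground_truth_minimum("HPPH", "cartesian")$energy, -1)
  expect_equal(ground_truth_minimum("PPPPPP", "cartesian")$energy, 0)
  expect_equal(ground_truth_minimum("HPPPPH", "diamond")$energy, -1)
  # HP minima are never positive (a contact-free walk always exists)
  for (seed in 1:4) {
    s <- random_hp(7, seed)
    expect_lte(ground_truth_minimum(s, "cartesian")$energy, 0)
  }
  # argmin folds actually achieve the reported minimum and are valid
  gt <- ground_truth_minimum("HPPHPH", "cartesian", keep = 10)
  for (f in gt$folds) {
    expect_true(fold_valid(f))
    expect_equal(contact_energy(f, "HPPHPH", hp_interaction()), gt$energy)
  }
})

test_that("fold writers emit well-formed records", {
  sq <- fold(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)), "cartesian")
  xyz <- tempfile(fileext = ".xyz")
  write_fold_xyz(sq, "HPPH", xyz)
  lines <- readLines(xyz)
  expect_equal(lines[1], "4")
  expect_length(lines, 6)
  pdb <- tempfile(fileext = ".pdb")
  write_fold_pdb(sq, "HPPH", pdb)
  expect_equal(sum(grepl("^ATOM", readLines(pdb))), 4)
})
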