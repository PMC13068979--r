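test_that("small lattices have the printed sizes and degrees", {
  l2 <- build_lattice(lattice_spec("cartesian", 2))
  expect_equal(nrow(l2$coords), 8L)
  expect_true(all(lengths(l2$adj) == 3))  # every corner of the 2-cube

  l3 <- build_lattice(lattice_spec("cartesian", 3))
  expect_equal(nrow(l3$coords), 27L)
  center <- which(apply(l3$coords, 1, function(p) all(p == 1)))
  expect_equal(length(l3$adj[[center]]), 6L)

  d3 <- build_lattice(lattice_spec("diamond", 3))
  expect_equal(nrow(d3$coords), 54L)
  expect_equal(as.integer(table(d3$parity)), c(27L, 27L))
  expect_true(all(lengths(d3$adj) >= 1 & lengths(d3$adj) <= 4))
})

test_that("adjacency is symmetric, irreflexive and bipartite by parity", {
  for (spec in list(lattice_spec("cartesian", 3), lattice_spec("diamond", 2),
                    lattice_spec("diamond", 3))) {
    lat <- build_lattice(spec)
    for (i in seq_along(lat$adj)) {
      expect_false(i %in% lat$adj[[i]])
      for (j in lat$adj[[i]]) {
        expect_true(i %in% lat$adj[[j]])
        expect_true(lat$parity[i] != lat$parity[j])  # proper 2-coloring
      }
    }
  }
})

test_that("interior sites have full degree", {
  l4 <- build_lattice(lattice_spec("cartesian", 4))
  interior <- apply(l4$coords, 1, function(p) all(p >= 1 & p <= 2))
  expect_true(all(lengths(l4$adj)[interior] == 6))
  d3 <- build_lattice(lattice_spec("diamond", 3))
  # a B site inside the sublattice-A hull has all four neighbours
  expect_true(any(lengths(d3$adj) == 4))
})

test_that("site ordering is deterministic and neighbor queries validated", {
  a <- build_lattice(lattice_spec("diamond", 3))
  b <- build_lattice(lattice_spec("diamond", 3))
  expect_identical(a$coords, b$coords)
  expect_identical(a$adj, b$adj)

  l3 <- build_lattice(lattice_spec("cartesian", 3))
  origin <- which(apply(l3$coords, 1, function(p) all(p == 0)))
  nb <- l3$coords[neighbors(l3, origin), , drop = FALSE]
  expect_setequal(apply(nb, 1, paste, collapse = ","),
                  c("1,0,0", "0,1,0", "0,0,1"))
  expect_error(neighbors(l3, 99L), "unknown site_id")
  expect_error(site_parity(l3, 0L), "unknown site_id")

  # diamond sublattice-0 site: all neighbours on sublattice 1
  d <- build_lattice(lattice_spec("diamond", 2))
  s0 <- which(d$parity == 0L)[1]
  expect_true(all(site_parity(d, neighbors(d, s0)) == 1L))
  expect_lte(length(neighbors(d, s0)), 4L)
})

test_that("min_grid follows the printed formulas", {
  g <- min_grid(10, "cartesian")
  expect_equal(g$extents, rep(4L, 3))
  expect_equal(g$site_count, 64L)
  expect_equal(min_grid(10, "diamond")$extents, rep(3L, 2))
  expect_equal(min_grid(10, "diamond")$site_count, 54L)
  expect_equal(min_grid(2, "cartesian")$extents, rep(3L, 3))
  expect_equal(min_grid(8, "cartesian")$extents, rep(3L, 3))  # exact cube root
  expect_error(min_grid(1, "cartesian"), ">= 2")
  expect_error(lattice_spec("cartesian", 0), "positive")
})

test_that("lattice JSON dump round-trips structure", {
  lat <- build_lattice(lattice_spec("cartesian", 2))
  path <- tempfile(fileext = ".json")
  lattice_to_json(lat, path)
  x <- jsonlite::read_json(path)
  expect_equal(x$kind, "cartesian")
  expect_equal(length(x$sites), 8)
  expect_equal(length(x$edges), 12)  # edges of the 2-cube
})
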