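#' Finite lattice specification
#'
#' Two lattice families are supported.  `"cartesian"` is the simple-cubic
#' lattice on an `Lx x Ly x Lz` box with up to 6 neighbours per site.
#' `"diamond"` is the tetrahedral lattice built from two interleaved FCC
#' sublattices offset by a quarter of the cell diagonal; each sublattice is a
#' parallelepiped of `l^3` primitive cells, every site has up to 4
#' neighbours, and the two sublattices are the parity classes of the
#' (bipartite) adjacency graph.
#'
#' Integer quarter-cell coordinates are used throughout: sublattice A is
#' spanned by (0,2,2), (2,0,2), (2,2,0) and sublattice B is A + (1,1,1), so
#' the four A-to-B neighbour offsets are (1,1,1), (1,-1,-1), (-1,1,-1),
#' (-1,-1,1) (the sign-product +1 vectors).
#'
#' @param kind `"cartesian"` or `"diamond"`.
#' @param extents positive integers: length 1 or 3 (`Lx, Ly, Lz`) for
#'   cartesian; length 1 or 2 (cells per FCC sublattice) for diamond.
#' @return A `lattice_spec` with fields `kind`, `extents`, `site_count`.
#' @examples
#' lattice_spec("diamond", 3)$site_count  # 2 * 27 = 54
#' @export
lattice_spec <- function(kind = c("cartesian", "diamond"), extents) {
  kind <- match.arg(kind)
  extents <- as.integer(extents)
  if (any(is.na(extents)) || any(extents < 1)) stop("extents must be positive integers")
  if (kind == "cartesian") {
    if (length(extents) == 1) extents <- rep(extents, 3)
    if (length(extents) != 3) stop("cartesian extents must have length 1 or 3")
    sc <- prod(extents)
  } else {
    if (length(extents) == 1) extents <- rep(extents, 2)
    if (length(extents) != 2) stop("diamond extents must have length 1 or 2")
    sc <- sum(extents^3)
  }
  structure(list(kind = kind, extents = extents, site_count = as.integer(sc)),
            class = "lattice_spec")
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf("<lattice_spec> %s [%s], %d sites\n", x$kind,
              paste(x$extents, collapse = "x"), x$site_count))
  invisible(x)
}

# integer cube root with guard against floating error (8^(1/3) = 2 exactly)
int_ceil_root3 <- function(x) {
  r <- x^(1 / 3)
  if (abs(r - round(r)) < 1e-9) r <- round(r)
  as.integer(ceiling(r))
}

#' Minimal symmetric grid for a chain of given length
#'
#' The smallest symmetric box that can host the native fold of an N-residue
#' chain, with one extra layer of slack:
#' \eqn{L_{min} = \lceil N^{1/3} \rceil + 1} for the cubic lattice and
#' \eqn{l_{min} = \lceil (N/2)^{1/3} \rceil + 1} cells per sublattice for the
#' diamond lattice.
#'
#' @param sequence_length chain length N (>= 2).
#' @param kind lattice kind.
#' @return A `lattice_spec`.
#' @examples
#' min_grid(10, "cartesian")  # L = 4, 64 sites
#' min_grid(10, "diamond")    # l = 3, 54 sites
#' @export
min_grid <- function(sequence_length, kind = c("cartesian", "diamond")) {
  kind <- match.arg(kind)
  n <- as.integer(sequence_length)
  if (is.na(n) || n < 2) stop("sequence_length must be an integer >= 2")
  if (kind == "cartesian") {
    lattice_spec("cartesian", int_ceil_root3(n) + 1L)
  } else {
    lattice_spec("diamond", int_ceil_root3(n / 2) + 1L)
  }
}

#' Build a finite lattice with site index map and adjacency
#'
#' Sites are indexed 1..site_count in a deterministic order: lexicographic on
#' (x, y, z) for the cubic lattice; sublattice-major (all of sublattice A
#' first), lexicographic within each sublattice, for the diamond lattice.
#' Parity is (x+y+z) mod 2 for cubic sites and sublattice membership (A = 0,
#' B = 1) for diamond sites; adjacent sites always have opposite parity.
#'
#' @param spec a `lattice_spec`.
#' @return A `lattice` object: the spec plus `coords` (site_count x 3 integer
#'   matrix), `parity` (0/1 vector) and `adj` (list of neighbour site ids).
#' @export
build_lattice <- function(spec) {
  stopifnot(inherits(spec, "lattice_spec"))
  if (spec$kind == "cartesian") {
    e <- spec$extents
    g <- expand.grid(z = 0:(e[3] - 1), y = 0:(e[2] - 1), x = 0:(e[1] - 1))
    coords <- as.matrix(g[, c("x", "y", "z")])
    coords <- coords[order(coords[, 1], coords[, 2], coords[, 3]), , drop = FALSE]
    parity <- as.integer(rowSums(coords) %% 2)
    offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                     c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else {
    e <- spec$extents
    basis <- rbind(c(0, 2, 2), c(2, 0, 2), c(2, 2, 0))
    sub_coords <- function(l, shift) {
      g <- as.matrix(expand.grid(i = 0:(l - 1), j = 0:(l - 1), k = 0:(l - 1)))
      xyz <- g %*% basis
      xyz <- sweep(xyz, 2, shift, "+")
      xyz[order(xyz[, 1], xyz[, 2], xyz[, 3]), , drop = FALSE]
    }
    a <- sub_coords(e[1], c(0, 0, 0))
    b <- sub_coords(e[2], c(1, 1, 1))
    coords <- rbind(a, b)
    parity <- c(rep(0L, nrow(a)), rep(1L, nrow(b)))
    offsets <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  }
  dimnames(coords) <- NULL
  n <- nrow(coords)
  key <- paste(coords[, 1], coords[, 2], coords[, 3])
  id_of <- new.env(parent = emptyenv())
  for (i in seq_len(n)) id_of[[key[i]]] <- i
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    sgn <- if (spec$kind == "diamond" && parity[i] == 1L) -1L else 1L
    nb <- integer(0)
    for (r in seq_len(nrow(offsets))) {
      p <- coords[i, ] + sgn * offsets[r, ]
      j <- id_of[[paste(p[1], p[2], p[3])]]
      if (!is.null(j)) nb <- c(nb, j)
    }
    adj[[i]] <- sort(nb)
  }
  structure(list(spec = spec, coords = coords, parity = parity, adj = adj),
            class = "lattice")
}

#' @export
print.lattice <- function(x, ...) {
  cat(sprintf("<lattice> %s [%s], %d sites, %d edges\n", x$spec$kind,
              paste(x$spec$extents, collapse = "x"), nrow(x$coords),
              sum(lengths(x$adj)) / 2))
  invisible(x)
}

#' Neighbours and parity of a lattice site
#'
#' @param lattice a built `lattice`.
#' @param site_id integer site id in 1..site_count.
#' @return `neighbors()`: integer vector of adjacent site ids;
#'   `site_parity()`: 0 or 1.
#' @export
neighbors <- function(lattice, site_id) {
  stopifnot(inherits(lattice, "lattice"))
  site_id <- as.integer(site_id)
  if (is.na(site_id) || site_id < 1 || site_id > nrow(lattice$coords)) {
    stop("unknown site_id: ", site_id)
  }
  lattice$adj[[site_id]]
}

#' @rdname neighbors
#' @export
site_parity <- function(lattice, site_id) {
  stopifnot(inherits(lattice, "lattice"))
  site_id <- as.integer(site_id)
  if (is.na(site_id) || site_id < 1 || site_id > nrow(lattice$coords)) {
    stop("unknown site_id: ", site_id)
  }
  lattice$parity[site_id]
}

#' Serialize a lattice to JSON
#'
#' Writes `{kind, extents, sites: [{id, xyz, parity}], edges: [[i, j]]}`.
#'
#' @param lattice a `lattice`.
#' @param path output file.
#' @export
lattice_to_json <- function(lattice, path) {
  stopifnot(inherits(lattice, "lattice"))
  n <- nrow(lattice$coords)
  sites <- lapply(seq_len(n), function(i) {
    list(id = i, xyz = as.integer(lattice$coords[i, ]),
         parity = lattice$parity[i])
  })
  edges <- list()
  for (i in seq_len(n)) {
    for (j in lattice$adj[[i]]) if (j > i) edges[[length(edges) + 1]] <- c(i, j)
  }
  jsonlite::write_json(
    list(kind = lattice$spec$kind, extents = lattice$spec$extents,
         sites = sites, edges = edges),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
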