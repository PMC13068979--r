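#' Fold: ordered bead coordinates on a lattice
#'
#' A fold is the ordered list of integer lattice coordinates of the N beads
#' of a chain.  Connectivity (consecutive beads on adjacent sites) and
#' self-avoidance (distinct coordinates) are *computed* properties, not
#' constructor requirements: invalid, self-intersecting folds must be
#' representable because some encodings admit them as feasible solutions.
#'
#' Rows may be NA for beads a decoder could not place.
#'
#' @param coords N x 3 integer matrix of bead coordinates (quarter-cell
#'   units for the diamond lattice).
#' @param kind `"cartesian"` or `"diamond"`.
#' @return A `fold` object.
#' @export
fold <- function(coords, kind = c("cartesian", "diamond")) {
  kind <- match.arg(kind)
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("fold coordinates must be N x 3")
  storage.mode(coords) <- "integer"
  structure(coords, class = "fold", kind = kind)
}

#' @export
print.fold <- function(x, ...) {
  cat(sprintf("<fold> %d beads on %s lattice, valid: %s\n", nrow(x),
              attr(x, "kind"), fold_valid(x)))
  invisible(x)
}

# are the sites of bead i and bead j adjacent? (i gives the step-sign
# convention on the diamond lattice: odd 1-based beads sit on sublattice A)
beads_adjacent <- function(f, i, j) {
  if (any(is.na(f[i, ])) || any(is.na(f[j, ]))) return(FALSE)
  d <- f[j, ] - f[i, ]
  if (attr(f, "kind") == "cartesian") return(sum(abs(d)) == 1)
  all(abs(d) == 1) && prod(d) == (if (i %% 2 == 1) 1 else -1)
}

#' Validity predicates for folds
#'
#' `fold_is_connected()`: every consecutive bead pair occupies adjacent
#' sites.  `fold_is_self_avoiding()`: all bead coordinates are distinct.
#' `fold_valid()`: both.
#'
#' @param f a `fold`.
#' @export
fold_is_connected <- function(f) {
  stopifnot(inherits(f, "fold"))
  n <- nrow(f)
  if (anyNA(f)) return(FALSE)
  all(vapply(seq_len(n - 1), function(i) beads_adjacent(f, i, i + 1), logical(1)))
}

#' @rdname fold_is_connected
#' @export
fold_is_self_avoiding <- function(f) {
  stopifnot(inherits(f, "fold"))
  if (anyNA(f)) return(FALSE)
  !anyDuplicated(paste(f[, 1], f[, 2], f[, 3]))
}

#' @rdname fold_is_connected
#' @export
fold_valid <- function(f) fold_is_connected(f) && fold_is_self_avoiding(f)

#' Contact energy of a fold
#'
#' Sums \eqn{\epsilon(a_i, a_j)} over all bead pairs with sequence
#' separation \eqn{|i-j| \ge 3} whose sites are lattice-adjacent.  Bonded
#' pairs are excluded and overlapping beads contribute no contact, so the
#' energy is defined for self-intersecting folds too.
#'
#' @param f a `fold` of the same length as the sequence.
#' @param seq a `protein_sequence`.
#' @param im an `interaction_matrix`.
#' @return The contact energy (dimensionless model units, k_B = 1).
#' @examples
#' sq <- fold(rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0)), "cartesian")
#' contact_energy(sq, as_protein_sequence("HPPH"), hp_interaction())
#' @export
contact_energy <- function(f, seq, im) {
  stopifnot(inherits(f, "fold"))
  seq <- as_protein_sequence(seq)
  n <- nrow(f)
  if (n != seq_length(seq)) stop("fold and sequence lengths differ")
  p <- pair_energy_matrix(seq, im)
  e <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j - i >= 3 && p[i, j] != 0 && beads_adjacent(f, i, j)) e <- e + p[i, j]
    }
  }
  e
}

#' Write folds as XYZ or CA-only PDB-like records
#'
#' @param f a `fold`.
#' @param seq the matching sequence (element column / residue names).
#' @param path output file.
#' @export
write_fold_xyz <- function(f, seq, path) {
  stopifnot(inherits(f, "fold"))
  res <- seq_residues(seq)
  lines <- c(sprintf("%d", nrow(f)),
             sprintf("lattice=%s", attr(f, "kind")),
             sprintf("%s %d %d %d", res, f[, 1], f[, 2], f[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fold_xyz
#' @export
write_fold_pdb <- function(f, seq, path) {
  stopifnot(inherits(f, "fold"))
  res <- seq_residues(seq)
  three <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
             H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
             P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
             W = "TRP", Y = "TYR")
  rn <- ifelse(res %in% names(three), three[res],
               ifelse(res == "H", "HPH", "HPP"))
  lines <- sprintf("ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                   seq_len(nrow(f)), rn, seq_len(nrow(f)),
                   as.numeric(f[, 1]), as.numeric(f[, 2]), as.numeric(f[, 3]))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
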