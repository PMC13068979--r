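#' Exhaustive enumeration of self-avoiding walks
#'
#' Enumerates every self-avoiding walk of `n` beads starting at the origin of
#' the infinite cubic or diamond lattice, in a deterministic depth-first
#' order over the lattice step directions.  These walks are the ground-truth
#' space of valid folds against which the binary encodings are checked.
#'
#' The walk count grows exponentially; the default guards (`n <= 10` cubic,
#' `n <= 14` diamond) keep enumeration below a few seconds.  Pass
#' `allow_large = TRUE` to override.
#'
#' @param n number of beads (>= 1).
#' @param kind lattice kind.
#' @param reduce_symmetry if TRUE the first step is fixed to direction 1,
#'   removing the global orientation degeneracy of the first bond.
#' @param allow_large override the enumeration guard.
#' @return A list of `fold` objects.
#' @examples
#' length(enumerate_saws(2, "cartesian"))  # 6
#' length(enumerate_saws(3, "diamond"))    # 12
#' @export
enumerate_saws <- function(n, kind = c("cartesian", "diamond"),
                           reduce_symmetry = FALSE, allow_large = FALSE) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  stopifnot(n >= 1)
  guard <- if (kind == "cartesian") 10L else 14L
  if (n > guard && !allow_large) {
    stop("n = ", n, " exceeds the enumeration guard for ", kind,
         " (", guard, "); pass allow_large = TRUE to override")
  }
  res <- cpp_saw_scan(n, kind, reduce_symmetry, NULL, TRUE, 0L)
  lapply(res$folds, fold, kind = kind)
}

#' Minimal chain length admitting a non-bonded nearest-neighbour contact
#'
#' By exhaustive enumeration: the smallest N such that some self-avoiding
#' walk of N beads places two beads with sequence separation >= 3 on
#' adjacent sites.  The chain geometry gives 4 on the cubic and 6 on the
#' diamond lattice.
#'
#' @param kind lattice kind.
#' @return An integer.
#' @export
min_contact_length <- function(kind = c("cartesian", "diamond")) {
  kind <- match.arg(kind)
  for (n in 3:10) {
    res <- cpp_saw_scan(n, kind, TRUE, NULL, FALSE, 0L)
    if (res$n_contact_walks > 0) return(n)
  }
  stop("no contact found up to n = 10")  # unreachable for supported lattices
}

#' Exact lattice-space ground state by exhaustive SAW enumeration
#'
#' Minimises the contact energy over every self-avoiding walk of the chain
#' on the infinite lattice.  Symmetry reduction (first step fixed) is applied
#' by default; contact energies are invariant under the lattice point group,
#' so the minimum is unaffected.
#'
#' @param seq a `protein_sequence`.
#' @param kind lattice kind.
#' @param im an `interaction_matrix` (HP preset by default).
#' @param keep maximum number of minimising folds returned.
#' @param allow_large override the enumeration guard (n <= 10 cubic,
#'   n <= 14 diamond).
#' @return list(energy, folds = list of minimising `fold`s,
#'   argmin_count, n_walks).
#' @examples
#' ground_truth_minimum(as_protein_sequence("HPPH"), "cartesian")$energy  # -1
#' @export
ground_truth_minimum <- function(seq, kind = c("cartesian", "diamond"),
                                 im = hp_interaction(), keep = 100L,
                                 allow_large = FALSE) {
  kind <- match.arg(kind)
  seq <- as_protein_sequence(seq)
  n <- seq_length(seq)
  guard <- if (kind == "cartesian") 10L else 14L
  if (n > guard && !allow_large) {
    stop("N = ", n, " exceeds the enumeration guard; pass allow_large = TRUE")
  }
  p <- pair_energy_matrix(seq, im)
  res <- cpp_saw_scan(n, kind, TRUE, p, FALSE, as.integer(keep))
  list(energy = res$min_energy,
       folds = lapply(res$folds, fold, kind = kind),
       argmin_count = res$argmin_count,
       n_walks = res$n_walks)
}

#' Exact minimum over chain placements on a finite lattice
#'
#' Enumerates every self-avoiding placement of the chain on a built finite
#' lattice, with bead 1 restricted to parity-0 sites (the coordinate-model
#' bead-parity convention), and minimises the contact energy.  This is the
#' feasible space of the coordinate-based encodings, so the result equals
#' their feasible-space minimum.
#'
#' @param seq sequence.
#' @param lattice a built `lattice` (or a `lattice_spec`).
#' @param im interaction matrix.
#' @param keep max number of minimising placements returned.
#' @return list(energy, site_paths = list of site-id vectors, folds,
#'   argmin_count, n_folds).
#' @export
lattice_fold_minimum <- function(seq, lattice, im = hp_interaction(), keep = 10L) {
  if (inherits(lattice, "lattice_spec")) lattice <- build_lattice(lattice)
  stopifnot(inherits(lattice, "lattice"))
  seq <- as_protein_sequence(seq)
  n <- seq_length(seq)
  p <- pair_energy_matrix(seq, im)
  res <- cpp_lattice_fold_scan(lattice$adj, lattice$parity, n, p, as.integer(keep))
  folds <- lapply(res$folds, function(path) {
    fold(lattice$coords[path, , drop = FALSE], lattice$spec$kind)
  })
  list(energy = res$min_energy, site_paths = res$folds, folds = folds,
       argmin_count = res$argmin_count, n_folds = res$n_folds)
}
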