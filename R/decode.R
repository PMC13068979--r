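#' Decode a solver bitstring back to a fold
#'
#' Maps an assignment of a (possibly Rosenberg-reduced) encoded model back to
#' bead coordinates, computing feasibility flags rather than raising on
#' infeasible states: self-intersecting or partially decodable configurations
#' are first-class results because some encodings admit them as (even
#' optimal) feasible solutions.
#'
#' Flags: `onehot_ok` (every one-hot register has exactly one bit set;
#' coordinate models and sparse turn registers), `connectivity_ok`,
#' `self_avoiding`, `invalid_turn_codes` (dense Cartesian only),
#' `ancilla_consistent` (every ancilla equals the product of its parents).
#' When all flags are clean, the model energy equals the contact energy
#' (all penalties vanish).
#'
#' @param assignment 0/1 vector over the model's variables (reduced model
#'   variables if `reduction` is given).
#' @param encoded the `encoded_model`.
#' @param reduction optional `reduction_record`; ancillas are stripped after
#'   a consistency check.
#' @return A `decoded_solution`: list(fold, flags, model_energy,
#'   contact_energy).
#' @export
decode_solution <- function(assignment, encoded, reduction = NULL) {
  stopifnot(inherits(encoded, "encoded_model"))
  seq <- as_protein_sequence(encoded$sequence)
  n <- seq_length(seq)
  ancilla_consistent <- TRUE
  model_energy <- NA_real_
  if (!is.null(reduction)) {
    stopifnot(inherits(reduction, "reduction_record"))
    n_red <- length(reduction$original_labels) + nrow(reduction$ancillas)
    if (length(assignment) != n_red) stop("assignment/reduced-model size mismatch")
    a <- as.numeric(assignment)
    for (k in seq_len(nrow(reduction$ancillas))) {
      idx <- reduction$ancillas$ancilla_index[k]
      p1 <- reduction$ancillas$parent1[k]; p2 <- reduction$ancillas$parent2[k]
      if (a[idx] != a[p1] * a[p2]) ancilla_consistent <- FALSE
    }
    assignment <- a[seq_along(reduction$original_labels)]
  }
  a <- check_assignment(encoded$poly, assignment, c(0, 1))
  model_energy <- evaluate_energy(encoded$poly, a)
  dec <- encoded$decoder
  onehot_ok <- TRUE
  invalid_turn_codes <- FALSE
  kind <- if (encoded$model_kind %in% c("coord_cartesian", "turn_cartesian"))
    "cartesian" else "diamond"

  if (encoded$model_kind %in% c("coord_cartesian", "coord_tetrahedral")) {
    lat <- build_lattice(encoded$lattice)
    coords <- matrix(NA_integer_, n, 3)
    for (t in seq_len(n)) {
      rows <- dec[dec$role == "site" & dec$bead == t, ]
      on <- rows$site[a[rows$var] == 1]
      if (length(on) == 1) coords[t, ] <- lat$coords[on, ]
      else onehot_ok <- FALSE
    }
    f <- fold(coords, kind)
  } else {
    nturn <- n - 1
    dirs <- integer(nturn)
    dirs[seq_along(encoded$fixed_dirs)] <- encoded$fixed_dirs
    for (k in seq_len(nturn)) {
      if (k <= length(encoded$fixed_dirs)) next
      rows <- dec[dec$role %in% c("turn_bit", "turn_dir") & dec$turn == k, ]
      rows <- rows[order(rows$bit), ]
      bits <- a[rows$var]
      if (encoded$flavor == "sparse") {
        on <- which(bits == 1)
        if (length(on) != 1) { onehot_ok <- FALSE; dirs[k] <- NA_integer_ }
        else dirs[k] <- on
      } else if (kind == "diamond") {
        dirs[k] <- 1L + bits[1] + 2L * bits[2]
      } else {
        code <- match(paste(bits, collapse = ""),
                      apply(CART_DENSE_CODE, 1, paste, collapse = ""))
        if (is.na(code)) { invalid_turn_codes <- TRUE; dirs[k] <- NA_integer_ }
        else dirs[k] <- code
      }
    }
    if (anyNA(dirs)) {
      coords <- matrix(NA_integer_, n, 3)
      coords[1, ] <- 0L
      dtab <- turn_dirs(kind)
      for (k in seq_len(nturn)) {
        if (is.na(dirs[k]) || anyNA(coords[k, ])) break
        s <- if (kind == "diamond" && k %% 2 == 0) -1L else 1L
        coords[k + 1, ] <- coords[k, ] + s * dtab[dirs[k], ]
      }
      f <- fold(coords, kind)
    } else {
      f <- decode_turns_to_fold(dirs, kind)
    }
  }

  flags <- list(onehot_ok = onehot_ok,
                connectivity_ok = fold_is_connected(f),
                self_avoiding = fold_is_self_avoiding(f),
                invalid_turn_codes = invalid_turn_codes,
                ancilla_consistent = ancilla_consistent)
  ce <- if (!anyNA(f)) contact_energy(f, seq, encoded$im) else NA_real_
  structure(list(fold = f, flags = flags, model_energy = model_energy,
                 contact_energy = ce),
            class = "decoded_solution")
}

#' @export
print.decoded_solution <- function(x, ...) {
  ok <- x$flags
  cat(sprintf(paste0("<decoded_solution> model energy %g, contact energy %s; ",
                     "onehot %s, connected %s, self-avoiding %s\n"),
              x$model_energy,
              if (is.na(x$contact_energy)) "NA" else sprintf("%g", x$contact_energy),
              ok$onehot_ok, ok$connectivity_ok, ok$self_avoiding))
  invisible(x)
}

#' Encode a fold as a feasible coordinate-model assignment
#'
#' Inverse of [decode_solution()] for coordinate models: places each bead's
#' one-hot register according to the fold (which must live on the model's
#' lattice with bead 1 on a parity-0 site).
#'
#' @param f a `fold` whose rows are coordinates of sites of the model's
#'   lattice.
#' @param encoded a coordinate-based `encoded_model`.
#' @return A 0/1 assignment vector.
#' @export
encode_fold_assignment <- function(f, encoded) {
  stopifnot(inherits(encoded, "encoded_model"),
            encoded$model_kind %in% c("coord_cartesian", "coord_tetrahedral"))
  lat <- build_lattice(encoded$lattice)
  key <- paste(lat$coords[, 1], lat$coords[, 2], lat$coords[, 3])
  site <- match(paste(f[, 1], f[, 2], f[, 3]), key)
  if (anyNA(site)) stop("fold leaves the model's lattice")
  a <- numeric(n_variables(encoded))
  dec <- encoded$decoder
  for (t in seq_len(nrow(f))) {
    row <- dec[dec$role == "site" & dec$bead == t & dec$site == site[t], ]
    if (nrow(row) != 1) stop("bead ", t, " cannot occupy site ", site[t],
                             " (wrong parity class?)")
    a[row$var] <- 1
  }
  a
}

#' Demonstrate the turn-based tetrahedral overlap flaw
#'
#' For sequences such as HPPPPHPPPPH the turn-based tetrahedral model admits
#' self-intersecting folds in its feasible space at the same minimal energy
#' as valid folds: overlaps are only penalised near an active interaction,
#' so "sacrificing" an interaction variable (setting \eqn{q_{ij} = 0}) or
#' overlapping beads that form no eligible pair costs nothing.
#'
#' @param seq sequence (free turns <= `guard`).
#' @param im interaction matrix.
#' @param penalties penalty configuration (tuned defaults).
#' @param guard maximum free turns for the exhaustive search.
#' @return list(energy, n_valid, n_overlapping, example_valid,
#'   example_overlapping, argmin_count) where the examples are minimiser
#'   records (fold, turns, q, valid) or NULL.
#' @export
demonstrate_overlap_flaw <- function(seq, im = hp_interaction(), penalties = NULL,
                                     guard = 9) {
  seq <- as_protein_sequence(seq)
  enc <- encode_turn_tetrahedral(seq, im, "dense", penalties)
  res <- turn_space_exact(enc, guard = guard)
  valid <- Filter(function(m) m$valid, res$minimizers)
  bad <- Filter(function(m) !m$valid, res$minimizers)
  structure(list(energy = res$energy,
                 n_valid = length(valid), n_overlapping = length(bad),
                 example_valid = if (length(valid)) valid[[1]] else NULL,
                 example_overlapping = if (length(bad)) bad[[1]] else NULL,
                 argmin_count = res$argmin_count),
            class = "overlap_flaw_report")
}

#' @export
print.overlap_flaw_report <- function(x, ...) {
  cat(sprintf(paste0("<overlap_flaw_report> minimal energy %g: %d valid and %d ",
                     "self-intersecting minimisers kept (of %g total)\n"),
              x$energy, x$n_valid, x$n_overlapping, x$argmin_count))
  invisible(x)
}
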