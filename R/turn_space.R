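# Exhaustive search over the conformation (turn) space of a turn-based
# encoded model, with interaction and slack variables set to their
# conditionally optimal values.  This is the feasible-space oracle for the
# turn encodings: code-validity and one-hot penalties are at their minimum
# by construction, every interaction variable is 1 iff its bracket is
# negative, and every overlap slack register is at its optimum.

decode_turns_to_fold <- function(dirs, kind) {
  n <- length(dirs) + 1
  dtab <- turn_dirs(kind)
  coords <- matrix(0L, n, 3)
  for (k in seq_len(n - 1)) {
    s <- if (kind == "diamond" && k %% 2 == 0) -1L else 1L
    coords[k + 1, ] <- coords[k, ] + s * dtab[dirs[k], ]
  }
  fold(coords, kind)
}

# squared turn-count distance for a block of assignments
chunk_distance <- function(dirs, kind, i, j, ndir) {
  m <- nrow(dirs)
  xa <- matrix(0, m, if (kind == "diamond") 4 else 6)
  # per-axis signed sums; for cartesian, sum direction vectors directly
  if (kind == "diamond") {
    for (k in i:(j - 1)) {
      s <- if (k %% 2 == 0) -1 else 1
      idx <- cbind(seq_len(m), dirs[, k])
      xa[idx] <- xa[idx] + s
    }
    return(rowSums(xa^2))
  }
  dtab <- turn_dirs("cartesian")
  pos <- matrix(0, m, 3)
  for (k in i:(j - 1)) pos <- pos + dtab[dirs[, k], , drop = FALSE]
  rowSums(pos^2)
}

#' Exhaustive minimisation over the turn space of a turn-based model
#'
#' Enumerates every assignment of the free turns, sets each interaction
#' variable to its conditionally optimal value (1 iff its bracket is
#' negative) and each overlap slack register to its optimum, and returns the
#' exact feasible-space minimum together with all minimising folds.
#'
#' @param encoded a turn-based `encoded_model`.
#' @param guard refuse models with more free turns than this.
#' @param keep maximum number of minimisers returned.
#' @param chunk assignments processed per block.
#' @return list(energy, minimizers = list of list(fold, turns, q, valid),
#'   argmin_count).
#' @export
turn_space_exact <- function(encoded, guard = 9, keep = 200, chunk = 65536) {
  stopifnot(inherits(encoded, "encoded_model"))
  if (!encoded$model_kind %in% c("turn_cartesian", "turn_tetrahedral")) {
    stop("turn_space_exact needs a turn-based model")
  }
  kind <- if (encoded$model_kind == "turn_cartesian") "cartesian" else "diamond"
  seq <- as_protein_sequence(encoded$sequence)
  n <- seq_length(seq)
  nturn <- n - 1
  ndir <- if (kind == "cartesian") 6L else 4L
  fixed <- encoded$fixed_dirs
  n_free <- nturn - length(fixed)
  if (n_free > guard) stop(n_free, " free turns exceed the guard (", guard, ")")
  pen <- encoded$penalties
  min_sep <- if (kind == "cartesian") 3 else 5
  ep <- eligible_pairs(seq, encoded$im, min_sep)
  total <- ndir^max(n_free, 0)

  best <- Inf
  argmin_count <- 0
  kept <- list()

  eval_chunk <- function(ids) {  # ids: 0-based assignment indices
    m <- length(ids)
    dirs <- matrix(0L, m, nturn)
    for (k in seq_along(fixed)) dirs[, k] <- fixed[k]
    r <- ids
    for (f in seq_len(n_free)) {
      dirs[, length(fixed) + f] <- (r %% ndir) + 1L
      r <- r %/% ndir
    }
    e <- numeric(m)
    if (kind == "diamond" && nturn >= 2) {
      for (k in seq_len(nturn - 1)) {
        e <- e + pen$lambda_bt * (dirs[, k] == dirs[, k + 1])
      }
    }
    if (kind == "cartesian" && n >= 3) {
      for (jj in seq_len(n - 2)) {
        for (kk in seq(jj + 2, n)) {
          if ((kk - jj) %% 2 != 0) next
          d <- chunk_distance(dirs, kind, jj, kk, ndir)
          e <- e + pen$lambda1 * (d == 0)
        }
      }
    }
    qmat <- NULL
    if (nrow(ep)) {
      qmat <- matrix(0L, m, nrow(ep))
      for (rr in seq_len(nrow(ep))) {
        i <- ep$i[rr]; j <- ep$j[rr]
        bracket <- ep$eps[rr] +
          pen$lambda1 * (chunk_distance(dirs, kind, i, j, ndir) - 1)
        if (kind == "diamond") {
          for (r2 in intersect(c(j - 1, j + 1), seq_len(n))) {
            bracket <- bracket + pen$lambda2 *
              (2 - chunk_distance(dirs, kind, min(i, r2), max(i, r2), ndir))
          }
          for (m2 in intersect(c(i - 1, i + 1), seq_len(n))) {
            bracket <- bracket + pen$lambda2 *
              (2 - chunk_distance(dirs, kind, min(m2, j), max(m2, j), ndir))
          }
        }
        on <- bracket < 0
        qmat[, rr] <- as.integer(on)
        e <- e + ifelse(on, bracket, 0)
      }
    }
    list(dirs = dirs, e = e, q = qmat)
  }

  done <- 0
  while (done < total) {
    ids <- seq(done, min(done + chunk, total) - 1)
    res <- eval_chunk(ids)
    done <- done + length(ids)
    mn <- min(res$e)
    if (mn < best - 1e-9) {
      best <- mn
      argmin_count <- 0
      kept <- list()
    }
    hits <- which(res$e < best + 1e-9)
    argmin_count <- argmin_count + length(hits)
    for (h in hits) {
      if (length(kept) >= keep) break
      f <- decode_turns_to_fold(res$dirs[h, ], kind)
      q <- if (!is.null(res$q)) {
        setNames(res$q[h, ], sprintf("q%d.%d", ep$i, ep$j))
      } else setNames(integer(0), character(0))
      kept[[length(kept) + 1]] <- list(fold = f, turns = res$dirs[h, ],
                                       q = q, valid = fold_valid(f))
    }
  }
  list(energy = best, minimizers = kept, argmin_count = argmin_count)
}
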