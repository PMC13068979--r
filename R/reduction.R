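#' Rosenberg penalty gadget
#'
#' The quadratic penalty \eqn{\alpha(b_2 b_3 - 2 b_4 (b_2 + b_3) + 3 b_4)}
#' that enforces the ancilla identity \eqn{b_4 = b_2 b_3}: it is 0 whenever
#' the identity holds and at least \eqn{\alpha} otherwise.
#'
#' @param pair integer vector of the two parent variable indices.
#' @param ancilla index of the ancilla variable.
#' @param alpha penalty strength (> 0).
#' @param labels variable labels for the returned polynomial (defaults to
#'   `b1..bk` up to the largest index used).
#' @return A `binary_polynomial`.
#' @examples
#' p <- rosenberg_penalty(c(2L, 3L), 4L, 1)
#' evaluate_energy(p, c(0, 1, 1, 0))  # violated: 1
#' @export
rosenberg_penalty <- function(pair, ancilla, alpha, labels = NULL) {
  if (alpha <= 0) stop("alpha must be strictly positive")
  pair <- as.integer(pair)
  ancilla <- as.integer(ancilla)
  stopifnot(length(pair) == 2, length(ancilla) == 1, !ancilla %in% pair)
  if (is.null(labels)) labels <- paste0("b", seq_len(max(pair, ancilla)))
  binary_polynomial(labels,
                    list(pair, c(ancilla, pair[1]), c(ancilla, pair[2]), ancilla),
                    alpha * c(1, -2, -2, 3))
}

#' Worst-case Rosenberg penalty strength
#'
#' \eqn{\alpha = 1 + \sum |c|} over all non-constant coefficients of the
#' objective: violating any ancilla identity then always costs more than any
#' objective-term gain, so the reduced model's energy landscape is conserved.
#'
#' @param poly a `binary_polynomial` (or `encoded_model`).
#' @return The penalty strength.
#' @export
worst_case_alpha <- function(poly) {
  if (inherits(poly, "encoded_model")) poly <- poly$poly
  stopifnot(inherits(poly, "binary_polynomial"))
  1 + sum(abs(poly$coeffs))
}

#' Reduce a HUBO to a QUBO by iterated Rosenberg substitution
#'
#' Repeatedly substitutes a variable pair by an ancilla until every monomial
#' has degree at most 2.  The pair occurring in the most monomials of degree
#' >= 3 is substituted first (ties broken by lowest variable indices); each
#' pair is substituted at most once across all monomials.  Exactness: for
#' every assignment of the original variables, the minimum of the reduced
#' energy over the ancilla variables equals the original energy.
#'
#' @param poly a `binary_polynomial` (or `encoded_model`, whose polynomial is
#'   reduced).
#' @param alpha penalty strength, or `"auto"` for the worst-case
#'   [worst_case_alpha()] of the input.
#' @return list(model = `quadratic_model`, record = `reduction_record` with
#'   the ancilla parent table, alpha and the degree bookkeeping).
#' @export
reduce_to_quadratic <- function(poly, alpha = "auto") {
  if (inherits(poly, "encoded_model")) poly <- poly$poly
  stopifnot(inherits(poly, "binary_polynomial"))
  if (identical(alpha, "auto")) alpha <- worst_case_alpha(poly)
  if (alpha <= 0) stop("alpha must be strictly positive")
  original_degree <- bp_degree(poly)

  labels <- poly$labels
  vars <- poly$vars
  coeffs <- poly$coeffs
  offset <- poly$offset
  anc <- data.frame(ancilla = character(), ancilla_index = integer(),
                    parent1 = integer(), parent2 = integer())
  penalty_vars <- list(); penalty_coeffs <- numeric()

  repeat {
    deg <- lengths(vars)
    high <- which(deg >= 3)
    if (!length(high)) break
    # frequency of each unordered pair among high-degree monomials
    counts <- new.env(parent = emptyenv())
    for (t in high) {
      v <- vars[[t]]
      for (a in seq_len(length(v) - 1)) {
        for (b in seq(a + 1, length(v))) {
          key <- paste(v[a], v[b])
          counts[[key]] <- (counts[[key]] %||% 0L) + 1L
        }
      }
    }
    keys <- ls(counts)
    freq <- vapply(keys, function(k) counts[[k]], integer(1))
    ij <- do.call(rbind, lapply(strsplit(keys, " "), as.integer))
    best <- which(freq == max(freq))
    best <- best[order(ij[best, 1], ij[best, 2])][1]
    p1 <- ij[best, 1]; p2 <- ij[best, 2]

    new_idx <- length(labels) + 1L
    lab <- sprintf("anc%d.%d", p1, p2)
    labels <- c(labels, lab)
    anc <- rbind(anc, data.frame(ancilla = lab, ancilla_index = new_idx,
                                 parent1 = p1, parent2 = p2))
    for (t in high) {
      v <- vars[[t]]
      if (p1 %in% v && p2 %in% v) vars[[t]] <- sort(c(setdiff(v, c(p1, p2)), new_idx))
    }
    penalty_vars <- c(penalty_vars,
                      list(c(p1, p2), c(new_idx, p1), c(new_idx, p2), new_idx))
    penalty_coeffs <- c(penalty_coeffs, alpha * c(1, -2, -2, 3))
  }

  reduced <- binary_polynomial(labels, c(vars, penalty_vars),
                               c(coeffs, penalty_coeffs), offset)
  record <- structure(list(ancillas = anc, alpha = alpha,
                           original_degree = original_degree,
                           final_degree = bp_degree(reduced),
                           original_labels = poly$labels),
                      class = "reduction_record")
  list(model = as_quadratic_model(reduced), record = record)
}

#' @export
print.reduction_record <- function(x, ...) {
  cat(sprintf("<reduction_record> degree %d -> %d, %d ancillas, alpha = %g\n",
              x$original_degree, x$final_degree, nrow(x$ancillas), x$alpha))
  invisible(x)
}
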