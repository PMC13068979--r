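#' Multilinear Boolean polynomial (HUBO objective)
#'
#' A `binary_polynomial` stores a multilinear objective over Boolean
#' variables \eqn{b_i \in \{0,1\}}: a sum of monomials (subsets of variable
#' indices) with real coefficients plus a constant offset.  Multilinearity
#' (\eqn{b^2 = b}) is applied on construction: repeated indices inside a
#' monomial are collapsed and duplicate monomials are merged.
#'
#' @param labels character vector of variable labels (defines variable count
#'   and order).
#' @param vars list of integer vectors; each entry is one monomial given as
#'   1-based variable indices.  Empty vectors contribute to the offset.
#' @param coeffs numeric coefficients, one per monomial.
#' @param offset constant term.
#' @return An object of class `binary_polynomial` with fields `labels`,
#'   `vars` (list of sorted unique index vectors), `coeffs` and `offset`.
#' @examples
#' p <- binary_polynomial(c("a", "b"), list(1L, c(1L, 2L)), c(1, -2))
#' evaluate_energy(p, c(1, 1))
#' @export
binary_polynomial <- function(labels, vars = list(), coeffs = numeric(), offset = 0) {
  stopifnot(is.character(labels), length(vars) == length(coeffs))
  if (anyDuplicated(labels)) stop("variable labels must be unique")
  n <- length(labels)
  if (length(vars)) {
    bad <- vapply(vars, function(v) length(v) && (min(v) < 1 || max(v) > n), logical(1))
    if (any(bad)) stop("monomial indices out of range")
    col <- cpp_poly_collapse(lapply(vars, as.integer), as.numeric(coeffs))
    vars <- col$vars
    coeffs <- col$coeffs
    empty <- lengths(vars) == 0
    if (any(empty)) {
      offset <- offset + sum(coeffs[empty])
      vars <- vars[!empty]
      coeffs <- coeffs[!empty]
    }
  }
  structure(list(labels = labels, vars = vars, coeffs = as.numeric(coeffs),
                 offset = offset),
            class = "binary_polynomial")
}

#' @export
print.binary_polynomial <- function(x, ...) {
  cat(sprintf("<binary_polynomial> %d variables, %d terms, degree %d, offset %g\n",
              n_variables(x), length(x$coeffs), bp_degree(x), x$offset))
  invisible(x)
}

#' Degree and variable count of a binary model
#'
#' `bp_degree()` returns the maximum monomial size (the locality of the
#' objective); `n_variables()` the number of registered variables.
#'
#' @param x a `binary_polynomial`, `quadratic_model`, `ising_model` or
#'   `encoded_model`.
#' @return An integer.
#' @export
bp_degree <- function(x) {
  if (inherits(x, "encoded_model")) x <- x$poly
  if (inherits(x, "quadratic_model") || inherits(x, "ising_model")) {
    has2 <- length(x[["qv"]] %||% x[["jv"]]) > 0
    return(if (has2) 2L else if (any(x[["linear"]] %||% x[["h"]] != 0)) 1L else 0L)
  }
  if (!length(x$vars)) return(0L)
  max(lengths(x$vars))
}

#' @rdname bp_degree
#' @export
n_variables <- function(x) {
  if (inherits(x, "encoded_model")) x <- x$poly
  length(x$labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a binary or spin model on one assignment
#'
#' @param x a `binary_polynomial`, `quadratic_model` (Boolean domain) or
#'   `ising_model` (spin domain).
#' @param assignment numeric vector covering all variables, in label order
#'   (or named by label).  Values must be 0/1 for Boolean models and -1/+1
#'   for Ising models.
#' @return The exact energy including the stored offset.
#' @export
evaluate_energy <- function(x, assignment) {
  UseMethod("evaluate_energy")
}

check_assignment <- function(x, assignment, domain) {
  n <- n_variables(x)
  if (!is.null(names(assignment))) {
    miss <- setdiff(x$labels, names(assignment))
    if (length(miss)) stop("assignment missing variables: ", paste(head(miss, 5), collapse = ", "))
    assignment <- assignment[x$labels]
  }
  if (length(assignment) != n) stop("assignment must cover all ", n, " variables")
  if (!all(assignment %in% domain)) {
    stop("assignment values must be in {", paste(domain, collapse = ","), "}")
  }
  as.numeric(assignment)
}

#' @export
evaluate_energy.binary_polynomial <- function(x, assignment) {
  a <- check_assignment(x, assignment, c(0, 1))
  if (!length(x$coeffs)) return(x$offset)
  x$offset + sum(x$coeffs * vapply(x$vars, function(v) prod(a[v]), numeric(1)))
}

#' @export
evaluate_energy.quadratic_model <- function(x, assignment) {
  a <- check_assignment(x, assignment, c(0, 1))
  x$offset + sum(x$linear * a) + sum(x$qv * a[x$qi] * a[x$qj])
}

#' @export
evaluate_energy.ising_model <- function(x, assignment) {
  s <- check_assignment(x, assignment, c(-1, 1))
  x$offset + sum(x$h * s) + sum(x$jv * s[x$ji] * s[x$jj])
}

#' @export
evaluate_energy.encoded_model <- function(x, assignment) {
  evaluate_energy(x$poly, assignment)
}

#' Linear combinations of binary polynomials
#'
#' @param p,q binary polynomials over the same variable registry.
#' @param a scalar.
#' @return A `binary_polynomial`.
#' @export
bp_add <- function(p, q) {
  stopifnot(identical(p$labels, q$labels))
  binary_polynomial(p$labels, c(p$vars, q$vars), c(p$coeffs, q$coeffs),
                    p$offset + q$offset)
}

#' @rdname bp_add
#' @export
bp_scale <- function(p, a) {
  binary_polynomial(p$labels, p$vars, p$coeffs * a, p$offset * a)
}

#' Quadratic Boolean model (QUBO)
#'
#' Degree-at-most-2 specialisation with energy
#' \eqn{E(b) = \sum_i h_i b_i + \sum_{i<j} Q_{ij} b_i b_j + c}.
#'
#' @param labels variable labels.
#' @param linear length-n vector of linear coefficients (QUBO diagonal).
#' @param qi,qj,qv parallel vectors describing the strictly-upper-triangular
#'   quadratic coefficients (`qi < qj`).
#' @param offset constant.
#' @return An object of class `quadratic_model`.
#' @export
quadratic_model <- function(labels, linear = numeric(length(labels)),
                            qi = integer(), qj = integer(), qv = numeric(),
                            offset = 0) {
  n <- length(labels)
  stopifnot(length(linear) == n, length(qi) == length(qj), length(qj) == length(qv))
  if (length(qi)) {
    swap <- qi > qj
    if (any(swap)) { tmp <- qi[swap]; qi[swap] <- qj[swap]; qj[swap] <- tmp }
    if (any(qi == qj)) stop("diagonal entries belong in `linear`")
    key <- paste(qi, qj)
    if (anyDuplicated(key)) {
      agg <- rowsum(qv, key)
      ij <- do.call(rbind, strsplit(rownames(agg), " "))
      qi <- as.integer(ij[, 1]); qj <- as.integer(ij[, 2]); qv <- as.numeric(agg)
    }
    keepnz <- qv != 0
    qi <- qi[keepnz]; qj <- qj[keepnz]; qv <- qv[keepnz]
    o <- order(qi, qj)
    qi <- qi[o]; qj <- qj[o]; qv <- qv[o]
  }
  structure(list(labels = labels, linear = as.numeric(linear),
                 qi = as.integer(qi), qj = as.integer(qj), qv = as.numeric(qv),
                 offset = offset),
            class = "quadratic_model")
}

#' @export
print.quadratic_model <- function(x, ...) {
  cat(sprintf("<quadratic_model> %d variables, %d couplers, offset %g\n",
              n_variables(x), length(x$qv), x$offset))
  invisible(x)
}

#' Ising spin model
#'
#' Energy \eqn{H(s) = \sum_{i<j} J_{ij} s_i s_j + \sum_i h_i s_i + c} over
#' spins \eqn{s_i \in \{-1,+1\}}.
#'
#' @param labels variable labels.
#' @param h fields.
#' @param ji,jj,jv couplings (upper triangle).
#' @param offset constant.
#' @export
ising_model <- function(labels, h = numeric(length(labels)),
                        ji = integer(), jj = integer(), jv = numeric(), offset = 0) {
  stopifnot(length(h) == length(labels), length(ji) == length(jj),
            length(jj) == length(jv))
  structure(list(labels = labels, h = as.numeric(h), ji = as.integer(ji),
                 jj = as.integer(jj), jv = as.numeric(jv), offset = offset),
            class = "ising_model")
}

#' @export
print.ising_model <- function(x, ...) {
  cat(sprintf("<ising_model> %d spins, %d couplings, offset %g\n",
              n_variables(x), length(x$jv), x$offset))
  invisible(x)
}

#' Convert a binary polynomial of degree at most 2 to a quadratic model
#'
#' @param x a `binary_polynomial` (or `encoded_model`).
#' @return A `quadratic_model` with identical energies on all states.
#' @export
as_quadratic_model <- function(x) {
  if (inherits(x, "encoded_model")) x <- x$poly
  if (inherits(x, "quadratic_model")) return(x)
  stopifnot(inherits(x, "binary_polynomial"))
  if (bp_degree(x) > 2) stop("degree > 2; reduce with reduce_to_quadratic()")
  n <- n_variables(x)
  linear <- numeric(n)
  deg <- lengths(x$vars)
  for (k in which(deg == 1)) linear[x$vars[[k]]] <- linear[x$vars[[k]]] + x$coeffs[k]
  i2 <- which(deg == 2)
  qi <- vapply(x$vars[i2], `[`, integer(1), 1L)
  qj <- vapply(x$vars[i2], `[`, integer(1), 2L)
  quadratic_model(x$labels, linear, qi, qj, x$coeffs[i2], x$offset)
}

#' @rdname as_quadratic_model
#' @export
as_binary_polynomial <- function(x) {
  if (inherits(x, "binary_polynomial")) return(x)
  if (inherits(x, "encoded_model")) return(x$poly)
  stopifnot(inherits(x, "quadratic_model"))
  vars <- c(as.list(which(x$linear != 0)), mapply(c, x$qi, x$qj, SIMPLIFY = FALSE))
  coeffs <- c(x$linear[x$linear != 0], x$qv)
  binary_polynomial(x$labels, vars, coeffs, x$offset)
}

#' Boolean/spin transformations between QUBO and Ising form
#'
#' Uses the linear substitution \eqn{b_i = (1 + s_i)/2}; energies of
#' corresponding states agree exactly (offsets included), so the two forms
#' order all states identically.
#'
#' @param x a `quadratic_model` (for `qubo_to_ising`) or an `ising_model`
#'   (for `ising_to_qubo`).
#' @return The transformed model.
#' @export
qubo_to_ising <- function(x) {
  x <- as_quadratic_model(x)
  n <- n_variables(x)
  h <- x$linear / 2
  jv <- x$qv / 4
  for (k in seq_along(x$qv)) {
    h[x$qi[k]] <- h[x$qi[k]] + x$qv[k] / 4
    h[x$qj[k]] <- h[x$qj[k]] + x$qv[k] / 4
  }
  offset <- x$offset + sum(x$linear) / 2 + sum(x$qv) / 4
  ising_model(x$labels, h, x$qi, x$qj, jv, offset)
}

#' @rdname qubo_to_ising
#' @export
ising_to_qubo <- function(x) {
  stopifnot(inherits(x, "ising_model"))
  linear <- 2 * x$h
  for (k in seq_along(x$jv)) {
    linear[x$ji[k]] <- linear[x$ji[k]] - 2 * x$jv[k]
    linear[x$jj[k]] <- linear[x$jj[k]] - 2 * x$jv[k]
  }
  offset <- x$offset - sum(x$h) + sum(x$jv)
  quadratic_model(x$labels, linear, x$ji, x$jj, 4 * x$jv, offset)
}

#' Convert a Boolean 0/1 state to the corresponding spin state and back
#'
#' @param b 0/1 vector; `s` a -1/+1 vector.
#' @export
boolean_to_spin <- function(b) 2 * as.numeric(b) - 1

#' @rdname boolean_to_spin
#' @param s spin vector.
#' @export
spin_to_boolean <- function(s) (as.numeric(s) + 1) / 2
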