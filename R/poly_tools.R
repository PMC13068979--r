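# Internal polynomial-building machinery shared by the encoders.
#
# A "small poly" (sp) is list(vars = list of 1-based index vectors, possibly
# empty for the constant term, coeffs = numeric).  An accumulator (acc) is an
# environment collecting terms of a growing model: variable registry plus a
# hashed term map keyed by the monomial index string.

sp_const <- function(c) list(vars = list(integer(0)), coeffs = c)

sp_var <- function(i) list(vars = list(as.integer(i)), coeffs = 1)

sp_combine <- function(...) {
  ps <- list(...)
  list(vars = do.call(c, lapply(ps, `[[`, "vars")),
       coeffs = do.call(c, lapply(ps, `[[`, "coeffs")))
}

sp_scale <- function(p, a) {
  p$coeffs <- p$coeffs * a
  p
}

sp_add <- function(...) {
  p <- sp_combine(...)
  cpp_poly_collapse(p$vars, p$coeffs)
}

sp_mul <- function(p, q) {
  cpp_poly_mul(p$vars, p$coeffs, q$vars, q$coeffs)
}

sp_square <- function(p) sp_mul(p, p)

# sum_k of polys in a list
sp_sum <- function(ps) {
  if (!length(ps)) return(sp_const(0))
  do.call(sp_add, ps)
}

acc_new <- function() {
  acc <- new.env(parent = emptyenv())
  acc$labels <- character()
  acc$index <- new.env(parent = emptyenv())
  acc$terms <- new.env(parent = emptyenv())
  acc$offset <- 0
  acc
}

acc_var <- function(acc, label) {
  idx <- acc$index[[label]]
  if (is.null(idx)) {
    idx <- length(acc$labels) + 1L
    acc$labels <- c(acc$labels, label)
    acc$index[[label]] <- idx
  }
  idx
}

acc_add_term <- function(acc, vars, coeff) {
  if (coeff == 0) return(invisible(NULL))
  vars <- unique(sort(as.integer(vars)))
  if (!length(vars)) {
    acc$offset <- acc$offset + coeff
    return(invisible(NULL))
  }
  key <- paste(vars, collapse = " ")
  cur <- acc$terms[[key]]
  acc$terms[[key]] <- if (is.null(cur)) list(vars, coeff) else list(vars, cur[[2]] + coeff)
  invisible(NULL)
}

acc_add_sp <- function(acc, p, scale = 1) {
  for (k in seq_along(p$coeffs)) acc_add_term(acc, p$vars[[k]], scale * p$coeffs[k])
  invisible(NULL)
}

acc_finalize <- function(acc) {
  keys <- ls(acc$terms)
  vars <- vector("list", length(keys))
  coeffs <- numeric(length(keys))
  for (k in seq_along(keys)) {
    t <- acc$terms[[keys[k]]]
    vars[[k]] <- t[[1]]
    coeffs[k] <- t[[2]]
  }
  keep <- abs(coeffs) > 1e-12
  binary_polynomial(acc$labels, vars[keep], coeffs[keep], acc$offset)
}
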