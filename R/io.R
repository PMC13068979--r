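# JSON / COO serialisation of models, sample sets and SOD histograms.

poly_to_list <- function(p) {
  list(variables = p$labels,
       terms = lapply(seq_along(p$coeffs), function(k) {
         list(vars = p$vars[[k]], coeff = p$coeffs[k])
       }),
       offset = p$offset)
}

poly_from_list <- function(x) {
  vars <- lapply(x$terms, function(t) as.integer(unlist(t$vars)))
  coeffs <- vapply(x$terms, function(t) as.numeric(t$coeff), numeric(1))
  binary_polynomial(unlist(x$variables), vars, coeffs, as.numeric(x$offset))
}

#' Serialize models to and from JSON
#'
#' Binary polynomials serialise as `{variables, terms: [{vars, coeff}],
#' offset}`; encoded models add a decoder block (model kind, flavor, lattice,
#' variable roles, penalties); reduction records can be embedded so decoders
#' can strip ancillas.
#'
#' @param model a `binary_polynomial`, `quadratic_model` or `encoded_model`.
#' @param path JSON file.
#' @param reduction optional `reduction_record` stored alongside.
#' @export
write_model_json <- function(model, path, reduction = NULL) {
  if (inherits(model, "quadratic_model")) model <- as_binary_polynomial(model)
  out <- if (inherits(model, "encoded_model")) {
    list(type = "encoded_model", poly = poly_to_list(model$poly),
         decoder = list(model_kind = model$model_kind, flavor = model$flavor,
                        lattice = if (is.null(model$lattice)) NULL else
                          list(kind = model$lattice$kind,
                               extents = model$lattice$extents),
                        sequence = model$sequence, alphabet = model$alphabet,
                        eps = list(alphabet = model$im$alphabet,
                                   matrix = unname(model$im$eps)),
                        penalties = unclass(model$penalties),
                        fixed_dirs = model$fixed_dirs,
                        var_roles = model$decoder))
  } else {
    list(type = "binary_polynomial", poly = poly_to_list(model))
  }
  if (!is.null(reduction)) {
    out$reduction <- list(ancillas = reduction$ancillas, alpha = reduction$alpha,
                          original_degree = reduction$original_degree,
                          final_degree = reduction$final_degree,
                          original_labels = reduction$original_labels)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @return `read_model_json()`: the model (plus a `reduction` attribute if one
#'   was stored).
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path)
  poly <- poly_from_list(x$poly)
  model <- if (identical(x$type, "encoded_model")) {
    d <- x$decoder
    vr <- do.call(rbind, lapply(x$decoder$var_roles, function(r) {
      data.frame(var = as.integer(r$var), role = as.character(r$role),
                 bead = as.integer(r$bead %||% NA), site = as.integer(r$site %||% NA),
                 turn = as.integer(r$turn %||% NA), bit = as.integer(r$bit %||% NA),
                 i = as.integer(r$i %||% NA), j = as.integer(r$j %||% NA))
    }))
    eps <- matrix(unlist(d$eps$matrix), length(unlist(d$eps$alphabet)),
                  byrow = TRUE)
    dimnames(eps) <- list(unlist(d$eps$alphabet), unlist(d$eps$alphabet))
    lat <- if (is.null(d$lattice)) NULL else
      lattice_spec(d$lattice$kind, unlist(d$lattice$extents))
    pen <- do.call(penalty_config, lapply(d$penalties, as.numeric))
    new_encoded_model(poly, d$model_kind, d$flavor %||% NA_character_, lat,
                      as_protein_sequence(d$sequence), interaction_matrix(eps),
                      pen, vr, as.integer(unlist(d$fixed_dirs)))
  } else poly
  if (!is.null(x$reduction)) {
    anc <- do.call(rbind, lapply(x$reduction$ancillas, function(r) {
      data.frame(ancilla = r$ancilla, ancilla_index = as.integer(r$ancilla_index),
                 parent1 = as.integer(r$parent1), parent2 = as.integer(r$parent2))
    }))
    attr(model, "reduction") <- structure(
      list(ancillas = anc %||% data.frame(), alpha = as.numeric(x$reduction$alpha),
           original_degree = as.integer(x$reduction$original_degree),
           final_degree = as.integer(x$reduction$final_degree),
           original_labels = unlist(x$reduction$original_labels)),
      class = "reduction_record")
  }
  model
}

#' QUBO serialisation as COO text
#'
#' Plain-text triplets `i j value` (1-based), with diagonal entries carrying
#' the linear coefficients; a comment header stores the offset.
#'
#' @param model degree <= 2 model.
#' @param path output file.
#' @export
write_qubo_coo <- function(model, path) {
  qm <- as_quadratic_model(model)
  lines <- c(sprintf("# qubo n=%d offset=%.17g", n_variables(qm), qm$offset))
  nz <- which(qm$linear != 0)
  lines <- c(lines, sprintf("%d %d %.17g", nz, nz, qm$linear[nz]),
             sprintf("%d %d %.17g", qm$qi, qm$qj, qm$qv))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_qubo_coo
#' @export
read_qubo_coo <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  n <- as.integer(sub(".*n=([0-9]+).*", "\\1", hdr))
  offset <- as.numeric(sub(".*offset=([-0-9.eE+]+).*", "\\1", hdr))
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- do.call(rbind, strsplit(body, "\\s+"))
  i <- as.integer(parts[, 1]); j <- as.integer(parts[, 2])
  v <- as.numeric(parts[, 3])
  if (anyNA(i) || anyNA(j) || anyNA(v)) stop("malformed COO line in ", path)
  diag_ <- i == j
  linear <- numeric(n)
  linear[i[diag_]] <- v[diag_]
  quadratic_model(paste0("b", seq_len(n)), linear, i[!diag_], j[!diag_],
                  v[!diag_], offset)
}

#' Serialize sample sets and SOD histograms to JSON
#'
#' @param x a `sample_set` or `overlap_distribution`.
#' @param path output file.
#' @export
write_sampleset_json <- function(x, path) {
  stopifnot(inherits(x, "sample_set"))
  jsonlite::write_json(
    list(labels = x$labels, energies = x$energies,
         assignments = unname(apply(x$assignments, 1, paste, collapse = "")),
         best_energy = x$best_energy, seed = x$seed,
         config = unclass(x$config)),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_sampleset_json
#' @export
read_sampleset_json <- function(path) {
  x <- jsonlite::read_json(path)
  rows <- lapply(x$assignments, function(s) as.integer(strsplit(s, "")[[1]]))
  assignments <- do.call(rbind, rows)
  new_sample_set(assignments, as.numeric(unlist(x$energies)),
                 unlist(x$labels), x$seed, x$config)
}

#' @rdname write_sampleset_json
#' @export
write_sod_json <- function(x, path) {
  stopifnot(inherits(x, "overlap_distribution"))
  jsonlite::write_json(
    list(mids = x$mids, masses = x$masses, bin_width = x$bin_width,
         n_olap = x$n_olap, thermalization = x$thermalization, q = x$q),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
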