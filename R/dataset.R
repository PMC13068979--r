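#' Seeded random benchmark dataset
#'
#' Generates `n_instances` random sequences of length `max_length`, each
#' residue sampled uniformly from the chosen alphabet (the 20 natural amino
#' acids, or H/P), together with the nested prefixes of lengths
#' `min_prefix..max_length` used for scaling analyses.  No post-selection for
#' unique energy minima is performed.  Generation is deterministic given the
#' seed and does not disturb the global RNG state.
#'
#' @param n_instances number of sequences.
#' @param max_length full sequence length.
#' @param alphabet `"AA20"` or `"HP"`.
#' @param seed RNG seed.
#' @param min_prefix shortest prefix emitted.
#' @return A `fold_dataset`: list of records
#'   list(id, sequence, prefixes = character vector).
#' @examples
#' ds <- generate_dataset(3, 10, "HP", seed = 7)
#' ds[[1]]$prefixes
#' @export
generate_dataset <- function(n_instances = 100, max_length = 10,
                             alphabet = c("AA20", "HP"), seed = 1L,
                             min_prefix = 4) {
  alphabet <- match.arg(alphabet)
  if (min_prefix < 2 || min_prefix > max_length) stop("invalid prefix range")
  letters_ <- if (alphabet == "AA20") AA20 else c("H", "P")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  records <- lapply(seq_len(n_instances), function(k) {
    res <- sample(letters_, max_length, replace = TRUE)
    s <- paste(res, collapse = "")
    list(id = sprintf("inst%03d", k), sequence = s,
         prefixes = vapply(min_prefix:max_length,
                           function(l) substr(s, 1, l), character(1)))
  })
  structure(records, class = "fold_dataset",
            spec = list(n_instances = n_instances, max_length = max_length,
                        alphabet = alphabet, seed = seed, min_prefix = min_prefix))
}

#' @export
print.fold_dataset <- function(x, ...) {
  sp <- attr(x, "spec")
  cat(sprintf("<fold_dataset> %d instances of length %d (%s, seed %d)\n",
              sp$n_instances, sp$max_length, sp$alphabet, sp$seed))
  invisible(x)
}

#' Write a dataset as FASTA
#'
#' One record per instance, full-length sequences; prefixes are reproducible
#' from the records.
#'
#' @param ds a `fold_dataset`.
#' @param path output FASTA file.
#' @export
write_dataset_fasta <- function(ds, path) {
  stopifnot(inherits(ds, "fold_dataset"))
  seqs <- Biostrings::AAStringSet(vapply(ds, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(ds, `[[`, character(1), "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
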