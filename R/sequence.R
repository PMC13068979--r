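AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
HYDROPHOBIC <- c("A", "C", "F", "I", "L", "M", "V", "W", "Y")

#' Protein sequences for lattice models
#'
#' Sequences are strings over either the two-letter HP alphabet (H =
#' hydrophobic, P = polar) or the 20-letter amino-acid alphabet.  Lowercase
#' input is normalised to uppercase with a warning.
#'
#' @param x a single string (or anything coercible).
#' @param alphabet `"auto"` (HP if the string uses only H/P, else AA20),
#'   `"HP"` or `"AA20"`.
#' @return A `protein_sequence`: the string with attributes `alphabet` and
#'   `length`.
#' @examples
#' as_protein_sequence("HPPH")
#' @export
as_protein_sequence <- function(x, alphabet = c("auto", "HP", "AA20")) {
  alphabet <- match.arg(alphabet)
  if (inherits(x, "protein_sequence") && alphabet == "auto") return(x)
  x <- as.character(x)
  stopifnot(length(x) == 1)
  if (grepl("[a-z]", x)) {
    warning("lowercase residues normalised to uppercase")
    x <- toupper(x)
  }
  res <- strsplit(x, "")[[1]]
  if (length(res) < 2) stop("invalid sequence: need at least 2 residues")
  hp <- all(res %in% c("H", "P"))
  if (alphabet == "auto") alphabet <- if (hp) "HP" else "AA20"
  allowed <- if (alphabet == "HP") c("H", "P") else AA20
  bad <- setdiff(res, allowed)
  if (length(bad)) {
    stop("invalid residues for ", alphabet, " alphabet: ", paste(bad, collapse = ""))
  }
  structure(x, class = "protein_sequence", alphabet = alphabet,
            length = length(res))
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence> %s (%s, N=%d)\n", unclass(x)[1],
              attr(x, "alphabet"), attr(x, "length")))
  invisible(x)
}

seq_residues <- function(x) strsplit(unclass(as_protein_sequence(x))[1], "")[[1]]

seq_length <- function(x) attr(as_protein_sequence(x), "length")

#' Read a sequence from a FASTA file (first record)
#'
#' @param path FASTA file.
#' @return A `protein_sequence`.
#' @export
read_sequence_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (!length(set)) stop("no FASTA records in ", path)
  as_protein_sequence(as.character(set[[1]]))
}

#' Collapse a 20-letter sequence to the HP alphabet
#'
#' Maps the hydrophobic residues A, C, F, I, L, M, V, W, Y to H and all other
#' amino acids to P.  This mapping is an explicit opt-in; HP-model runs
#' otherwise require native H/P strings.
#'
#' @param x a sequence.
#' @return A `protein_sequence` over the HP alphabet.
#' @export
hp_collapse <- function(x) {
  res <- seq_residues(x)
  as_protein_sequence(paste(ifelse(res %in% HYDROPHOBIC, "H", "P"), collapse = ""),
                      alphabet = "HP")
}

#' Pairwise residue contact-energy matrix
#'
#' A symmetric matrix of dimensionless contact energies \eqn{\epsilon_{ij}}
#' over a residue alphabet.  The HP preset has \eqn{\epsilon(H,H) = -1} and 0
#' otherwise; Miyazawa-Jernigan-style 20x20 matrices can be loaded from CSV
#' (their numeric values are not bundled).
#'
#' @param eps symmetric numeric matrix with residue letters as dimnames.
#' @return An `interaction_matrix`.
#' @export
interaction_matrix <- function(eps) {
  eps <- as.matrix(eps)
  if (is.null(rownames(eps)) || is.null(colnames(eps)) ||
      !identical(rownames(eps), colnames(eps))) {
    stop("interaction matrix needs matching residue-letter dimnames")
  }
  bad <- which(abs(eps - t(eps)) > 1e-12, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("interaction matrix not symmetric at (%s, %s)",
                 rownames(eps)[bad[1, 1]], colnames(eps)[bad[1, 2]]))
  }
  structure(list(alphabet = rownames(eps), eps = eps), class = "interaction_matrix")
}

#' @rdname interaction_matrix
#' @export
hp_interaction <- function() {
  eps <- matrix(0, 2, 2, dimnames = list(c("H", "P"), c("H", "P")))
  eps["H", "H"] <- -1
  interaction_matrix(eps)
}

#' @rdname interaction_matrix
#' @param path CSV file: first row and first column carry residue letters,
#'   body is the symmetric energy matrix.
#' @export
read_interaction_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric entries in interaction matrix ", path)
  colnames(m) <- trimws(colnames(m))
  rownames(m) <- trimws(rownames(m))
  interaction_matrix(m)
}

#' @rdname interaction_matrix
#' @param x an `interaction_matrix`.
#' @export
write_interaction_csv <- function(x, path) {
  stopifnot(inherits(x, "interaction_matrix"))
  write.csv(x$eps, path)
  invisible(path)
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("<interaction_matrix> %d-letter alphabet [%s...]\n",
              length(x$alphabet), paste(head(x$alphabet, 4), collapse = "")))
  invisible(x)
}

# epsilon(a, b) lookup with alphabet check
eps_lookup <- function(im, a, b) {
  stopifnot(inherits(im, "interaction_matrix"))
  if (!all(c(a, b) %in% im$alphabet)) {
    stop("residues outside interaction-matrix alphabet: ",
         paste(setdiff(c(a, b), im$alphabet), collapse = ""))
  }
  im$eps[a, b]
}

# N x N matrix of pair energies for contact-eligible pairs (|i-j| >= 3),
# zero elsewhere; shared by the oracles and the encoders.
pair_energy_matrix <- function(seq, im) {
  res <- seq_residues(seq)
  n <- length(res)
  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) >= 3) p[i, j] <- eps_lookup(im, res[i], res[j])
    }
  }
  p
}
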