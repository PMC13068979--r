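# Shared fixtures and independent mini-oracles (kept deliberately naive and
# separate from the package's C++ paths).

# all 2^n Boolean states as an (2^n x n) matrix, low bit first
all_states <- function(n) {
  unname(as.matrix(expand.grid(rep(list(0:1), n))))
}

# naive recursive SAW counter on the simple-cubic lattice (independent of the
# package's enumerator)
naive_cubic_saw_count <- function(n) {
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  count <- 0L
  recurse <- function(path) {
    if (nrow(path) == n) {
      count <<- count + 1L
      return(invisible())
    }
    last <- path[nrow(path), ]
    for (d in seq_len(6)) {
      nxt <- last + dirs[d, ]
      if (!any(apply(path, 1, function(p) all(p == nxt)))) {
        recurse(rbind(path, nxt))
      }
    }
  }
  recurse(matrix(0, 1, 3))
  count
}

random_hp <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("H", "P"), n, replace = TRUE), collapse = "")
}

random_qubo <- function(n, seed) {
  set.seed(seed)
  qi <- integer(); qj <- integer()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) { qi <- c(qi, i); qj <- c(qj, j) }
  keep <- runif(length(qi)) < 0.6
  quadratic_model(paste0("v", seq_len(n)), linear = round(runif(n, -2, 2), 2),
                  qi = qi[keep], qj = qj[keep],
                  qv = round(runif(sum(keep), -1, 1), 2))
}

random_hubo <- function(n, seed, n_terms = 12, max_deg = 4) {
  set.seed(seed)
  vars <- lapply(seq_len(n_terms), function(k) {
    sort(sample.int(n, sample(1:max_deg, 1)))
  })
  binary_polynomial(paste0("b", seq_len(n)), vars,
                    round(runif(n_terms, -3, 3), 1), offset = round(runif(1), 2))
}

# brute-force check of the Rosenberg exactness contract on every original state
reduction_is_exact <- function(poly, red) {
  n <- n_variables(poly)
  nanc <- nrow(red$record$ancillas)
  sts <- all_states(n)
  ancs <- if (nanc > 0) all_states(nanc) else matrix(0, 1, 0)
  for (r in seq_len(nrow(sts))) {
    orig <- evaluate_energy(poly, sts[r, ])
    vals <- apply(ancs, 1, function(z) {
      evaluate_energy(red$model, unname(c(sts[r, ], z)))
    })
    if (abs(min(vals) - orig) > 1e-9) return(FALSE)
  }
  TRUE
}

# small constructed overlap distribution for classifier tests
fake_sod <- function(masses, mids = NULL) {
  nb <- length(masses)
  if (is.null(mids)) mids <- seq(-1 + 1 / nb, 1 - 1 / nb, length.out = nb)
  if (sum(masses) > 0) masses <- masses / sum(masses)
  structure(list(q = numeric(0), mids = mids, masses = masses,
                 bin_width = 2 / nb, n_olap = 0L, thermalization = 0L),
            class = "overlap_distribution")
}
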