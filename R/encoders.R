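#' Penalty configuration for the lattice-folding encodings
#'
#' All constraint families of the encodings are enforced through positive
#' Lagrange-type penalty weights:
#' \describe{
#'   \item{lambda_onehot, lambda_conn, lambda_selfavoid}{coordinate models:
#'     one-hot site registers, chain connectivity, same-site exclusion.}
#'   \item{lambda1, lambda2}{turn-based tetrahedral interaction bracket:
#'     `lambda1` forces interacting beads to distance 1, `lambda2` forces the
#'     sequence neighbours of an interacting pair to distance 2.}
#'   \item{lambda_bt}{turn models: immediate chain reversal (backtrack).}
#'   \item{lambda_code}{turn-based code validity: the two invalid dense
#'     Cartesian turn codes, and the one-hot constraint of sparse turn
#'     registers.}
#' }
#'
#' @param lambda_onehot,lambda_conn,lambda_selfavoid,lambda1,lambda2,lambda_bt,lambda_code
#'   strictly positive weights.
#' @return A `penalty_config`.
#' @export
penalty_config <- function(lambda_onehot = 2, lambda_conn = 2, lambda_selfavoid = 2,
                           lambda1 = 20, lambda2 = 2, lambda_bt = 20,
                           lambda_code = 20) {
  cfg <- list(lambda_onehot = lambda_onehot, lambda_conn = lambda_conn,
              lambda_selfavoid = lambda_selfavoid, lambda1 = lambda1,
              lambda2 = lambda2, lambda_bt = lambda_bt, lambda_code = lambda_code)
  if (any(unlist(cfg) <= 0)) stop("all penalty weights must be strictly positive")
  structure(cfg, class = "penalty_config")
}

# contact-eligible residue pairs: |i-j| >= min_sep, odd separation (bipartite
# lattices), non-zero pair energy.  Returns data.frame(i, j, eps).
eligible_pairs <- function(seq, im, min_sep = 3) {
  res <- seq_residues(seq)
  n <- length(res)
  out <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i && (j - i) >= min_sep && (j - i) %% 2 == 1) {
        e <- eps_lookup(im, res[i], res[j])
        if (e != 0) out[[length(out) + 1]] <- data.frame(i = i, j = j, eps = e)
      }
    }
  }
  if (!length(out)) return(data.frame(i = integer(), j = integer(), eps = numeric()))
  do.call(rbind, out)
}

#' Default penalty weights
#'
#' `worst_case` sets the base weight to \eqn{1 + \sum |\epsilon|} over the
#' contact-eligible residue pairs (the worst-case bound that provably keeps
#' every constraint violation unprofitable); `tuned` uses the milder
#' \eqn{1 + \max|\epsilon|}.  In both modes the distance-1 constraint of the
#' turn-based tetrahedral interaction bracket, the backtrack penalty and the
#' code-validity penalty are an order of magnitude stronger
#' (`lambda1 = lambda_bt = lambda_code = 10 x` base): with equal weights the
#' bracket's distance-2 guard terms can reward stretched geometries more than
#' the distance-1 violation costs (see the methods vignette for the bound).
#'
#' @param seq sequence.
#' @param im interaction matrix.
#' @param mode `"tuned"` or `"worst_case"`.
#' @return A `penalty_config`.
#' @export
default_penalties <- function(seq, im = hp_interaction(),
                              mode = c("tuned", "worst_case")) {
  mode <- match.arg(mode)
  base <- if (mode == "worst_case") {
    1 + sum(abs(eligible_pairs(seq, im, 3)$eps))
  } else {
    1 + max(abs(im$eps))
  }
  penalty_config(lambda_onehot = base, lambda_conn = base, lambda_selfavoid = base,
                 lambda1 = 10 * base, lambda2 = base, lambda_bt = 10 * base,
                 lambda_code = 10 * base)
}

new_encoded_model <- function(poly, model_kind, flavor, lattice, seq, im,
                              penalties, decoder, fixed_dirs = integer()) {
  structure(list(poly = poly, model_kind = model_kind, flavor = flavor,
                 lattice = lattice, sequence = unclass(seq)[1],
                 alphabet = attr(seq, "alphabet"), im = im,
                 penalties = penalties, decoder = decoder,
                 fixed_dirs = fixed_dirs),
            class = "encoded_model")
}

#' @export
print.encoded_model <- function(x, ...) {
  cat(sprintf("<encoded_model> %s%s, N=%d, %d variables, degree %d\n",
              x$model_kind,
              if (is.na(x$flavor)) "" else paste0(" (", x$flavor, ")"),
              nchar(x$sequence), n_variables(x), bp_degree(x)))
  invisible(x)
}

#' Coordinate-based encoding (cubic or tetrahedral lattice)
#'
#' One one-hot register per bead over the sites of the bead's parity class
#' (bead t lives on parity (t-1) mod 2; on the diamond lattice the classes
#' are the two FCC sublattices).  The objective is natively quadratic:
#' one-hot penalties \eqn{\lambda_{oh}(\sum_f x_{t,f} - 1)^2}, connectivity
#' penalties on non-adjacent consecutive placements, same-site exclusion for
#' same-parity beads, and contact terms \eqn{\epsilon(a_i,a_j) x_{i,f} x_{j,g}}
#' over adjacent site pairs for eligible residue pairs (odd separation >= 3).
#'
#' @param seq sequence.
#' @param lattice a `lattice_spec` or built `lattice`; each parity class must
#'   hold at least ceiling(N/2) beads.
#' @param im interaction matrix.
#' @param penalties a `penalty_config` (default: tuned weights).
#' @param anchor if TRUE, bead 1's register is restricted to its first
#'   admissible site, cutting translational degeneracy (changes the variable
#'   count).
#' @return An `encoded_model` with a degree-2 `binary_polynomial`.
#' @export
encode_coordinate <- function(seq, lattice, im = hp_interaction(),
                              penalties = NULL, anchor = FALSE) {
  seq <- as_protein_sequence(seq)
  if (inherits(lattice, "lattice_spec")) lattice <- build_lattice(lattice)
  stopifnot(inherits(lattice, "lattice"))
  if (is.null(penalties)) penalties <- default_penalties(seq, im, "tuned")
  n <- seq_length(seq)
  class_sites <- list(which(lattice$parity == 0L), which(lattice$parity == 1L))
  need <- c(ceiling(n / 2), floor(n / 2))
  if (length(class_sites[[1]]) < need[1] || length(class_sites[[2]]) < need[2]) {
    stop("lattice too small: parity classes of ",
         length(class_sites[[1]]), "/", length(class_sites[[2]]),
         " sites cannot host ", n, " beads")
  }
  bead_class <- ((seq_len(n) - 1) %% 2) + 1
  bead_sites <- lapply(seq_len(n), function(t) {
    s <- class_sites[[bead_class[t]]]
    if (anchor && t == 1) s[1] else s
  })

  labels <- character(0)
  var_of <- vector("list", n)  # per bead: named map site -> var index
  dec <- list()
  for (t in seq_len(n)) {
    s <- bead_sites[[t]]
    idx <- length(labels) + seq_along(s)
    labels <- c(labels, sprintf("b%d.s%d", t, s))
    v <- rep(NA_integer_, nrow(lattice$coords))
    v[s] <- idx
    var_of[[t]] <- v
    dec[[t]] <- data.frame(var = idx, role = "site", bead = t, site = s)
  }

  vars <- list()
  coeffs <- numeric()
  offset <- 0
  push <- function(v, c) {
    vars[[length(vars) + 1]] <<- as.integer(v)
    coeffs[[length(coeffs) + 1]] <<- c
  }

  # one-hot: lambda * (sum x - 1)^2 = lambda * (1 - sum x + 2 sum_{f<g} x_f x_g)
  loh <- penalties$lambda_onehot
  for (t in seq_len(n)) {
    ix <- var_of[[t]][bead_sites[[t]]]
    offset <- offset + loh
    for (a in ix) push(a, -loh)
    if (length(ix) > 1) {
      for (u in seq_len(length(ix) - 1)) {
        for (w in (u + 1):length(ix)) push(c(ix[u], ix[w]), 2 * loh)
      }
    }
  }

  # connectivity: penalise consecutive beads on non-adjacent site pairs
  is_adj <- matrix(FALSE, nrow(lattice$coords), nrow(lattice$coords))
  for (f in seq_len(nrow(lattice$coords))) is_adj[f, lattice$adj[[f]]] <- TRUE
  for (t in seq_len(n - 1)) {
    for (f in bead_sites[[t]]) {
      for (g in bead_sites[[t + 1]]) {
        if (!is_adj[f, g]) push(c(var_of[[t]][f], var_of[[t + 1]][g]),
                                penalties$lambda_conn)
      }
    }
  }

  # self-avoidance: same-parity beads may not share a site
  for (t in seq_len(n - 1)) {
    for (u in seq(t + 1, n)) {
      if (bead_class[t] != bead_class[u]) next
      common <- intersect(bead_sites[[t]], bead_sites[[u]])
      for (f in common) push(c(var_of[[t]][f], var_of[[u]][f]),
                             penalties$lambda_selfavoid)
    }
  }

  # contacts: eligible pairs on adjacent site pairs
  min_sep <- 3
  ep <- eligible_pairs(seq, im, min_sep)
  if (nrow(ep)) {
    edges <- list()
    for (f in seq_len(nrow(lattice$coords))) {
      for (g in lattice$adj[[f]]) if (g > f) edges[[length(edges) + 1]] <- c(f, g)
    }
    for (r in seq_len(nrow(ep))) {
      i <- ep$i[r]; j <- ep$j[r]
      for (e in edges) {
        f <- if (lattice$parity[e[1]] == bead_class[i] - 1) e[1] else e[2]
        g <- setdiff(e, f)
        vi <- var_of[[i]][f]; vj <- var_of[[j]][g]
        if (!is.na(vi) && !is.na(vj)) push(c(vi, vj), ep$eps[r])
      }
    }
  }

  poly <- binary_polynomial(labels, vars, coeffs, offset)
  decoder <- do.call(rbind, dec)
  decoder$turn <- NA_integer_; decoder$bit <- NA_integer_
  decoder$i <- NA_integer_; decoder$j <- NA_integer_
  kind <- lattice$spec$kind
  new_encoded_model(poly,
                    if (kind == "cartesian") "coord_cartesian" else "coord_tetrahedral",
                    NA_character_, lattice$spec, seq, im, penalties, decoder)
}

# ---- turn-based machinery ----------------------------------------------

# direction tables (1-based direction ids)
turn_dirs <- function(kind) {
  if (kind == "cartesian") {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else {
    rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  }
}

# dense Cartesian turn code for each direction (bits a, b, c); codes
# (0,0,1) and (1,1,1) are the two invalid null-step codes
CART_DENSE_CODE <- rbind(
  c(1, 0, 0),  # +x
  c(0, 1, 0),  # -x
  c(1, 0, 1),  # +y
  c(0, 1, 1),  # -y
  c(1, 1, 0),  # +z
  c(0, 0, 0))  # -z

# indicator polynomials (one per direction) for one turn, given its variable
# indices; fixed turns yield constant indicators.
turn_indicators <- function(kind, flavor, bits, fixed_dir = NA) {
  ndir <- if (kind == "cartesian") 6 else 4
  if (!is.na(fixed_dir)) {
    return(lapply(seq_len(ndir), function(a) sp_const(as.numeric(a == fixed_dir))))
  }
  if (flavor == "sparse") return(lapply(bits, sp_var))
  if (kind == "diamond") {
    b1 <- sp_var(bits[1]); b2 <- sp_var(bits[2])
    nb1 <- sp_add(sp_const(1), sp_scale(b1, -1))
    nb2 <- sp_add(sp_const(1), sp_scale(b2, -1))
    return(list(sp_mul(nb1, nb2), sp_mul(b1, nb2), sp_mul(nb1, b2), sp_mul(b1, b2)))
  }
  # dense Cartesian: indicator of each 3-bit code
  lapply(seq_len(6), function(a) {
    code <- CART_DENSE_CODE[a, ]
    fs <- lapply(1:3, function(k) {
      v <- sp_var(bits[k])
      if (code[k] == 1) v else sp_add(sp_const(1), sp_scale(v, -1))
    })
    sp_mul(sp_mul(fs[[1]], fs[[2]]), fs[[3]])
  })
}

# per-axis step polynomials for one turn.  For the dense Cartesian code the
# components are the degree-2 forms
#   dx = (a-b)(1-c),  dy = (a-b)c,  dz = (a+b-1)(1-c),
# which realise the 6 unit steps on 6 codes and the null step on the 2
# invalid codes; all other flavors take differences of indicators.
turn_components <- function(kind, flavor, bits, indicators, fixed_dir = NA) {
  dirs <- turn_dirs(kind)
  if (!is.na(fixed_dir)) {
    return(lapply(1:3, function(ax) sp_const(dirs[fixed_dir, ax])))
  }
  if (kind == "cartesian" && flavor == "dense") {
    a <- sp_var(bits[1]); b <- sp_var(bits[2]); cc <- sp_var(bits[3])
    amb <- sp_add(a, sp_scale(b, -1))
    omc <- sp_add(sp_const(1), sp_scale(cc, -1))
    apbm1 <- sp_add(a, b, sp_const(-1))
    return(list(sp_mul(amb, omc), sp_mul(amb, cc), sp_mul(apbm1, omc)))
  }
  lapply(1:3, function(ax) {
    sp_sum(lapply(seq_len(nrow(dirs)), function(a) {
      if (dirs[a, ax] == 0) sp_const(0) else sp_scale(indicators[[a]], dirs[a, ax])
    }))
  })
}

# squared distance function D(i, j) between beads i < j.
#
# Cubic lattice: positional squared distance, per Cartesian axis,
#   D = sum_axis (sum_{k=i}^{j-1} step_k,axis)^2  (unit steps, so D = 1 for
# nearest neighbours and D = 0 for overlaps).
#
# Diamond lattice: squared distance in *signed direction-count* space,
#   D = sum_{a=1}^{4} (sum_{k=i}^{j-1} (-1)^{k-1} [a_k = a])^2,
# the natural integer distance of the turn encoding (beads one step apart
# have D = 1 although their quarter-cell Euclidean separation is sqrt(3)).
turn_distance <- function(kind, comps, indicators, i, j) {
  if (kind == "diamond") {
    return(sp_sum(lapply(1:4, function(a) {
      x <- sp_sum(lapply(i:(j - 1), function(k) {
        s <- if (k %% 2 == 0) -1 else 1
        sp_scale(indicators[[k]][[a]], s)
      }))
      sp_square(x)
    })))
  }
  sp_sum(lapply(1:3, function(ax) {
    x <- sp_sum(lapply(i:(j - 1), function(k) comps[[k]][[ax]]))
    sp_square(x)
  }))
}

sp_is_const <- function(p) all(lengths(p$vars) == 0)

sp_const_value <- function(p) if (length(p$coeffs)) sum(p$coeffs[lengths(p$vars) == 0]) else 0

#' Turn-based tetrahedral encoding
#'
#' The conformation is the sequence of N-1 turns over the 4 tetrahedral
#' directions; bead positions are prefix sums of the direction vectors with
#' the sign alternating by bead sublattice.  The first two turns are fixed
#' (directions 1 and 2) to remove the global symmetry.  Dense flavor encodes
#' each free turn in 2 bits, sparse flavor in a 4-bit one-hot register.
#'
#' For every contact-eligible pair (odd separation >= 5, non-zero pair
#' energy) one interaction variable \eqn{q_{ij}} carries the bracket
#' \deqn{q_{ij}(\epsilon_{ij} + \lambda_1(D(i,j) - 1)
#'   + \sum_{r \in N(j)} \lambda_2 (2 - D(i,r))
#'   + \sum_{m \in N(i)} \lambda_2 (2 - D(m,j)))}
#' with \eqn{N(\cdot)} the sequence neighbours and D the squared distance in
#' signed turn-count space.  Immediate backtracks (equal consecutive turns)
#' are penalised with `lambda_bt`.  Overlaps far from any interaction are
#' *not* penalised -- this is the known flaw demonstrated by
#' [demonstrate_overlap_flaw()].
#'
#' Maximum monomial degree: 5 (dense) or 3 (sparse).
#'
#' @param seq sequence (N >= 2).
#' @param im interaction matrix.
#' @param flavor `"dense"` or `"sparse"`.
#' @param penalties a `penalty_config`.
#' @return An `encoded_model`.
#' @export
encode_turn_tetrahedral <- function(seq, im = hp_interaction(),
                                    flavor = c("dense", "sparse"),
                                    penalties = NULL) {
  flavor <- match.arg(flavor)
  encode_turn(seq, im, flavor, penalties, kind = "diamond")
}

#' Turn-based Cartesian encoding
#'
#' N-1 turns over the 6 cubic directions (first two fixed to +x then +y).
#' Dense flavor uses 3 bits per free turn with the two invalid codes
#' penalised (`lambda_code`); sparse flavor uses a 6-bit one-hot register.
#' Every same-parity bead pair (even separation >= 2) gets an overlap
#' constraint D(j,k) > 0 encoded as an equality with binary slack variables:
#' \eqn{\lambda_1 (D(j,k) - 1 - \sum_l 2^l \alpha_l)^2} with
#' \eqn{\mu = \lceil \log_2 D_{max} \rceil} slack bits.  Contact-eligible
#' pairs (odd separation >= 3) get \eqn{q_{ij}(\epsilon_{ij} +
#' \lambda_1(D(i,j)-1))}.
#'
#' Maximum monomial degree: 8 (dense) or 4 (sparse), attained by the squared
#' overlap constraints once a window contains four free turns.
#'
#' @inheritParams encode_turn_tetrahedral
#' @return An `encoded_model`.
#' @export
encode_turn_cartesian <- function(seq, im = hp_interaction(),
                                  flavor = c("dense", "sparse"),
                                  penalties = NULL) {
  flavor <- match.arg(flavor)
  encode_turn(seq, im, flavor, penalties, kind = "cartesian")
}

encode_turn <- function(seq, im, flavor, penalties, kind) {
  seq <- as_protein_sequence(seq)
  if (is.null(penalties)) penalties <- default_penalties(seq, im, "tuned")
  n <- seq_length(seq)
  nturn <- n - 1
  ndir <- if (kind == "cartesian") 6L else 4L
  fixed <- if (kind == "cartesian") c(1L, 3L) else c(1L, 2L)  # +x,+y / v1,v2
  fixed <- fixed[seq_len(min(2, nturn))]
  bits_per_turn <- if (flavor == "sparse") ndir else (if (kind == "cartesian") 3L else 2L)

  labels <- character(0)
  dec <- list()
  turn_bits <- vector("list", nturn)
  for (k in seq_len(nturn)) {
    if (k <= length(fixed)) next
    idx <- length(labels) + seq_len(bits_per_turn)
    lab <- if (flavor == "sparse") sprintf("t%d.d%d", k, seq_len(bits_per_turn))
           else sprintf("t%d.b%d", k, seq_len(bits_per_turn))
    labels <- c(labels, lab)
    turn_bits[[k]] <- idx
    dec[[length(dec) + 1]] <- data.frame(
      var = idx, role = if (flavor == "sparse") "turn_dir" else "turn_bit",
      bead = NA_integer_, site = NA_integer_, turn = k, bit = seq_len(bits_per_turn),
      i = NA_integer_, j = NA_integer_)
  }

  indicators <- vector("list", nturn)
  comps <- vector("list", nturn)
  for (k in seq_len(nturn)) {
    fd <- if (k <= length(fixed)) fixed[k] else NA
    indicators[[k]] <- turn_indicators(kind, flavor, turn_bits[[k]], fd)
    comps[[k]] <- turn_components(kind, flavor, turn_bits[[k]], indicators[[k]], fd)
  }

  vars <- list(); coeffs <- numeric(); offset <- 0
  push_sp <- function(p, scale = 1) {
    for (t in seq_along(p$coeffs)) {
      v <- p$vars[[t]]
      if (!length(v)) offset <<- offset + scale * p$coeffs[t]
      else {
        vars[[length(vars) + 1]] <<- v
        coeffs[[length(coeffs) + 1]] <<- scale * p$coeffs[t]
      }
    }
  }
  new_var <- function(lab, role, i = NA, j = NA, bit = NA) {
    labels <<- c(labels, lab)
    idx <- length(labels)
    dec[[length(dec) + 1]] <<- data.frame(
      var = idx, role = role, bead = NA_integer_, site = NA_integer_,
      turn = NA_integer_, bit = as.integer(bit), i = as.integer(i), j = as.integer(j))
    idx
  }

  # code validity: sparse one-hot registers; dense Cartesian invalid codes
  for (k in seq_len(nturn)) {
    if (k <= length(fixed)) next
    if (flavor == "sparse") {
      reg <- sp_sum(lapply(turn_bits[[k]], sp_var))
      push_sp(sp_square(sp_add(reg, sp_const(-1))), penalties$lambda_code)
    } else if (kind == "cartesian") {
      a <- sp_var(turn_bits[[k]][1]); b <- sp_var(turn_bits[[k]][2])
      cc <- sp_var(turn_bits[[k]][3])
      na_ <- sp_add(sp_const(1), sp_scale(a, -1))
      nb_ <- sp_add(sp_const(1), sp_scale(b, -1))
      inval <- sp_add(sp_mul(sp_mul(na_, nb_), cc), sp_mul(sp_mul(a, b), cc))
      push_sp(inval, penalties$lambda_code)
    }
  }

  # backtrack penalty (diamond: equal consecutive turns step back onto the
  # previous-but-one bead; cubic reversals are covered by the overlap terms)
  if (kind == "diamond") {
    for (k in seq_len(nturn - 1)) {
      for (a in seq_len(ndir)) {
        push_sp(sp_mul(indicators[[k]][[a]], indicators[[k + 1]][[a]]),
                penalties$lambda_bt)
      }
    }
  }

  # overlap exclusion (cubic): D(j,k) > 0 via slack-bit equality
  if (kind == "cartesian") {
    for (jj in seq_len(n - 2)) {
      for (kk in seq(jj + 2, n)) {
        if ((kk - jj) %% 2 != 0) next
        d <- turn_distance(kind, comps, indicators, jj, kk)
        if (sp_is_const(d)) next  # fully fixed window, D constant > 0
        dmax <- (kk - jj)^2
        mu <- ceiling(log2(dmax))
        slack <- vapply(seq_len(mu) - 1L, function(l) {
          new_var(sprintf("s%d.%d.a%d", jj, kk, l), "slack", jj, kk, l)
        }, integer(1))
        sterm <- sp_sum(lapply(seq_along(slack), function(l) {
          sp_scale(sp_var(slack[l]), -2^(l - 1))
        }))
        push_sp(sp_square(sp_add(d, sp_const(-1), sterm)), penalties$lambda1)
      }
    }
  }

  # interaction terms
  min_sep <- if (kind == "cartesian") 3 else 5
  ep <- eligible_pairs(seq, im, min_sep)
  if (nrow(ep)) {
    for (r in seq_len(nrow(ep))) {
      i <- ep$i[r]; j <- ep$j[r]
      qv <- new_var(sprintf("q%d.%d", i, j), "interaction", i, j)
      dij <- turn_distance(kind, comps, indicators, i, j)
      bracket <- sp_add(sp_const(ep$eps[r] - penalties$lambda1),
                        sp_scale(dij, penalties$lambda1))
      if (kind == "diamond") {
        for (rr in intersect(c(j - 1, j + 1), seq_len(n))) {
          dd <- turn_distance(kind, comps, indicators, min(i, rr), max(i, rr))
          bracket <- sp_add(bracket, sp_const(2 * penalties$lambda2),
                            sp_scale(dd, -penalties$lambda2))
        }
        for (mm in intersect(c(i - 1, i + 1), seq_len(n))) {
          dd <- turn_distance(kind, comps, indicators, min(mm, j), max(mm, j))
          bracket <- sp_add(bracket, sp_const(2 * penalties$lambda2),
                            sp_scale(dd, -penalties$lambda2))
        }
      }
      push_sp(sp_mul(list(vars = list(as.integer(qv)), coeffs = 1), bracket))
    }
  }

  poly <- binary_polynomial(labels, vars, coeffs, offset)
  decoder <- if (length(dec)) do.call(rbind, dec) else
    data.frame(var = integer(), role = character(), bead = integer(),
               site = integer(), turn = integer(), bit = integer(),
               i = integer(), j = integer())
  new_encoded_model(poly,
                    if (kind == "cartesian") "turn_cartesian" else "turn_tetrahedral",
                    flavor, NULL, seq, im, penalties, decoder, fixed_dirs = fixed)
}
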