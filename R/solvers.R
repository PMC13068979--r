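# ---- internal solver view ----------------------------------------------
# Converts any supported model into the flat arrays the C++ engines consume.

solver_view <- function(model) {
  if (inherits(model, "encoded_model")) model <- model$poly
  if (inherits(model, "ising_model")) model <- ising_to_qubo(model)
  if (inherits(model, "binary_polynomial") && bp_degree(model) <= 2) {
    model <- as_quadratic_model(model)
  }
  if (inherits(model, "quadratic_model")) {
    n <- n_variables(model)
    deg <- integer(n)
    for (k in seq_along(model$qv)) {
      deg[model$qi[k]] <- deg[model$qi[k]] + 1L
      deg[model$qj[k]] <- deg[model$qj[k]] + 1L
    }
    aptr <- c(0L, cumsum(deg))
    aidx <- integer(sum(deg)); w <- numeric(sum(deg))
    fill <- aptr[seq_len(n)]
    for (k in seq_along(model$qv)) {
      i <- model$qi[k]; j <- model$qj[k]
      fill[i] <- fill[i] + 1L; aidx[fill[i]] <- j - 1L; w[fill[i]] <- model$qv[k]
      fill[j] <- fill[j] + 1L; aidx[fill[j]] <- i - 1L; w[fill[j]] <- model$qv[k]
    }
    return(list(quad = TRUE, n = n, h = model$linear, aptr = aptr, aidx = aidx,
                w = w, offset = model$offset, labels = model$labels,
                qmodel = model))
  }
  stopifnot(inherits(model, "binary_polynomial"))
  n <- n_variables(model)
  nt <- length(model$coeffs)
  tptr <- c(0L, cumsum(lengths(model$vars)))
  tvars <- as.integer(unlist(model$vars)) - 1L
  vcount <- integer(n)
  for (t in seq_len(nt)) for (v in model$vars[[t]]) vcount[v] <- vcount[v] + 1L
  vptr <- c(0L, cumsum(vcount))
  vterm <- integer(sum(vcount))
  fill <- vptr[seq_len(n)]
  for (t in seq_len(nt)) {
    for (v in model$vars[[t]]) {
      fill[v] <- fill[v] + 1L
      vterm[fill[v]] <- t - 1L
    }
  }
  list(quad = FALSE, n = n, tptr = tptr, tvars = tvars, tcoef = model$coeffs,
       vptr = vptr, vterm = vterm, offset = model$offset, labels = model$labels,
       poly = model)
}

view_adjacency <- function(view) {
  n <- view$n
  if (view$quad) {
    lapply(seq_len(n), function(i) {
      unique(view$aidx[seq_len(view$aptr[i + 1] - view$aptr[i]) + view$aptr[i]] + 1L)
    })
  } else {
    adj <- lapply(seq_len(n), function(i) integer(0))
    nt <- length(view$tcoef)
    for (t in seq_len(nt)) {
      v <- view$tvars[seq_len(view$tptr[t + 1] - view$tptr[t]) + view$tptr[t]] + 1L
      if (length(v) > 1) for (i in v) adj[[i]] <- union(adj[[i]], setdiff(v, i))
    }
    adj
  }
}

# deterministic delta-energy helper used by the start-temperature probe
view_delta <- function(view, b, i) {
  if (view$quad) {
    idx <- seq_len(view$aptr[i + 1] - view$aptr[i]) + view$aptr[i]
    f <- view$h[i] + sum(view$w[idx] * b[view$aidx[idx] + 1L])
    return((1 - 2 * b[i]) * f)
  }
  idx <- seq_len(view$vptr[i + 1] - view$vptr[i]) + view$vptr[i]
  s <- 0
  for (t in view$vterm[idx] + 1L) {
    v <- view$tvars[seq_len(view$tptr[t + 1] - view$tptr[t]) + view$tptr[t]] + 1L
    others <- setdiff(v, i)
    if (all(b[others] == 1)) s <- s + view$tcoef[t]
  }
  (1 - 2 * b[i]) * s
}

# ---- schedules and configs ---------------------------------------------

#' Annealing schedule
#'
#' Exponential cooling \eqn{T_{i+1} = \zeta T_i} applied after every full
#' sweep (one attempted flip per variable), clamped below at `t_min`.
#'
#' @param t0 start temperature, or `"auto"` for the probe-based rule of
#'   [auto_start_temperature()].
#' @param zeta cooling rate in (0, 1).
#' @param sweeps number of sweeps.
#' @param t_min temperature floor.
#' @return An `anneal_schedule`.
#' @export
anneal_schedule <- function(t0 = "auto", zeta = 0.99, sweeps = 1000, t_min = 1e-3) {
  if (!(identical(t0, "auto") || (is.numeric(t0) && t0 > 0))) {
    stop("t0 must be \"auto\" or a positive number")
  }
  if (!is.numeric(zeta) || zeta <= 0 || zeta >= 1) stop("zeta must lie in (0, 1)")
  if (sweeps < 1) stop("sweeps must be >= 1")
  if (t_min <= 0) stop("t_min must be positive")
  structure(list(t0 = t0, zeta = zeta, sweeps = as.integer(sweeps), t_min = t_min),
            class = "anneal_schedule")
}

#' Parallel-tempering configuration
#'
#' `n_replicas` temperatures distributed geometrically between `t_min` and
#' `t_max`; after every sweep of all replicas, neighbouring temperature pairs
#' (alternating even/odd pairings) attempt a swap.
#'
#' @param n_replicas number of replicas (>= 2).
#' @param t_min,t_max temperature range (0 < t_min < t_max).
#' @param sweeps total Monte Carlo sweeps.
#' @param thermalization sweeps discarded before the lowest-temperature
#'   trace is recorded (defaults to 80 percent of `sweeps`).
#' @return A `pt_config`.
#' @export
pt_config <- function(n_replicas = 16, t_min = 0.1, t_max = 10, sweeps = 2000,
                      thermalization = NULL) {
  if (n_replicas < 2) stop("need at least 2 replicas")
  if (!(t_min > 0 && t_min < t_max)) stop("need 0 < t_min < t_max")
  if (is.null(thermalization)) thermalization <- floor(0.8 * sweeps)
  if (thermalization >= sweeps) stop("thermalization must be < sweeps")
  m <- as.integer(n_replicas)
  ladder <- t_min * (t_max / t_min)^((seq_len(m) - 1) / (m - 1))
  structure(list(n_replicas = m, t_min = t_min, t_max = t_max,
                 ladder = ladder, sweeps = as.integer(sweeps),
                 thermalization = as.integer(thermalization)),
            class = "pt_config")
}

#' Metropolis acceptance rule
#'
#' Accepts energy changes \eqn{\Delta E \le 0} always, and otherwise with
#' probability \eqn{e^{-\Delta E / T}} (Boltzmann constant k = 1).
#'
#' @param delta_e energy change(s) of the proposed move.
#' @param temperature temperature (> 0).
#' @return Logical vector of acceptance decisions.
#' @export
metropolis_accept <- function(delta_e, temperature) {
  if (!is.numeric(temperature) || temperature <= 0) stop("temperature must be > 0")
  delta_e <= 0 | runif(length(delta_e)) < exp(-delta_e / temperature)
}

#' Probe-based start temperature
#'
#' Performs `n_probe` single-flip probes on a uniform-random state (accepted
#' downhill probes are applied, so the probe performs a zero-temperature
#' random walk) and sets
#' \deqn{T_0 = (\overline{\Delta E} + 3 s_{\Delta E}) / \ln(1/\chi)}
#' with \eqn{\chi = n_{flipped}/n} the fraction of probes with
#' \eqn{\Delta E \le 0}, and mean/sd taken over the uphill probes.  \eqn{\chi}
#' is clamped into \eqn{[1/n, 1 - 1/n]}; a degenerate model where every probe
#' is flat returns the fallback \eqn{T_0 = 1}.
#'
#' @param model any supported model.
#' @param n_probe number of probes (>= 100).
#' @param seed RNG seed.
#' @return A start temperature.
#' @export
auto_start_temperature <- function(model, n_probe = 1000, seed = 1L) {
  if (n_probe < 100) stop("n_probe must be >= 100")
  view <- solver_view(model)
  n <- view$n
  if (n == 0) return(1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  b <- as.numeric(runif(n) < 0.5)
  uphill <- numeric(0)
  n_flipped <- 0L
  picks <- sample.int(n, n_probe, replace = TRUE)
  for (p in picks) {
    de <- view_delta(view, b, p)
    if (de <= 0) {
      n_flipped <- n_flipped + 1L
      b[p] <- 1 - b[p]
    } else {
      uphill <- c(uphill, de)
    }
  }
  if (!length(uphill)) return(1)
  chi <- min(max(n_flipped / n_probe, 1 / n_probe), 1 - 1 / n_probe)
  m <- mean(uphill)
  s <- if (length(uphill) > 1) sd(uphill) else 0
  t0 <- (m + 3 * s) / log(1 / chi)
  if (!is.finite(t0) || t0 <= 0) 1 else t0
}

#' Greedy graph colouring (largest degree first)
#'
#' Deterministic proper colouring used to order the multi-flip sweeps: no two
#' adjacent variables share a colour class, so flips within a class have
#' independent energy changes.
#'
#' @param adjacency list of neighbour index vectors.
#' @return Integer colour per vertex (1-based).
#' @export
greedy_coloring <- function(adjacency) {
  n <- length(adjacency)
  deg <- lengths(adjacency)
  order_ <- order(-deg, seq_len(n))
  col <- integer(n)
  for (v in order_) {
    used <- col[adjacency[[v]]]
    k <- 1L
    while (k %in% used) k <- k + 1L
    col[v] <- k
  }
  col
}

sweep_order <- function(view) {
  if (!view$quad) return(seq_len(view$n) - 1L)  # sequential sweeps for HUBOs
  col <- greedy_coloring(view_adjacency(view))
  order(col, seq_len(view$n)) - 1L
}

# ---- sample sets --------------------------------------------------------

new_sample_set <- function(assignments, energies, labels, seed, config) {
  o <- order(energies)
  structure(list(assignments = assignments, energies = energies,
                 labels = labels, best_energy = energies[o[1]],
                 best_assignment = assignments[o[1], ], seed = seed,
                 config = config),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> %d samples over %d variables, best energy %g\n",
              nrow(x$assignments), ncol(x$assignments), x$best_energy))
  invisible(x)
}

#' Simulated annealing
#'
#' Metropolis single-flip annealing with the exponential cooling schedule.
#' Each sweep attempts one flip per variable, visiting variables colour class
#' by colour class (quadratic models) or sequentially (higher-order models);
#' the temperature is multiplied by `zeta` after every sweep.  Each repeat
#' runs an independent chain from a fresh random state and reports the best
#' state seen anywhere along the chain.  Fully reproducible from `seed`.
#'
#' @param model a `quadratic_model`, `binary_polynomial`, `ising_model` or
#'   `encoded_model`.
#' @param schedule an [anneal_schedule()].
#' @param n_repeats independent repeats.
#' @param seed master seed; per-repeat streams are derived deterministically.
#' @return A `sample_set` (energies include the model offset).
#' @export
simulated_annealing <- function(model, schedule = anneal_schedule(),
                                n_repeats = 10, seed = 1L) {
  stopifnot(inherits(schedule, "anneal_schedule"))
  view <- solver_view(model)
  t0 <- if (identical(schedule$t0, "auto")) {
    auto_start_temperature(model, seed = seed)
  } else schedule$t0
  res <- cpp_sa(view, sweep_order(view), schedule$sweeps, t0, schedule$zeta,
                schedule$t_min, as.integer(n_repeats), as.numeric(seed))
  sched <- schedule; sched$t0_used <- t0
  new_sample_set(res$states, res$energies + view$offset, view$labels, seed, sched)
}

#' Parallel tempering
#'
#' Runs `n_replicas` Metropolis chains at the fixed geometric temperature
#' ladder; after each sweep, neighbouring-temperature replicas swap with
#' probability \eqn{\min(1, e^{(E - E')(1/T - 1/T')})}.  Optionally records
#' the lowest-temperature replica's state after thermalization (the trace
#' used for spin-overlap estimation).
#'
#' @param model any supported model of degree <= 2.
#' @param config a [pt_config()].
#' @param seed RNG seed.
#' @param record_trace record the lowest-temperature trace?
#' @return list(best: `sample_set` of one state, replica_energies, trace
#'   (0/1 matrix or NULL), ladder, swap_rates).
#' @export
parallel_tempering <- function(model, config = pt_config(), seed = 1L,
                               record_trace = FALSE) {
  stopifnot(inherits(config, "pt_config"))
  view <- solver_view(model)
  res <- cpp_pt(view, sweep_order(view), config$ladder, config$sweeps,
                as.numeric(seed),
                if (record_trace) config$thermalization else -1L)
  best <- new_sample_set(matrix(res$best_state, 1), res$best_energy + view$offset,
                         view$labels, seed, config)
  list(best = best,
       replica_energies = res$replica_energies + view$offset,
       trace = if (record_trace) res$trace else NULL,
       ladder = config$ladder,
       swap_rates = ifelse(res$swap_attempts > 0,
                           res$swap_accepts / pmax(res$swap_attempts, 1), NA))
}

#' Exhaustive exact solver
#'
#' Gray-code enumeration of all \eqn{2^n} states; exact minimum and all
#' minimising states (up to `keep`).
#'
#' @param model any supported model.
#' @param guard refuse instances with more variables than this.
#' @param allow_large override the guard (up to 30 variables).
#' @param keep maximum number of argmin states returned.
#' @return list(energy, states (matrix, one row per argmin), argmin_count).
#' @export
exact_solve <- function(model, guard = 24, allow_large = FALSE, keep = 4096) {
  view <- solver_view(model)
  if (view$n > guard && !allow_large) {
    stop(view$n, " variables exceed the exhaustive guard (", guard, ")")
  }
  res <- cpp_exact(view, as.integer(keep))
  list(energy = res$energy + view$offset, states = res$states,
       argmin_count = res$argmin_count)
}
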