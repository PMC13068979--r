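#' Spin overlap between two states
#'
#' The spin-glass order parameter \eqn{q = \frac{1}{n}\sum_i s_i^{(1)}
#' s_i^{(2)}} between two states over the same variables.  Boolean 0/1
#' states are converted to spins first.
#'
#' @param state_a,state_b equal-length vectors over \{0,1\} or \{-1,+1\}.
#' @return q in \[-1, 1\].
#' @export
spin_overlap <- function(state_a, state_b) {
  if (length(state_a) != length(state_b)) stop("states cover different variables")
  to_spin <- function(x) {
    if (all(x %in% c(0, 1))) boolean_to_spin(x)
    else if (all(x %in% c(-1, 1))) as.numeric(x)
    else stop("states must be 0/1 or -1/+1")
  }
  mean(to_spin(state_a) * to_spin(state_b))
}

#' Estimate the spin-overlap distribution (SOD) of a model
#'
#' Runs two independent parallel-tempering instances with identical
#' temperature ladders but different seeds; after thermalization, the spin
#' overlap between the two lowest-temperature replicas is recorded every
#' sweep.  The distribution P(q) of these overlaps is a proxy for the
#' free-energy landscape: support concentrated at |q| > 0.5 indicates thin
#' barriers (many minima a few flips apart), support near 0 thick barriers.
#'
#' @param model any supported model of degree <= 2.
#' @param config a [pt_config()]; `sweeps - thermalization` overlap sweeps
#'   are recorded.
#' @param seeds two distinct seeds, one per PT instance.
#' @param bin_width histogram bin width on \[-1, 1\].
#' @return An `overlap_distribution`: list(q, mids, masses, bin_width,
#'   n_olap, thermalization).
#' @export
estimate_sod <- function(model, config = pt_config(), seeds = c(1L, 2L),
                         bin_width = 0.02) {
  if (length(seeds) != 2 || seeds[1] == seeds[2]) stop("need two distinct seeds")
  r1 <- parallel_tempering(model, config, seed = seeds[1], record_trace = TRUE)
  r2 <- parallel_tempering(model, config, seed = seeds[2], record_trace = TRUE)
  t1 <- 2 * r1$trace - 1
  t2 <- 2 * r2$trace - 1
  q <- rowMeans(t1 * t2)
  breaks <- seq(-1, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  nb <- length(breaks) - 1
  idx <- pmin(pmax(findInterval(q, breaks, rightmost.closed = TRUE), 1), nb)
  masses <- tabulate(idx, nb) / length(q)
  mids <- (breaks[-1] + breaks[-(nb + 1)]) / 2
  structure(list(q = q, mids = mids, masses = masses,
                 bin_width = bin_width, n_olap = length(q),
                 thermalization = config$thermalization),
            class = "overlap_distribution")
}

#' @export
print.overlap_distribution <- function(x, ...) {
  cat(sprintf("<overlap_distribution> %d overlap samples, support on %d bins\n",
              x$n_olap, sum(x$masses > 0)))
  invisible(x)
}

#' Classify the barrier structure of an overlap distribution
#'
#' Peaks are histogram bins that are local maxima with mass at least
#' `prominence` times the maximum bin mass.  If every peak lies at
#' \eqn{|q| > 0.5} the instance has *thin* barriers (amenable to tunneling);
#' any peak inside \eqn{|q| \le 0.5} marks *thick* barriers.
#'
#' @param dist an `overlap_distribution`.
#' @param prominence minimum relative peak height.
#' @return `"thin"` or `"thick"`.
#' @export
classify_barriers <- function(dist, prominence = 0.05) {
  stopifnot(inherits(dist, "overlap_distribution"))
  m <- dist$masses
  if (!length(m) || anyNA(m) || all(m == 0)) stop("empty overlap distribution")
  thresh <- prominence * max(m)
  up <- c(-Inf, m[-length(m)])
  down <- c(m[-1], -Inf)
  peaks <- which(m >= up & m >= down & m >= thresh & m > 0)
  if (all(abs(dist$mids[peaks]) > 0.5)) "thin" else "thick"
}

#' Time-to-solution (TTS)
#'
#' Expected total runtime to observe the ground state at least once with 99
#' percent confidence, given a per-run success probability:
#' \deqn{TTS = \tau \log(1 - 0.99) / \log(1 - p_{ground}).}
#' For \eqn{p \ge 0.99} a single run suffices and \eqn{TTS = \tau}; for
#' \eqn{p = 0} the TTS is infinite.
#'
#' @param tau runtime of a single run (any units; the package reports
#'   hardware-independent work units, sweeps x variables).
#' @param p_ground per-run ground-state probability in \[0, 1\].
#' @return The TTS in the units of `tau`.
#' @export
time_to_solution <- function(tau, p_ground) {
  if (any(tau <= 0)) stop("tau must be positive")
  if (any(p_ground < 0 | p_ground > 1)) stop("p_ground must lie in [0, 1]")
  ifelse(p_ground == 0, Inf,
         ifelse(p_ground >= 0.99, tau, tau * log(1 - 0.99) / log(1 - p_ground)))
}

#' Optimize the TTS over a schedule grid
#'
#' Runs simulated annealing for every schedule in the grid, estimates the
#' per-run ground-state probability as the fraction of repeats whose best
#' energy reaches the (externally known) ground energy, and reports the
#' schedule minimising the TTS with \eqn{\tau} measured in work units
#' (sweeps x variables).
#'
#' @param model any supported model.
#' @param ground_energy exact ground-state energy (from an oracle).
#' @param schedules non-empty list of [anneal_schedule()]s.
#' @param n_repeats repeats per schedule.
#' @param seed master seed.
#' @param tol energy tolerance for counting a hit.
#' @return A `tts_result`: list(table = data.frame(sweeps, zeta, t0,
#'   p_ground, tau, tts), best = row index of the optimum).
#' @export
optimize_tts <- function(model, ground_energy, schedules, n_repeats = 50,
                         seed = 1L, tol = 1e-9) {
  if (!length(schedules)) stop("empty schedule grid")
  view_n <- solver_view(model)$n
  rows <- lapply(seq_along(schedules), function(k) {
    sch <- schedules[[k]]
    ss <- simulated_annealing(model, sch, n_repeats = n_repeats,
                              seed = seed + k - 1L)
    p <- mean(ss$energies <= ground_energy + tol)
    tau <- sch$sweeps * view_n
    data.frame(sweeps = sch$sweeps, zeta = sch$zeta,
               t0 = if (identical(sch$t0, "auto")) NA_real_ else sch$t0,
               p_ground = p, tau = tau, tts = time_to_solution(tau, p))
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab, best = which.min(tab$tts)), class = "tts_result")
}

#' @export
print.tts_result <- function(x, ...) {
  cat("<tts_result>\n")
  print(x$table)
  cat(sprintf("best schedule: row %d (TTS = %g)\n", x$best, x$table$tts[x$best]))
  invisible(x)
}

#' QUBO resource metrics
#'
#' The hardware-oriented metrics used to compare model encodings: number of
#' variables (logical qubits), density \eqn{\rho} of the coupling matrix
#' (non-zero off-diagonal pairs over n(n-1)/2), mean couplers per qubit, and
#' coupler resolution \eqn{J_{max}/J_{min}} (largest over smallest non-zero
#' coupling magnitude; 1 for models without couplers).
#'
#' @param model a model of degree <= 2.
#' @return A `qubo_metrics`: list(n_variables, density, couplers_per_qubit,
#'   resolution).
#' @export
qubo_metrics <- function(model) {
  qm <- as_quadratic_model(model)
  n <- n_variables(qm)
  nz <- abs(qm$qv) > 1e-15
  npairs <- sum(nz)
  density <- if (n < 2) 0 else npairs / (n * (n - 1) / 2)
  cpq <- if (n < 1) 0 else 2 * npairs / n
  resolution <- if (npairs == 0) 1 else max(abs(qm$qv[nz])) / min(abs(qm$qv[nz]))
  structure(list(n_variables = n, density = density, couplers_per_qubit = cpq,
                 resolution = resolution),
            class = "qubo_metrics")
}

#' @export
print.qubo_metrics <- function(x, ...) {
  cat(sprintf(paste0("<qubo_metrics> %d qubits, density %.4f, ",
                     "%.2f couplers/qubit, resolution %.3g\n"),
              x$n_variables, x$density, x$couplers_per_qubit, x$resolution))
  invisible(x)
}
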