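---
title: "Lattice protein folding as binary optimization: models, solvers and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lattice protein folding as binary optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latticefold)
```

## The problem

A coarse-grained lattice model of protein folding represents an N-residue
chain as N beads on a discrete lattice, one bead per residue, with
consecutive beads on adjacent sites and no two beads on the same site
(a self-avoiding walk).  The free energy of a fold is the sum of pairwise
contact energies $\epsilon(a_i, a_j)$ over all non-bonded bead pairs
(sequence separation $|i-j| \ge 3$) that sit on adjacent sites.  In the HP
model only hydrophobic-hydrophobic contacts count, $\epsilon(H,H) = -1$;
20-letter statistical contact matrices (Miyazawa–Jernigan style) can be
loaded from CSV, but their numeric values are not bundled.  Finding the
minimum-energy fold is NP-complete already in the HP case, which motivates
casting it as quadratic/higher-order unconstrained binary optimization
(QUBO/HUBO) — the native input of annealing-type heuristics and quantum
annealers.

Two lattices are supported: the simple-cubic lattice (6 neighbours) and the
tetrahedral *diamond* lattice (4 neighbours), built from two interleaved FCC
sublattices offset by a quarter of the cell diagonal.  In the package's
integer quarter-cell units, sublattice A is spanned by $(0,2,2)$, $(2,0,2)$,
$(2,2,0)$ and sublattice B is A shifted by $(1,1,1)$; the four A-to-B bond
vectors are the sign-product-$+1$ corners $(1,1,1)$, $(1,-1,-1)$,
$(-1,1,-1)$, $(-1,-1,1)$.  Both lattices are bipartite, so a chain
alternates between parity classes and only odd sequence separations can ever
form contacts.  Exhaustive enumeration (`min_contact_length()`) shows the
smallest chain with a non-bonded contact has 4 beads on the cubic lattice
and 6 on the diamond lattice.

## The four encodings

| model | variables | native locality |
|---|---|---|
| coordinate, cubic | one-hot site register per bead, $N/2 \cdot L_{tot}$ | 2 |
| coordinate, tetrahedral | per-bead register over one FCC sublattice | 2 |
| turn, cubic (dense / sparse) | 3 / 6 bits per free turn + slack + interaction | 8 / 4 |
| turn, tetrahedral (dense / sparse) | 2 / 4 bits per free turn + interaction | 5 / 3 |

**Coordinate-based models** place bead $t$ in a one-hot register over the
sites of parity class $(t-1) \bmod 2$ (on the diamond lattice: one
sublattice), which halves the register length and guarantees that same-parity
beads can never be adjacent.  The objective is natively quadratic: one-hot
penalties $\lambda_{oh}(\sum_f x_{t,f}-1)^2$, connectivity penalties on
non-adjacent consecutive placements, same-site exclusion for same-parity
beads, and contact terms $\epsilon(a_i,a_j)\,x_{i,f}x_{j,g}$ over adjacent
site pairs.  The minimal symmetric grid is $L_{min} = \lceil N^{1/3}\rceil+1$
(cubic) or $\lceil (N/2)^{1/3}\rceil + 1$ cells per sublattice (diamond).
Bead 1 is *not* anchored by default, keeping the variable-count formulas
exact; `anchor = TRUE` trims the translational degeneracy.

**Turn-based models** encode the $N-1$ bond directions.  The first two turns
are fixed to remove the global rotation/reflection degeneracy.  On the
diamond lattice this is lossless: the full point group acts transitively on
ordered pairs of distinct directions, and equal consecutive directions are
backtracks anyway.  On the cubic lattice fixing the second turn to a
perpendicular direction also prunes conformations whose first two steps are
collinear; this affects degeneracy counting in the turn models only (the
coordinate models and all oracles are unaffected), and is accepted as the
standard symmetry reduction.

Positions are prefix sums of direction vectors; on the diamond lattice the
sign alternates with bead parity.  The squared distance function $D(i,j)$
that powers all constraints is the positional squared distance on the cubic
lattice, but on the diamond lattice it is computed in *signed
direction-count space*: $D(i,j) = \sum_{a=1}^{4}\big(\sum_{k=i}^{j-1}
(-1)^{k-1}[a_k = a]\big)^2$, so adjacent beads have $D = 1$ even though
their quarter-cell Euclidean separation is $\sqrt3$.  Early development
used the Euclidean form on the diamond lattice; the exhaustive turn-space
oracle immediately exposed the inconsistency, which is why the package keeps
dual routes (encoder vs oracle) for every model.

Contact-eligible pairs (odd separation, at least 3 on the cubic and 5 on the
tetrahedral lattice, non-zero $\epsilon$) each get one interaction variable
$q_{ij}$.  On the tetrahedral lattice it carries the bracket
$$q_{ij}\Big(\epsilon_{ij} + \lambda_1 (D(i,j)-1) + \sum_{r \in N(j)}
\lambda_2(2 - D(i,r)) + \sum_{m \in N(i)} \lambda_2(2-D(m,j))\Big),$$
with $N(\cdot)$ the sequence neighbours: $\lambda_1$ forces the interacting
beads to distance 1 and $\lambda_2$ forces their neighbours to distance 2
(excluding local overlaps).  On the cubic lattice the interaction term is
$q_{ij}(\epsilon_{ij} + \lambda_1(D(i,j)-1))$ and overlap exclusion is
global: every even-separation pair gets the inequality $D(j,k) > 0$,
rewritten with $\mu = \lceil \log_2 (k-j)^2 \rceil$ binary slack bits as
$\lambda_1\big(D - 1 - \sum_l 2^l \alpha_l\big)^2$.  Squaring the degree-4
dense distance polynomial is what produces the maximal locality 8.

The dense cubic turn code uses 3 bits with step components
$\Delta x = (a-b)(1-c)$, $\Delta y = (a-b)c$, $\Delta z = (a+b-1)(1-c)$ —
degree-2 polynomials realising the six unit steps on six codes; the two
remaining codes give a null step and are penalised (`lambda_code`).  Keeping
the components at degree 2 (rather than degree-3 code indicators) is what
keeps the overlap constraints at the printed locality.

## Penalty weights

`default_penalties()` offers two regimes with base weight $b$:

* **tuned**: $b = 1 + \max|\epsilon|$ — light weights that keep coupler
  magnitudes (and hence the coupler resolution $J_{max}/J_{min}$) small;
* **worst-case**: $b = 1 + \sum|\epsilon|$ over the eligible pairs — for the
  coordinate models this provably removes every incentive to violate a
  constraint: an $m$-fold register violation costs at least $bm$ while the
  extra contacts it can buy are bounded by $m \sum|\epsilon| < bm$.

In both regimes $\lambda_1 = \lambda_{bt} = \lambda_{code} = 10\,b$ while
$\lambda_2 = b$.  Equal weights $\lambda_1 = \lambda_2$ are *not* safe for
the tetrahedral bracket: when $q_{ij} = 1$ and $D(i,j) = 1$ each guard term
$2 - D(i,r)$ is provably 0 or $+2$, but when the chain stretches so that
$D(i,j) = d \ge 2$, parity-admissible geometries reach
$D(i,r) = d + 2\sqrt d + 1$, making the guard terms *negative* (a reward)
faster than $\lambda_1(d-1)$ grows.  The binding case is $d = 3$ with up to
four guards at $D = 6$, giving the sufficient condition $2\lambda_1 >
16 \lambda_2 + |\epsilon|$; $\lambda_1 = 10\lambda_2$ satisfies it with
margin.  A backtrack penalty $\lambda_{bt}\sum_k [a_k = a_{k+1}]$ is
included on the tetrahedral lattice (cubic reversals are already covered by
the overlap constraints); without it every immediate chain reversal is free
and the degenerate-ground-state demonstration below drowns in trivial
overlaps.

With these weights the model still exhibits its structural flaw, which is
the point of `demonstrate_overlap_flaw()`: overlaps far from any active
interaction are invisible to the energy function, so for a sequence like
`HPPPPHPPPPH` exhaustive turn-space search finds self-intersecting folds
*and* valid folds at the same minimal energy $-2$:

```{r flaw}
demonstrate_overlap_flaw("HPPPPHPPPPH")
```

## HUBO to QUBO

`reduce_to_quadratic()` iterates the Rosenberg substitution: the variable
pair occurring in the most monomials of degree $\ge 3$ (ties: lowest
indices) is replaced by an ancilla $b_4$ with penalty
$\alpha(b_2 b_3 - 2 b_4(b_2 + b_3) + 3 b_4)$, which is 0 iff
$b_4 = b_2 b_3$ and at least $\alpha$ otherwise.  Each pair is substituted
once across all monomials.  The default $\alpha = 1 + \sum|c|$ over the
original coefficients guarantees the exactness contract — for *every*
assignment of the original variables, the ancilla-minimised reduced energy
equals the original energy — which the tests verify by brute force on
randomized HUBOs of up to 10 variables.

## Solvers

*Simulated annealing* performs one attempted Metropolis flip per variable
per sweep, visiting variables colour class by colour class (a deterministic
largest-degree-first greedy colouring of the coupling graph; any proper
colouring preserves correctness, the colour structure only matters for
parallelisation) and multiplies the temperature by $\zeta$ after every
sweep, clamped at `t_min`.  Higher-order objectives are accepted and swept
sequentially.  Each repeat is an independent chain from a uniform random
state; the reported state is the best seen anywhere along the chain, and the
GPU-style parallelism of production implementations is modelled by the
`n_repeats` parameter.  One master seed drives per-repeat counter-derived
streams, so results are bit-reproducible.

The automatic start temperature performs `n_probe` single-flip probes on a
uniform-random state and sets $T_0 = (\overline{\Delta E} + 3 s_{\Delta E})
/ \ln(1/\chi)$.  The acceptance rule defining $\chi$ at probe time is not
fully specified by the construction this follows, so the package documents
its stand-in: a probe counts as flipped iff $\Delta E \le 0$ (and is then
applied, making the probe a zero-temperature walk), mean and standard
deviation are taken over the uphill probes, and $\chi$ is clamped into
$[1/n, 1-1/n]$.  Note a practical limitation, found during validation: on
strongly penalty-dominated models (coordinate encodings with worst-case
weights) the probe measures the *penalty* energy scale and can return
$T_0$ of order $10-10^2$, which a 2000-sweep $\zeta = 0.999$ schedule never
cools below the contact scale.  Because penalty violations are repaired
greedily at any temperature, $T_0$ only needs to melt the *contact*
ordering; the ground-state validation runs therefore fix $T_0 = 3$ (a few
times $\max|\epsilon|$, final temperature $\approx 0.4$), which reaches the
exact oracle minimum on all 20 random HP instances on both lattices.  Auto
$T_0$ remains the default for general use.

*Parallel tempering* runs replicas at a geometric temperature ladder; after
each sweep, neighbouring-temperature pairs (alternating even/odd pairings)
swap with probability $\min(1, e^{(E-E')(1/T-1/T')})$.  *Exhaustive
oracles* close the loop: `exact_solve()` enumerates all states in gray-code
order, `ground_truth_minimum()` enumerates self-avoiding walks,
`lattice_fold_minimum()` enumerates chain placements on a finite lattice
(the feasible space of the coordinate models), and `turn_space_exact()`
enumerates turn assignments with interaction and slack variables set to
their conditional optima.

## Diagnostics

The *spin-overlap distribution* $P(q)$, $q = \frac1n \sum_i s^{(1)}_i
s^{(2)}_i$, is estimated from two independent parallel-tempering instances
with identical ladders; after thermalization the overlap of the two
lowest-temperature replicas is recorded every sweep.  Instances whose
histogram peaks (local maxima with mass at least 5% of the maximum bin, bin
width 0.02 — both exposed in the API, since "peak" has no canonical
definition) all lie at $|q| > 0.5$ are classified *thin-barriered*,
otherwise *thick*.  Signed $q$ is kept (no $|q|$ folding).  Coordinate
models produce characteristically discrete, spiky SODs because each one-hot
block contributes only a few admissible overlap values; the tests assert
the support is a small set of grid values $(n - 2m)/n$.  Full-scale
estimation settings (hundreds of temperatures, $10^6$-sweep thermalization)
are accepted through `pt_config()`, while tests run desk-scale
configurations.

*Time-to-solution* is $TTS = \tau \log(1-0.99)/\log(1 - p_{ground})$ with
the conventions $TTS = \tau$ for $p \ge 0.99$ and $\infty$ at $p = 0$;
`optimize_tts()` scans a schedule grid because the metric is only meaningful
at its per-size optimum.  $\tau$ is measured in hardware-independent work
units (sweeps × variables); wall-clock comparisons are out of scope.
*QUBO metrics* report the resource quantities used to compare encodings:
variable count, coupling-matrix density, mean couplers per qubit, and
coupler resolution $\max|Q_{ij}| / \min_{\ne 0}|Q_{ij}|$.

## Synthetic data

`generate_dataset()` emulates the benchmark protocol: uniform random
sequences over the 20 amino-acid alphabet (or H/P), each with its nested
prefixes from length 4 up to the full length, no post-selection for unique
minima, fully determined by one seed.  The defaults (100 instances of
length 10, prefixes 4..10) match the stated benchmark conditions.  What the
generator does *not* emulate: real protein sequences (no composition bias,
no structure), real contact energetics (the MJ values are not bundled; HP is
the shipped potential), and hardware effects (embedding, noise).  A green
test on this data therefore establishes the correctness of encodings,
reductions and solvers on the stated model — not biological realism.

## Numerical conventions and limitations

* Energies are dimensionless, $k_B = 1$; penalties are integer-valued for HP
  inputs so oracle comparisons use a $10^{-9}$ absolute tolerance.
* Site and variable orderings are deterministic (lexicographic /
  sublattice-major), ties in the reduction pair choice break to lowest
  indices, and all randomness flows from explicit seeds.
* Enumeration guards: 10 beads (cubic SAWs), 14 (diamond SAWs), 24 variables
  (exact solver), 9 free turns (turn space); all overridable.
* The turn-based cubic model's overlap constraints grow quickly (a squared
  degree-4 polynomial per even-separation pair); encoding beyond N ≈ 10–16
  becomes expensive, mirroring the scaling wall of the construction itself.
* Quantum-annealing hardware, minor embedding, chain strength and
  chain-break repair are out of scope.
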