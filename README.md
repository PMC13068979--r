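# latticefold

Coarse-grained lattice protein folding as binary optimization, in R.

## The scientific problem

Predicting a protein's fold from its sequence can be coarse-grained onto a
lattice: each residue becomes a bead, consecutive beads occupy adjacent
sites, beads may not overlap, and the energy of a fold is the sum of contact
energies ε(aᵢ, aⱼ) over non-bonded bead pairs (|i − j| ≥ 3) on adjacent
sites — the HP potential (ε(H,H) = −1, else 0) or any 20×20
Miyazawa–Jernigan-style matrix loaded from CSV.  Minimising this energy is
NP-complete, which makes it a natural target for annealing heuristics and
quantum annealers — *if* it can be written as quadratic or higher-order
unconstrained binary optimization (QUBO/HUBO),

```
min_b Σᵢⱼ bᵢ Qᵢⱼ bⱼ          (QUBO, bᵢ ∈ {0,1})
H = Σ Jᵢⱼ sᵢsⱼ + Σ hᵢ sᵢ     (equivalent Ising form, bᵢ = (1+sᵢ)/2)
```

This package is for people who study such formulations: it implements the
four standard encodings of the lattice folding problem and everything needed
to compare them honestly.

* **Encodings** — coordinate-based (one-hot site registers per bead, natively
  2-local) and turn-based (bond directions, locality up to 8) on the
  simple-cubic and the tetrahedral *diamond* lattice (two interleaved FCC
  sublattices, 4 neighbours per site): `encode_coordinate()`,
  `encode_turn_cartesian()`, `encode_turn_tetrahedral()`.
* **Quadratization** — iterated Rosenberg substitution
  α(b₂b₃ − 2b₄(b₂+b₃) + 3b₄) with a worst-case α = 1 + Σ|c| that provably
  conserves the energy landscape: `reduce_to_quadratic()`.
* **Solvers** — simulated annealing (exponential cooling T ← ζT, probe-based
  start temperature, graph-coloured sweeps), parallel tempering (geometric
  ladder, swap probability min(1, e^{(E−E′)(1/T−1/T′)})), and exhaustive
  oracles for every space involved (all states, all self-avoiding walks, all
  lattice chain placements, all turn assignments).
* **Diagnostics** — spin-overlap distributions P(q) with thin/thick barrier
  classification (all peaks at |q| > 0.5 ⇒ thin), time-to-solution
  TTS = τ·log(0.01)/log(1 − p_ground), and QUBO resource metrics (qubits,
  density, couplers/qubit, coupler resolution).
* **Decoding** — bitstrings back to folds with feasibility flags;
  self-intersecting folds are first-class results, because the turn-based
  tetrahedral model famously admits them at ground-state energy
  (`demonstrate_overlap_flaw()`).

## Worked example

Encode a 6-mer on the minimal cubic grid, anneal it, and check against the
exact self-avoiding-walk oracle:

```r
library(latticefold)
seqA <- "HPPHPH"
enc <- encode_coordinate(seqA, min_grid(6, "cartesian"),
                         penalties = default_penalties(seqA, hp_interaction(),
                                                       "worst_case"))
enc
#> <encoded_model> coord_cartesian, N=6, 81 variables, degree 2

sa <- simulated_annealing(enc, anneal_schedule(t0 = 3, zeta = 0.999, sweeps = 2000),
                          n_repeats = 50, seed = 1)
sa$best_energy                                  # -2
ground_truth_minimum(seqA, "cartesian")$energy  # -2  (exact oracle agrees)

decode_solution(sa$best_assignment, enc)
#> <decoded_solution> model energy -2, contact energy -2; onehot TRUE, connected TRUE, self-avoiding TRUE

qubo_metrics(enc)
#> <qubo_metrics> 81 qubits, density 0.4123, 32.99 couplers/qubit, resolution 6
```

The best energy −2 means the annealer found a fold with both eligible H–H
contacts; all feasibility flags are clean, so the model energy *is* the
physical contact energy.  The resource metrics are the quantities one
compares across encodings before attempting a hardware embedding.

The structural flaw of the turn-based tetrahedral model — overlaps are only
penalised near active interactions — reproduces on an 11-mer:

```r
demonstrate_overlap_flaw("HPPPPHPPPPH")
#> <overlap_flaw_report> minimal energy -2: 8 valid and 8 self-intersecting minimisers kept (of 16 total)
```

Exhaustive turn-space search finds valid and self-intersecting folds *at the
same minimal energy*: the model's ground state is degenerate between
physical and unphysical conformations.

## Command line

```sh
Rscript inst/cli/latticefold.R gen-dataset --n 100 --length 10 --seed 7 --out ds.fasta
Rscript inst/cli/latticefold.R encode --model coordt --seq HPPHPH --out model.json
Rscript inst/cli/latticefold.R solve-sa --model model.json --sweeps 2000 --repeats 50 --out samples.json
Rscript inst/cli/latticefold.R decode --model model.json --samples samples.json --out report.json
```

Subcommands: `gen-dataset`, `encode`, `reduce`, `solve-sa`, `solve-pt`,
`solve-exact`, `sod`, `metrics`, `tts`, `decode`, `flaw-demo`.

## Further reading

The methods vignette (`vignettes/lattice-folding-models.Rmd`) documents the
model algebra (distance functions, interaction brackets, slack encodings),
the penalty-weight analysis (why λ₁ ≫ λ₂ is required on the tetrahedral
lattice), solver conventions, the diagnostics' definitions, and what the
synthetic benchmark data does and does not establish.
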