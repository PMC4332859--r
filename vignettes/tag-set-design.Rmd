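---
title: "Designing edit-distance DNA tag sets with edittags"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing edit-distance DNA tag sets with edittags}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The design problem

In multiplexed sequencing every DNA fragment carries a short
oligonucleotide tag (barcode) identifying its sample of origin.
Synthesis, amplification and sequencing introduce substitutions as well
as insertions and deletions, so two tags that are merely *different* are
not enough: a single error must not turn one tag into something closer
to another sample's tag. Tags separated by Hamming distance protect only
against substitutions; separating them by **Levenshtein edit distance**
`d` — the minimum number of single-base insertions, deletions or
substitutions converting one word into the other — also covers indels.

Formally, a tag set is a subset `S` of the 4^n words of length `n` over
{A, C, G, T} such that every pair `u, v` in `S` satisfies `E(u, v) >= d`.
The quantity driving the search is the **tag-tag edit distance**

    TTE(u) = min over v in S, v != u, of E(u, v)

a candidate may join `S` exactly when `TTE(u) >= d`. Larger sets for
given `(n, d)` are better: the achieved size is a constructive lower
bound on the optimal code size.

On top of the distance code, practical tags obey biochemical side
constraints, bundled here in a `constraint_profile()`:

* **GC content.** `range` mode keeps each tag's GC percentage inside an
  inclusive window (default 40-60%), the loose rule most designers use.
  `fixed` mode pins every tag to exactly `floor(n/2)` G/C bases. The
  fixed count is the sharper rule: GC content is the first-order
  determinant of duplex stability, so pinning the count compresses the
  melting-temperature spread of the set. For n = 4, 6, 8 the two rules
  coincide (the only GC fraction inside 40-60% is 50%); for odd n and
  n = 10 the fixed count is strictly stronger.
* **Continuity.** The longest homopolymer run in any tag is capped
  (default 2); runs destabilize the molecule and are a classic
  sequencing error mode.
* **Complementarity.** `self` excludes tags equal to their own reverse
  complement (palindromes that fold back or self-dimerize). `cross`
  additionally forbids any tag equal to the reverse complement of any
  other tag in the set, which blocks tag-tag hybridization across
  samples in a pooled reaction. The self rule is the diagonal case of
  the cross rule, so `cross` implies `self`. "Complement" throughout
  means the reverse complement with both strands written 5'→3', as the
  involution `GTCAA <-> TTGAC` shows.

`design_profile()` packages the three bundles used by the experiment
harness: `range_gc`, `fixed_gc` and `cross_comp`.

## The greedy-closure genetic algorithm

`evolve()` maintains two collections: a population of `k` candidate
words being evolved, and the growing result set `S`. The fitness of an
individual is its TTE against `S` (to be maximized), with a **lethal
filter**: any individual violating a single-tag rule of the profile —
GC, homopolymer cap, self-complementarity, or (in cross mode) being the
reverse complement of a set member — scores 0. Against an empty set the
TTE is vacuously unconstrained and scored as `Inf`.

One generation consists of:

1. **Greedy closure.** Every individual with fitness `>= d` is appended
   to `S`, scanning in population order. After each append the
   remaining candidates are re-validated against the enlarged set, so
   two near-identical qualifying candidates in one generation can never
   both enter: the emitted set passes `validate_set()` by construction,
   for every configuration.
2. **Selection.** `ceiling(0.10 k)` binary tournaments, contestants
   drawn uniformly with replacement, higher fitness wins, ties split
   uniformly.
3. **Crossover.** Winner pairs recombine with probability 0.45 by
   three-point crossover: three distinct cut positions among the `n - 1`
   internal boundaries, alternating segments exchanged.
4. **Replacement.** The offspring displace the lowest-fitness
   individuals; the rest of the population carries over (steady state).
5. **Mutation.** Every individual (except the incumbent best, an
   elitism of one) mutates per base at a dynamic rate: 0.01 above the
   population-mean fitness, 0.03 at the mean (tolerance 1e-9), 0.3
   below it. A mutated base always changes (uniform over the other
   three). `Inf` fitness values are excluded from the mean and receive
   the gentle 0.01 rate.

Two globalization devices frame the run. The initial population is
placed **equidistantly** over the whole word space (indices
`floor(i * 4^n / k)` under the base-4 codec A=0, C=1, G=2, T=3), giving
coverage no uniform random draw matches. And when the result set has
not grown for `g_stall = 20` consecutive generations the population is
re-initialized uniformly at random — once per run, since repeated
restarts would erase convergence late in the run. The first member of
`S` is the first individual, scanning from a seeded random offset, that
passes the single-tag rules; requiring those rules at the seed is what
makes the closure property unconditional.

### Design choices that were genuinely open

* **Replacement policy.** The alternative we evaluated — regenerating
  the entire population each generation from the ~10% tournament
  winners — funnels every generation through ~50 parents and rapidly
  abandons the equidistant coverage. Head-to-head under identical
  budgets the steady-state policy produced consistently larger sets
  across the (n, d) grid and found the rare high-`d` configurations far
  more often, so it is the package's policy. The stated tournament
  parameters (size 2, repetitions 10% of the population) and mutation
  schedule are identical under both readings.
* **Population size at small n.** The default population (500) exceeds
  the 256-word space at n = 4; `evolve()` caps the effective population
  at `4^n` (the equidistant initialization is then the full
  enumeration), keeping one default configuration valid across the
  grid. `init_population_even()` itself treats `k > 4^n` as infeasible.
* **Offspring fitness for the mutation schedule.** A child's fitness is
  unknown until the next evaluation; for rate-classing it inherits the
  fitness of the parent it derives from.
* **Re-initialization trigger.** "Premature convergence" is detected as
  result-set stall (no growth for `g_stall` generations) — a checkable
  rule serving the stated purpose; the trigger and its threshold are
  config fields.

All randomness flows from `ga_config(rng_seed=)`; identical seed and
configuration reproduce the result set and per-generation log
bit-for-bit. `run_experiments()` repeats `evolve()` with seeds
`rng_seed + 0 .. runs - 1` and reports the maximum — set sizes from a
stochastic designer are only meaningful as best-of-`runs`, and the
published grid values this package is compared against are maxima over
100 runs.

## Baselines and oracles

`greedy_lexicode()` is the classical deterministic construction: scan
all 4^n words in lexicographic order (A < C < G < T), keep every word
compatible with the kept set. It is strong exactly where the GA is
weak — low `d`, where the optimal sets are large, structured families
that reward an exhaustive ordered scan — and it is deterministic, so it
anchors the comparison harness (`reproduce_table()`).

`brute_force_optimum()` gives the exact maximum for `n <= 5`: the
single-tag-valid words form the vertices of a compatibility graph
(edges join words at distance `>= d` that are not mutual reverse
complements when the cross rule is on) and a maximum clique — igraph's
exact branch-and-bound search — is the optimum. The sandwich
`greedy <= GA-best <= optimum` is asserted in the tests; at n = 4 under
the range-GC profile the GA's best-of-25 attains the exact optimum of
the 256-word space.

## Nearest-neighbor melting temperature

`melting_temperature()` implements the two-state nearest-neighbor
model: summing stack enthalpies and entropies over consecutive
dinucleotides plus terminal initiation terms,

    Tm = dH / (dS + R ln(CT/4)) - 273.15

with the packaged unified parameter table (`inst/extdata/
nn_unified.json`; 10 unique Watson-Crick stacks, the other 6 read
through their reverse complements), `R = 1.987` cal/(mol K), total
strand concentration `CT = 0.25 uM`, and 50 mM Na+ applied as the
entropy salt correction `0.368 (n-1) ln[Na+]`. The `CT/4` form assumes
non-self-complementary duplexes; valid designed sets contain none, and
scoring a palindromic tag warns. The parameter file and both
concentrations are swappable (`thermo_model()`), because reaction
conditions move absolute Tm values by many degrees — which is why this
package treats per-set `tm_gap()` (max Tm minus min Tm, smaller is
better for uniform pooled hybridization) as the meaningful quantity and
makes no claim about reproducing absolute published Tm-gap tables whose
conditions are not stated. The reproducible claim is the trend: under
the fixed-count GC rule the mean Tm gap of random valid sets is lower
than under the range rule, which the test suite checks over 50 paired
seeded sets.

## The fixture generator

`generate_fixture_set()` rejection-samples seeded random tags under the
single-tag rules (optionally also the pairwise distance rule), and can
plant a violation — a reverse-complement pair or a duplicate — for
validator tests. It emulates the combinatorial structure of designed
sets only: uniform random membership, no sequencing error process, no
primer/adapter context, no synthesis bias. Tests built on it therefore
certify the constraint mathematics and the designers, not performance
on any real sequencing library.

## Problem sizes in the shipped tests

The suite keeps runtimes at desk scale by choice: oracle equivalence is
exhaustive for two-letter words up to length 5 and sampled (200 pairs,
length <= 8) over the full alphabet; closure is asserted over the
(n, d) grid {4..8} x {3..6} at reduced population/generations (the
property is exact, not stochastic, so any budget must satisfy it); the
stochastic grid comparisons use n <= 7 with 5 runs per cell and
the two hard n = 10 cells use up to 50 seeded runs of the full study
configuration (population 500, 200 generations). The full-scale
low-`d`, n = 10 cells (set sizes in the thousands) are supported by the
same code but are multi-hour computations and are not exercised.

## Known limitations

* Best-of-`runs` values at high `d` are extreme-value statistics: at
  n = 10, d = 8-9 most runs' greedily chosen first pair admits *no*
  third/fifth companion anywhere in the valid pool, so per-run success
  is a few percent and reported maxima fluctuate with the seed set.
* The GA does not dominate the lexicode everywhere; at low `d` the
  exhaustive ordered scan wins, and the honest comparison is per-cell.
* Thermodynamic absolute values inherit the parameter-set and
  condition choices above; only set-internal spreads are comparable
  across tools.
* `brute_force_optimum()` is exponential and deliberately refuses
  n > 5; `greedy_lexicode()` refuses n > 12 unless forced.
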