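---
title: "Estimating viral richness and genome length from contig spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating viral richness and genome length from contig spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virospectra)
```

## The problem

Most viruses in an environmental sample have no close relative in any
reference database, so the standard ecological questions — how many viral
genotypes are present (richness $M$), how evenly abundance is spread over
them, and how large their genomes are on average ($L$) — cannot be answered
by mapping reads to references. What a shotgun metavirome does provide,
after assembly, is the **contig spectrum** $(C_1, C_2, \dots)$: $C_q$
counts the contigs built from exactly $q$ reads. Deeply sampled, abundant
genotypes produce large contigs; rare genotypes produce singletons. The
shape of the spectrum therefore carries information about the underlying
community, and `virospectra` extracts it by fitting a generative model of
contig formation — jointly over richness, average genome length, the
rank-abundance law and its shape parameter, with no database input.

## The model

A community of $M$ genotypes has relative abundances $f_1 \ge f_2 \ge
\dots \ge f_M$ drawn from one of four candidate rank-abundance laws with
shape parameter $d \ge 0$:

* power law: $f_i \propto i^{-d}$
* exponential: $f_i \propto e^{-i d}$
* logarithmic: $f_i \propto (\log(i+1))^{-d}$
* lognormal: $f_i \propto e^{m_i d}$, where $m_i$ is the mean of the
  $i$-th of $M$ equal-probability slices of the standard normal

All four reduce to the uniform community at $d = 0$. Community evenness is
the normalised Shannon entropy $-\sum_i f_i \ln f_i / \ln M$.

Sequencing is modelled as classical uniform shotgun coverage
(Lander–Waterman statistics). With $R$ total reads of length $r$ and a
minimum assembly overlap of $o$ bp, a read from genotype $i$ overlaps
another read of the same genotype with probability

$$p_i = 1 - \exp\left(-(r - o)\, f_i\, R / L\right),$$

and the expected number of reads found in contigs of exactly $q$ reads is

$$E_q = \sum_{i=1}^{M} f_i\, R\, q\, p_i^{q-1} (1 - p_i)^2,$$

with variance
$V_q^2 = \sum_i f_i R\, q\, p_i^{q-1}(1-p_i)^2\,
\bigl(1 - q\, p_i^{q-1}(1-p_i)^2\bigr)$.
Summing $E_q$ over all $q$ recovers $R$ exactly — every read lies in
exactly one contig — which the test suite verifies to $10^{-6} R$ in
coverage regimes where $p_i$ stays bounded away from 1. (When some
$p_i \to 1$ the model places its mass at expected island sizes far
beyond $R$ reads, and the truncated sum to $q = R$ legitimately falls
short: the model is a Poisson-coverage approximation that ignores the
finite read supply.)

The fit criterion is the variance-weighted residual

$$S(M, L, T, d) = \sum_{q=1}^{q_{\max}}
   \frac{(O_q - E_q)^2}{V_q^2}, \qquad O_q = q\, C_q,$$

summed to the largest $q$ with a non-zero observed count (real spectra are
empty far below $q = R$; appending empty bins does not change $S$). A
perfect model has $S = 0$, and perturbing one bin by one standard
deviation raises $S$ by exactly 1 — the calibration the tests assert.

## The search

$S$ is highly multimodal: different $(M, L, d)$ combinations can mimic one
another's spectra, and the attraction basin of the global minimum can be
very narrow in $L$ and $d$. The optimiser therefore *niches* the search
twice before optimising:

1. over the four candidate laws, and
2. over `N_L` overlapping genome-length windows of constant width
   $W_L = 2(L_{UB} - L_{LB})/(N_L + 1)$, spaced half a window apart, so
   every length value interior to the bounds is covered twice and never
   sits only on a window edge. (The window recursion is anchored at
   $W_{sp}(1) = L_{LB}$; the last window then ends exactly at $L_{UB}$.)

Each of the $4 N_L$ subspaces is discretised — $d$ in steps of 0.01, $M$
in steps of $10^{\lceil\log_{10} M_{UB}\rceil - 2}$ when
$\log_{10} M_{UB} > 2$, $L$ in steps of $0.025\, W_L$ — and searched with
an integer-coded genetic algorithm: tournament selection (k = 3), uniform
crossover (rate 0.8), per-gene geometric-step mutation (rate 0.1),
elitism, random immigrants (15% of the population per generation) and
early stopping after a stagnation patience. The GA population is seeded
from a deterministic coarse sweep: every $d$ value is scored at a few
$(M, L)$ anchors, the most promising $d$ columns are then scanned across
the full $L$ axis, and the best sweep points enter the initial
population. The sweep exists because the shape axis is the least
forgiving: good fits live in narrow $d$ columns that random initial
populations reliably miss, while within the right column the residual
decreases smoothly in $L$ and the GA descends easily. Subspaces with at
most 5000 grid points are enumerated exhaustively instead — at that size
enumeration costs about a second and guarantees the exact discrete
optimum, so a stochastic search has nothing to offer. All GA settings
are exposed in `search_spec()`.

The best of the $4 N_L$ subspace winners (ties broken by smaller $S$, then
smaller $M$ — parsimony — then smaller $L$, then the fixed law order
pl < exp < log < lgn) is then **refined**: a subspace centred on the
winner is re-searched with the $M$ and $L$ steps halved each round, down
to unit steps, with $d$ held on its 0.01 grid. While the $M$ step is
coarse the whole $M$ axis is rescanned rather than a local window,
because the residual is nearly flat in $M$ once $d \cdot M$ is large (the
abundance tail underflows) and a purely local window can strand the
search far from the parsimonious optimum on such a plateau. Refinement
never increases $S$; small refinement grids are enumerated exhaustively,
so the final result is a local minimum of the unit-step grid.

Reproducibility: one master seed deterministically spawns per-subspace
child seeds indexed by (law, window), so subspace searches are
order-independent and the whole fit is bit-reproducible
(`fit_virome()` twice with the same `search_spec()` gives identical
solutions).

### Fixed-length mode

`fit_virome_fixed_length()` pins $L$ (the situation of database-assisted
estimators that are handed a genome-length estimate) and fits only
$(M, T, d)$, niched over the laws. With $L$ fixed at the joint estimate's
value it returns the joint fit's $(M, T, d)$.

### Degeneracy at maximal evenness

At $d = 0$ every law gives the uniform community and the spectrum depends
on $(M, L)$ only through $M/L$-type compounds; a maximally even fit is
therefore reported with a multiple-minima warning rather than treated as
a unique optimum.

## The simulator

`simulate_population()` generates ground-truth communities under the
benchmark conditions: abundances from the chosen law, genome lengths
either all equal to $L_0$ (scenario 1) or i.i.d.
$N(L_0, (L_0 v)^2)$ rounded to integer bp (scenario 2), where $v$ is the
coefficient of variation; draws at or below the read length are redrawn,
a truncation that is negligible at the benchmark's $v \le 0.1$.
`montecarlo_contig_spectrum()` then places reads multinomially over
genotypes (so $\sum_q q C_q = R$ exactly), uniformly along each linear
genome, and chains reads whose start positions differ by at most $r - o$
— the island rule matching the $r - o$ effective length in $p_i$.
`expected_contig_spectrum()` instead returns the noiseless model
expectation $(E_1/1, E_2/2, \dots)$, the canonical input for
parameter-recovery experiments since its generating parameters are the
exact global optimum with $S = 0$.

Sequencing defaults ($R = 10^4$ reads, $r = 100$ bp, $o = 35$ bp) follow
the standard contig-spectrum pipeline settings; the benchmark grids are
available as `scenario_presets(1)` (richness × genome length × the four
law/shape pairs, fixed lengths) and `scenario_presets(2)`
($v \in \{10^{-4}, \dots, 0.1\}$, power law only, $L_0 = 50$ kbp,
$M_0 \in \{300, 10^4\}$).

What the simulator deliberately does not model: sequencing error,
paired-end constraints, read-length variation, chimeras, or
de-Bruijn-graph assembly artefacts. Passing recovery tests on simulated
spectra therefore demonstrates correctness of the estimator under the
model's own assumptions, not robustness to real-world assembly noise.

## Numerical choices

* Abundance laws are evaluated as log-weights with max-subtraction, so
  large $d M$ cannot overflow; weights that underflow to zero at extreme
  shapes contribute zero entropy to evenness.
* The lognormal bin boundaries satisfy an inverse-error-function
  recursion that telescopes to $t_i = \Phi^{-1}((i-1)/M)$; the closed
  form is used since it carries no accumulated error at large $M$
  (agreement with the literal recursion is ~$10^{-9}$ at $M = 5000$).
* $p_i$ is computed via `expm1`; powers $p_i^{q-1}$ by cumulative
  multiplication per genotype in compiled code, with the per-genotype
  series truncated once terms fall below $10^{-13}$ and are decreasing —
  far below the resolution of count data.
* Zero-variance bins: where $V_q^2 \le 10^{-12}$ and $O_q = 0$ the bin
  contributes nothing; where the model says "impossible" but a count was
  observed, the variance floor $10^{-12}$ keeps the penalty finite.
* The variance factor $1 - q p^{q-1}(1-p)^2$ is clamped at 0 from below
  as a guard (analytically it stays in $[0, 1]$).
* Exact cost ties in enumeration resolve to the smallest $M$, then
  smallest $L$, then smallest $d$ (parsimony).

## Problem sizes in the shipped checks

The package's own checks run the full analytic and calibration suites at
benchmark scale, a complete joint recovery on the noiseless
$(L = 12500, M = 300, \text{exp}, d = 0.030)$ spectrum over the full
benchmark bounds ($M \in [1, 15000]$, $L \in [10000, 310000]$ bp,
$d \in [0.01, 5]$, $N_L = 29$, all four laws) with a moderate GA budget
(population 40, 120 generations, patience 20 — the seeded sweep makes
larger populations unnecessary for basin capture), a four-dataset
fixed-length recovery suite, 25 oracle-equivalence trials on small
subspaces, and a 500-replicate Monte-Carlo validation of the expected
spectrum. The full published benchmark grids (the 64-dataset scenario-1
sweep, the 16-dataset fixed-length table, ten replicates per cell of
scenario 2) are reproducible with `scenario_presets()` plus the
`benchmark` CLI subcommand as long-running jobs.

## Known limitations

* The model assumes a single average genome length; communities with
  several distinct dominant lengths violate it, and under genome-length
  variation the estimator is reliable only for small coefficients of
  variation ($-\log_{10} v > 2$).
* The estimate of $L$ degrades above roughly 100 kbp, where the spectrum
  carries little length signal at typical read depth.
* Contig formation is modelled for greedy overlap assembly of linear
  genomes; spectra from de-Bruijn assemblers are outside the model.
* At maximal evenness the parameters are not identifiable (see above).
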