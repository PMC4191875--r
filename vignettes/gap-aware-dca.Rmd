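---
title: "Gap-aware direct coupling analysis: models, inference and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gap-aware direct coupling analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapdca)
```

## The model

A multiple sequence alignment of `B` homologous proteins over `N` aligned
columns is treated as a sample from a distribution over 21-state strings
(20 amino acids plus the gap symbol, encoded 1–20 and 0). The base model is
the Potts model

$$P(a) \propto \exp\Big(\sum_i h_i(a_i) + \sum_{i<j} J_{ij}(a_i,a_j)\Big),$$

whose pairwise couplings $J_{ij}$, once scored appropriately, predict
residue–residue contacts. The package's distinctive extension adds
*gap-run propensities*: for every maximal run of $l$ consecutive gaps
beginning at column $i$ the energy gains a term $g_i^l$, activated by an
indicator on the sequence. This targets a concrete failure mode of the
plain model: aligners produce long shared gap stretches (domain
insertions/deletions), which are combinatorially implausible under a
pairwise model and therefore get absorbed into strong — but spurious —
couplings concentrated in the gap-rich region. With the $g_i^l$ present,
the stretch statistics are explained by at most $N \cdot L$ extra
parameters instead.

The meta-parameter $L$ is the longest gap run observed in the alignment in
question (`alignment_max_gap_run()`); runs longer than $L$ carry no
parameter. Two consequences worth noting: the parameter set adapts to the
data, and on a gap-free alignment $L = 0$, so the gap-extended fit is the
plain fit *bit-exactly* — a property the test suite asserts.

## Inference

Exact likelihood is intractable (the normalizer sums $21^N$ terms), so the
package maximizes the asymmetric pseudo-likelihood: for each column $r$
independently, the weighted conditional log-likelihood of $a_r$ given the
rest of the row, plus L2 penalties,

$$\ell_r = -\tfrac{1}{B_\mathrm{eff}}\sum_s w_s \log P(a_r^s \mid
a_{\setminus r}^s) + \lambda_h\lVert h_r\rVert^2 +
\lambda_J\sum_i\lVert J_{r,i}\rVert^2 + \lambda_g\lVert g\rVert^2 .$$

The conditional of site $r$ sees exactly three gap-run terms per row: with
$\lambda$ gaps immediately left and $\rho$ immediately right of $r$, a gap
at $r$ activates the merged run $g_{r-\lambda}^{\lambda+\rho+1}$, while a
non-gap leaves the flanking runs $g_{r-\lambda}^{\lambda}$ and
$g_{r+1}^{\rho}$. Per conditioned site, only the (start, length) pairs
reachable this way from some data row — and not longer than $L$ — carry
free parameters; all others are pinned at zero by the penalty anyway. Gap
parameters are per-site nuisance parameters: they are reported
(`$site_gap_params`) but never merged across sites and never scored.

Defaults: $\lambda_h = \lambda_J = \lambda_g = 0.01$ on the
$B_\mathrm{eff}$-normalized objective (`reg_config()`). Sequence weights
are $w_s = 1/n_s$ with $n_s$ the number of sequences at least 90% identical
to $s$ (threshold argument `threshold_x = 0.1`, identity counted over all
21 states, self included).

### Numerical choices

* Each site objective is minimized by L-BFGS-B from **zero
  initialization** with gradient max-norm tolerance `1e-5`, a tight
  relative-change factor (`factr = 1e4`) and a 500-iteration cap. Zero init
  plus a deterministic optimizer makes every fit reproducible without
  seeds, and per-site independence makes serial and parallel execution
  bit-identical (`cores` uses forked workers).
* The objective and its exact analytic gradient are computed in C++; the
  gradient is validated against central finite differences in the tests.
* Duplicate rows are collapsed to (pattern, summed weight) pairs before
  fitting; the objective is unchanged.
* The two directed estimates of each pair block are averaged
  ($J_{ij} = (J^{(i)}_{ij} + J^{(j)\top}_{ji})/2$) and then explicitly
  projected to the zero-sum gauge (every row and column of every block sums
  to zero); the L2 penalty only enforces that gauge approximately at finite
  $\lambda$. The projection is idempotent and linear.
* Degenerate inputs: all-zero weights raise an error; non-finite parameters
  raise an error; an all-zero score matrix passes through the APC guard
  unchanged rather than dividing by zero.

## Scoring

Contacts are ranked by the Frobenius norm of the gauge-fixed blocks with
the average product correction,
$CN_{ij} = FN_{ij} - FN_{i\cdot}FN_{\cdot j}/FN_{\cdot\cdot}$, means taken
over off-diagonal entries (the APC literature's convention; the diagonal is
undefined). Two variants:

* `fn21` — the full $21\times 21$ block (plmDCA / gplmDCA scoring);
* `fn20` — the same block restricted to the amino-acid $20\times 20$
  submatrix, *without re-gauging*: the gap couplings are discarded only
  after gauge fixing, so gap observations still inform the retained
  entries. This is the plmDCA20 variant.

Pairs closer than 5 positions along the chain are excluded, and ties break
lexicographically on (i, j) so rankings are bit-reproducible.

`decimate_fit()` optionally iterates: fit, rank blocks by current APC
score, freeze the weakest `fraction_per_round` (default 0.1) of still-active
blocks at exactly zero, refit. Masks are monotone across rounds and whole
$21\times 21$ blocks are masked, not single entries — the block is the unit
that predicts a contact. `rounds = 0` (the default) reproduces the plain
fit exactly.

## Benchmarking

`contact_map_from_structure()` extracts truth from a PDB file under two
criteria: Cβ–Cβ distance ≤ 8 Å (Cα substitutes for glycine, the universal
convention) or minimum heavy-atom distance ≤ 8.5 Å. MODEL 1 is used for
multi-model files and the highest-occupancy conformer for alternate
locations. The column→residue mapping is an explicit two-column input;
aligning sequences to structures is out of scope, so real-structure
benchmarks are user-supplied while synthetic fixtures carry identity
mappings. Residues missing from the structure are *unresolved*: pairs
touching them are skipped by `ppv_curve()` without consuming a rank
position, so missing density neither helps nor hurts. PPV is true positives
over predictions among the top $n$, at absolute $n$, at fractions of the
length (default grid 0.1–2.0 of $N$), and summarized at $L/5$, $L/2$, $L$.
`weighted_moving_average()` smooths PPV-versus-covariate curves with
arithmetically decreasing weights ($w, w-1, \dots$ from the center,
truncated at boundaries).

## What the synthetic generator emulates — and what it does not

The generator provides ground truth where real data cannot:

* `make_planted_model()` plants `n_pairs` coupling blocks between columns
  at separation ≥ 5. Each block seeds `block_sparsity = 4` random ±1 cells,
  is projected to the zero-sum gauge and rescaled to Frobenius norm
  `coupling_strength = 5`. Concentrating the interaction on a few
  residue-pair combinations mirrors real contact energetics (salt bridges,
  hydrophobic packing favour specific pairings); spreading the same norm
  uniformly over all 441 cells produces per-cell effects so weak that no
  method — not a defect of this one — can separate them from sampling noise
  at realistic depths. Planting directly in the inference gauge makes
  generation truth and fitted couplings directly comparable.
* `sample_msa_gibbs()` draws rows from a single Gibbs chain (burn-in 100
  sweeps, thinning 10, both configurable), using the same conditional
  machinery that the inference validates against exact enumeration on
  two-site models. Gap propensities are clamped to $|g| \le 10$ to keep the
  chain away from degenerate all-gap attractors.
* `inject_gap_stretches()` overwrites a column range with gaps in a random
  row subset — the footprint of a shared deletion — either over the full
  range or over random-length prefixes.
* `toy_structure_fixture()` emits PDB text whose contact map is known in
  closed form (straight chain: contacts exactly $|i-j|\le 2$ at 3.8 Å
  spacing; hairpin: facing Cβ atoms at 6 Å add long-range contacts).

What passing these tests shows: the estimator recovers planted couplings,
the gap terms absorb stretch artifacts, and every bookkeeping step is
exact. What it does not show: performance on real alignments, which add
phylogenetic correlation between rows (the reweighting heuristic only
approximates independence), alignment errors, and contact geometries far
richer than the toys. The study-scale problem sizes used throughout
(N = 40, 15 planted pairs, B = 2000 for recovery; a 12-column stretch in
40% of rows for the artifact experiments) were chosen as the smallest
instances where the planted signal is comfortably above the noise floor
for a desk-scale run.

## Known limitations

* Gap parameters are per-site nuisance copies; no cross-site consistency is
  imposed (the asymmetric framework has the same property for couplings
  before symmetrization).
* The Gibbs sampler is a single chain; for strongly coupled models mixing
  may require raising `burn_in`/`thinning` (the two-site enumeration test
  is the calibration point).
* Identity for reweighting counts gap–gap matches as matches; alignments
  that are mostly gap can therefore cluster more aggressively than
  amino-acid identity alone would suggest.
* `fn20` inherits the full-model fit; it suppresses gap-driven scores but
  cannot recover signal the gap stretch has already displaced during
  inference — the two variants are complementary, not equivalent.
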