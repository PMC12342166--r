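---
title: "Differential GRN inference by double optimal transport: model, parameters, and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential GRN inference by double optimal transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dotgrn)
```

## The model

`dotgrn` treats the change of a transcriptome between two conditions as a
mass-transport problem. Cellular resources (energy, ribosomes, proteome
capacity) are finite; when a tumor deactivates one pathway and activates
another, expression "mass" effectively moves between gene sets. The package
therefore represents each condition by a probability vector of mean
expression proportions and asks how cheaply the normal-state vector can be
moved onto the tumor-state vector, where moving mass between a pair of genes
is cheap exactly when their expression profiles are strongly related. The
optimal transport plan is then read as a scored, directed network: entry
$(i, j)$ is the evidence for a regulatory influence of normal-state gene $i$
on tumor-state gene $j$.

Three transport problems underpin the package:

* **Classical (balanced) OT** moves all mass, matching both marginals
  exactly. It is the reference problem and the limit of the other two.
* **Robust (unbalanced) OT** replaces the marginal constraints with
  KL-divergence penalties of strength $\varepsilon$:
  $\min_{T \ge 0} \langle C, T\rangle - \eta H(T)
  + \varepsilon KL(T\mathbf{1}\,\|\,a)
  + \varepsilon KL(T^\top\mathbf{1}\,\|\,b)$.
  Soft marginals let noisy or outlying genes carry less mass than their
  nominal share, which is what makes the gene-level step robust to technical
  noise. As $\varepsilon \to \infty$ it recovers classical OT.
* **Partial OT** transports only a fixed budget $s$ of mass under capacity
  constraints $T\mathbf{1} \le a$, $T^\top\mathbf{1} \le b$. With unit
  masses and integer $s$, its linear-programming solution is a 0–1
  pseudo-permutation: exactly $s$ matched pairs, each sample used at most
  once. That is precisely a partial matching, which is why it drives the
  sample-alignment stage.

The published inequality form of the partial budget ($\mathbf{1}^\top T
\mathbf{1} \le s$) admits the useless optimum $T = 0$ for nonnegative costs;
consistent with the pseudo-permutation characterization of its solution, the
package implements the equality budget $\mathbf{1}^\top T\mathbf{1} = s$.

### Two levels

**Gene level.** For paired (or aligned) samples the cost is
$C_{ij} = 1 - |r(x_{(i)}, y_{(j)})|$ with $r$ the Spearman correlation
between gene rows. Rank correlation captures monotone nonlinear and negative
regulation alike and is insensitive to monotone normalization choices (so
log-transformation of expression does not change this stage). The marginals
are mean expression proportions. Solving robust OT yields the score matrix;
`rank_edges()`/`tidy()` order all $p^2$ directed pairs. Self-links are kept:
feedback loops are biologically real, and the transport plan has no
acyclicity constraint.

**Sample level.** When pairing is unknown, all $n + m$ samples are stacked
in gene space, jointly mean-centered, and projected onto the top $r$
right-singular directions; the sample–sample cost is the cosine distance in
that space (scale-invariant, standard for expression profiles). Partial OT
with unit masses and budget $s$ produces a near-binary plan which is
hardened deterministically: argmax along the shorter side, duplicate
targets resolved by descending plan mass, the $s$ heaviest candidates kept
(ties to the lowest index), pairs sorted by normal-sample index. Sorting by
normal index makes an exactly-recovered pairing reproduce the paired
pipeline bit for bit, which the test suite asserts.

## Parameters

| Parameter | Where | Default | Meaning and rationale |
|---|---|---|---|
| `eta` | both solvers | 1e-2 (gene), 5e-3 (sample) | Entropic smoothing (unitless, relative to costs in $[0,2]$). The gene level wants mild smoothing for stability; the sample level wants a sharper, near-binary plan, hence a smaller value. |
| `epsilon` | robust OT | 1 | Marginal-relaxation strength. Because marginals are normalized to proportions, $\varepsilon = 1$ means the KL penalties and the transport cost operate on the same scale regardless of the data's units. |
| `s` | partial OT | 0.8·min(n, m) | Matching budget: values below 1 are fractions of `min(n, m)`, values ≥ 1 are counts. Matching only the most confident 80% avoids forcing matches for samples with no counterpart. |
| `r` | sample PCA | min(50, n+m−1, p) | PC count for the cosine cost. When per-sample variation is spread isotropically over genes, the matching signal occupies many components; a sharp truncation (e.g. 10 PCs) measurably degrades alignment accuracy on the synthetic conditions, so the default is generous and capped only for scalability. |
| `tol` | solvers | 1e-9 (1e-7 alignment) | Convergence tolerance, measured on L1 marginal violation (balanced), marginal change (unbalanced), or plan change plus constraint feasibility (partial). The alignment consumes only the argmax pattern of the plan, so its default is looser. |
| `max_iter` | solvers | 1e4 (2e4 alignment) | Iteration cap; hitting it returns `converged = FALSE` with a warning rather than an error. |
| `normalize_marginals` | gene level | TRUE | Row means normalized to proportions (sum 1). Raw means are available; normalization keeps `epsilon` data-independent. |

The entropy used is $H(T) = -\sum T_{ij}(\log T_{ij} - 1)$, which makes the
$1{\times}1$ robust fixed point exactly $\exp(-c/(\eta + 2\varepsilon))$ —
a closed form the tests verify to $10^{-6}$ — and gives the unbalanced
Sinkhorn scaling exponent $\varepsilon/(\varepsilon + \eta)$.

## Numerical design

* **Log domain.** Whenever the Gibbs kernel $e^{-C/\eta}$ would underflow
  (roughly $\max C/\eta > 500$), all iterations run on log-scaled
  quantities; otherwise the balanced/unbalanced solvers use plain BLAS
  scaling for speed and fall back automatically on non-finite scalings.
* **ε-scaling annealing.** At small `eta` a directly-initialized Dykstra
  iteration can stall: any strictly feasible iterate with idle corrections
  is a floating-point fixed point, and the escape signal scales like
  $e^{-\Delta C/\eta}$. The partial solver therefore anneals `eta`
  geometrically (factor 3 from 0.1 down to the target). Each stage is warmed
  from the previous one by carrying the *dual multipliers*: the converged
  stage solution has the form $\log T = -C/\eta - A_i - B_j + G$, so $A$ and
  $B$ are recovered from row/column means, gauge-fixed by subtracting their
  minima (complementary slackness puts slack rows at zero multiplier),
  rescaled by $\eta_{old}/\eta_{new}$, pre-applied to the new kernel and
  mirrored in the Dykstra corrections. Warming the *plan* instead (powering
  it up) locks in wrong support and is avoided. The balanced solver uses the
  same schedule with carried potentials.
* **Stopping rules.** The partial solver stops only when the plan is both
  stationary and feasible for all three constraint sets; plan change alone
  goes quiet during slow mass redistribution and would stop too early.
* **Exact oracles.** `solve_exact_ot()` is a transportation simplex
  (north-west-corner start, MODI pivoting on the basis tree); no
  linear-programming package is required. `solve_exact_partial_ot()` reduces
  the partial problem to a balanced one with a dummy source and sink. The
  test suite checks both against an independent enumeration of basic
  feasible solutions, and the entropic solvers against the exact oracles
  (objective gaps below 2%, the residual being the documented entropy bias
  $\le \eta\, s\,(1 + \log n_1 n_2)$).
* **Degenerate input.** Zero-mass rows/columns are stripped before solving
  and restored as zero plan rows/columns. Constant gene rows get Spearman
  correlation 0 (cost 1) with a warning naming the genes, rather than an
  error. Ties in ranking are broken by (regulator index, target index), so
  every ranking is deterministic.

## The synthetic generator

`simulate_grn_data()` emulates the study conditions the method is evaluated
under: Gaussian baseline expression $X_{ik} = \mu_i + \xi_{ik}$ with
$\mu_i \sim U(2, 8)$, $\xi \sim N(0, 1)$, truncated at 0; a planted network
in which $\lceil \alpha p\rceil$ DE genes each receive
$1 + \mathrm{Poisson}(\lambda - 1)$ regulators (expected in-degree exactly
$\lambda$, self-parent always included), signed weights with magnitudes
$U(0.5, 1.5)$, and link functions drawn from linear / variance-matched
quadratic / sine; a conditional-Gaussian tumor state in which non-DE genes
keep their baseline up to $N(0, 0.1\,\sigma)$ noise (stable pathways) and DE
genes are rebuilt from their parents' baseline deviations with $N(0, \sigma)$
noise; and an optional uniform column shuffle to create unpaired data with a
recorded ground-truth pairing. One master seed drives independent substreams
for network, baseline, noise and shuffle, so each component can be varied
while holding the others fixed.

The standard regimes used by the tests and the acceptance script are
$p = 50$, $n = 200$, $\alpha = 0.2$, $\lambda = 2$, $\sigma = 0.5$ for
recovery, $p = 100$, $n = m = 40$ for alignment, and $p = 2000$,
$n = m = 100$ for the scalability smoke test — sizes chosen so the whole
suite runs in minutes on one CPU while still exercising the
$O(p^2 \log p + nm\log(n+m))$ scaling regime.

What the generator does *not* emulate: count noise (negative binomial,
dropout), library-size artifacts, batch effects, time-course dynamics, or
indirect/cascading regulation. Passing tests therefore demonstrate that the
two OT stages recover planted monotone conditional dependencies under
Gaussian noise — not that the method resolves direct from indirect
regulation in real tissues; on real data the inferred links are best read as
ranked associations between condition-specific expression states.

## Evaluation conventions

Metrics operate on the full candidate universe of $p^2$ ordered pairs,
including self-links by default (the planted networks contain them); a flag
excludes the diagonal. AUROC is the rank-based Mann–Whitney statistic with
mid-ranks for ties; AUPR uses step-wise summation over descending unique
thresholds with no interpolation (the conservative convention — stated here
because interpolating implementations report systematically higher values);
early precision is the fraction of true edges among the top-$K$ ranked
predictions with $K$ the number of true edges. Undefined metrics (e.g. an
all-positive truth) raise typed errors instead of returning sentinels.

## Known limitations

* Transport mass is evidence of association, not causality; confounded or
  indirect effects can score highly.
* The method ranks links but deliberately does not choose a score threshold
  for a binary network; thresholding is left to the analyst.
* Spearman costs need at least 3 (in practice dozens of) aligned samples;
  with very few samples the cost matrix is dominated by rank noise.
* The exact LP oracles are for verification at small sizes; production runs
  use the entropic solvers.
* Alignment assumes the two cohorts overlap biologically; if many samples
  have no counterpart, lower the budget `s` rather than forcing a full
  matching.
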