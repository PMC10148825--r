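---
title: "Methods: PROMETHEE-II outranking, linguistic elicitation, and sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PROMETHEE-II outranking, linguistic elicitation, and sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promethee2)
```

## The decision problem

The package ranks a set of $m$ alternatives against $k$ criteria from a crisp
decision matrix $C_{ij}$ using PROMETHEE-II, the outranking method that
produces a *complete* ranking from net outranking flows. The bundled case
study is a drug-prioritization problem: nine anti-angiogenic receptor
tyrosine kinase inhibitors ($In_1$–$In_9$; ponatinib through lenvatinib)
scored against three angiogenic growth-factor criteria (GF1 = VEGF,
GF2 = FGF, GF3 = PDGF, weights $0.45/0.35/0.20$), elicited from a 72-expert
panel on a five-level verbal scale.

## The pipeline

**Normalization.** Each criterion column is min–max normalized:
$t_j(z) = \frac{C_{zj} - \min_i C_{ij}}{\max_i C_{ij} - \min_i C_{ij}}$ for
beneficial criteria, and the mirrored form
$\frac{\max_i C_{ij} - C_{zj}}{\max_i C_{ij} - \min_i C_{ij}}$ for cost
criteria, so the best alternative always scores 1 and the worst 0. A
degenerate column ($\max = \min$) would divide by zero; it is set to all
zeros and flagged. That choice encodes indifference — a constant criterion
prefers nothing over anything — and keeps the remaining weights meaningful
instead of crashing.

**Pairwise preferences.** For every ordered pair $(z, y)$ and criterion $j$,
the deviation $w_j(z,y) = t_j(z) - t_j(y)$ is mapped to a preference degree
$P_j(z,y) \in [0,1]$ by a preference function. The default, `paper-linear`,
is the threshold-free linear function $P_j(w) = w$ for $w > 0$ and $0$
otherwise — well-defined because normalized deviations lie in $[-1, 1]$. The
six classical shapes (usual, U-shape, V-shape, level, V-shape with
indifference, Gaussian) are available per criterion via `pf_spec()`; their
thresholds $q$ (indifference), $p$ (strict preference) and $s$ (Gaussian
inflection) are expressed on the normalized deviation scale, so sensible
values lie in $(0, 1)$. All kinds return 0 at $w = 0$: a zero deviation
expresses no preference in either direction.

**Aggregation and flows.** The weighted preference index is
$\pi(z,y) = \sum_j d_j P_j(z,y)$ with $\sum_j d_j = 1$ (weights are
renormalized when needed; `normalize_weights()` accepts vectors already
summing to 1 within $10^{-9}$ silently and otherwise renormalizes with a
notice, so no silent reweighting occurs). Flows average the index over the
$n - 1$ opponents:
$\phi^+(z) = \tfrac{1}{n-1}\sum_{y \ne z} \pi(z,y)$,
$\phi^-(z) = \tfrac{1}{n-1}\sum_{y \ne z} \pi(y,z)$, and
$\phi(z) = \phi^+(z) - \phi^-(z)$. The diagonal $\pi(z,z)$ is excluded from
all sums rather than stored as zero. Conservation
($\sum_z \phi(z) = 0$) holds by construction and is asserted to $10^{-9}$ in
the tests.

**Ranking.** Alternatives are ranked by descending $\phi$ with *competition
ranking*: tied alternatives share the smallest applicable rank and the next
rank is skipped. Identical score rows produce exactly equal flows (the same
multiset of additions), so identical inputs always receive identical ranks —
the package never breaks such ties arbitrarily. Display order of tied
alternatives follows input order.

## Arithmetic modes

`run_promethee2()` offers two modes. `"full-precision"` (default) carries
full double precision end to end and is what the sensitivity and simulation
layers always use. `"paper"` rounds the normalized matrix and the aggregated
preference indices *half-up* to 3 decimals, the convention of hand-worked
decision-analysis tables; it exists to reproduce such tables digit for digit
and is not an analysis device. Half-up rounding (`round_half_up()`) is used
rather than R's round-half-even because printed tables round 0.2625 to 0.263;
a $10^{-9}$ guard absorbs binary representation error so decimal halves round
up reliably. In the case study the two modes agree on the leader but differ
in the third decimal of the flows, e.g. $\phi(In_4) = 0.514125$ (paper mode)
vs $0.513886$ (full precision).

Under paper-mode arithmetic the case-study flows follow exactly from the
aggregated preference table: every $\phi^+$, the column sums giving
$\phi^-(In_5) = 3.839/8 = 0.479875$, and
$\phi(In_6) = 0.426625 - 0.043750 = 0.382875$. With those values lenvatinib
($In_9$, $\phi = 0.420500$) outranks dovitinib ($In_6$, $\phi = 0.382875$),
so the final order is $In_4 \succ In_9 \succ In_6 \succ In_8 \succ In_3
\succ In_7 \succ In_1 = In_2 \succ In_5$, with the identical rows $In_1$ and
$In_2$ sharing rank 7.

## Linguistic elicitation

The five-level scale maps High → 1.000, Average → 0.666, Low → 0.333,
Very Low → 0.250, Null → 0.000; note the deliberately uneven spacing at the
bottom end. Label matching is case-insensitive and whitespace-trimmed for
robustness to hand-edited files. The inverse map `from_crisp()` returns the
nearest scale value with ties broken toward the better label (determinism),
using a $10^{-12}$ tolerance so decimal midpoints such as 0.2915 behave as
ties under binary arithmetic.

Panels are aggregated per cell by `mode` (default), `mean` or `median` of
the crisp-converted responses. Mode is the default because it preserves
membership in the scale — aggregated matrices then look exactly like
single-expert matrices, every cell a scale value, which matches how elicited
matrices of this kind are reported — and mode ties break toward the
higher-valued label, mirroring the `from_crisp()` convention. The raw
72-expert responses behind the bundled case study were never published, so
the case-study fixture enters the pipeline at the decision-matrix stage; the
elicitation layer is exercised by the synthetic generator instead.

## Synthetic panels and what they do (not) show

`panel_spec()` describes the generative model used for validation, with
defaults mirroring the bundled study's shape: 9 alternatives, 3 criteria, 72
experts. Each alternative carries a latent utility (default equally spaced on
$[0,1]$); each criterion reflects the rank-scaled utility through a loading
in $[0,1]$ (default 1; a loading of 0 yields a degenerate column); the true
cell score is the loaded utility snapped to the nearest scale value, so
synthetic matrices are structurally identical to elicited ones. Experts
report the true label, except that with probability `noise` (default 0.1, a
moderate elicitation error rate) the response slips one step up or down the
scale — errors in ordinal elicitation are local, which keeps the noise
parameter interpretable. The direction is chosen with equal probability and
the index clamped at the scale ends, so at an extreme label half of the
noise draws leave it unchanged. One root seed drives everything; replicate
$r$ uses a stream at a fixed offset ($seed + 1000003\,(r-1) \bmod 2^{31}-1$),
so replicates are independent yet individually reproducible.

`recovery_experiment()` scores a replicate as recovered when the pipeline's
ranking contains *no pair strictly discordant* with the latent-utility order.
This quotient-order criterion is deliberate: snapping is non-injective
(utilities 0.75 and 0.5 both snap to 0.666), so distinct utilities can
legitimately tie downstream, and equal utilities produce identical rows that
must tie. With zero noise, positive loadings and this criterion, recovery is
exactly 1 for every seed. Mean Kendall $\tau_b$ (via `rank_agreement()`,
which applies the tie correction) quantifies partial agreement and is
non-increasing in noise over a common-random-number grid: the same uniform
draws decide slips at every noise level, so the slip sets are nested and the
comparison is paired rather than independent.

The generator emulates independent experts with homogeneous error rates and
criteria that are (noisy) monotone views of a single latent quality. Real
panels have correlated experts, heterogeneous expertise, and criteria that
genuinely conflict; passing recovery tests therefore validates the pipeline's
mechanics, not the elicitation design of any particular study.

## Sensitivity analysis

`weight_sweep()` perturbs the base weights over a per-criterion delta grid
(all combinations), renormalizes each vector, and reruns the full-precision
pipeline; `criterion_knockout()` removes one criterion at a time and
renormalizes the survivors *proportionally*, preserving the decision-maker's
relative priorities (equal redistribution would silently change them).
Reports carry each scenario's order, per-alternative rank ranges (always
containing the base rank), and the pairs whose relative order reverses in
some scenario. In the case study the In4/In9 pair reverses under GF3-light
weightings — In9 beats In4 on normalized GF2 (1 vs 0.666) while In4's edge
is GF3 — whereas In5, whose normalized row is all zeros, is weakly dominated
by everything and stays last in every scenario with positive weights.

## Numerical choices and limitations

Problem sizes here are desk-scale ($m \le$ tens), so the implementation
favors clarity: dense $m \times m \times k$ preference arrays, no sparse
structures. Property tests run on random matrices up to $m = 9$ and check
the pipeline against a naive double-loop oracle to $10^{-12}$ for $m \le 5$;
the Monte-Carlo acceptance checks use 200 replicates per noise level, enough
for the paired monotonicity comparison at a 0.02 tolerance. Ties in net flow
are detected by exact floating-point equality — appropriate for identical
rows, but near-ties from distinct inputs are ranked by their computed order,
as in any floating-point sort. PROMETHEE-I partial preorders, GAIA planes,
interval or stochastic scores, hierarchical criteria, expert weighting and
formal weight-stability intervals are out of scope.
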