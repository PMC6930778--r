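---
title: "Screening monotonically expressed genes with network-weighted expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening monotonically expressed genes with network-weighted expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megrank)
```

## The model

`megrank` looks for genes whose expression drifts consistently in one
direction over the course of a treatment — *monotonically expressed genes*
(MEGs) — and interprets each one through its cross-sectional
disease-versus-control direction. The pipeline is a funnel of four stages,
each narrowing the gene set of the previous one:

**Stage 1 — cross-sectional DEGs.** For gene $g$ with group means
$\bar x_{g1}, \bar x_{g2}$ and pooled variance $s_g^2$ on
$d_g = n_1 + n_2 - 2$ degrees of freedom, we assume the standard
hierarchical model in which the true residual variances are drawn from a
scaled inverse-chi-square prior with $d_0$ degrees of freedom and scale
$s_0^2$. The posterior variance is the precision-weighted blend

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},$$

and the moderated statistic
$t_g = (\bar x_{g1} - \bar x_{g2}) / (\tilde s_g \sqrt{1/n_1 + 1/n_2})$
is referred to a t distribution on $d_0 + d_g$ degrees of freedom.
The hyperparameters are estimated by moment matching on
$z_g = \log s_g^2$: with
$e_g = z_g - \psi(d_g/2) + \log(d_g/2)$ ($\psi$ the digamma function),
$\mathrm{E}[e] = \log s_0^2 + \psi(d_0/2) - \log(d_0/2)$ and
$\mathrm{Var}[e] = \psi'(d_0/2) + \psi'(d_g/2)$, so $d_0$ comes from
inverting the trigamma $\psi'$ numerically. Benjamini-Hochberg adjustment
at $\alpha = 0.1$ defines the DEG set and each DEG's direction
(case minus control).

**Stage 2 — GeneRank weighting.** Raw per-sample expression ignores that
genes act in networks. For each sample, the DEG expression vector
$\mathrm{exp}$ is re-weighted by solving

$$(I_p - d\, W D^{-1})\, r = (1 - d)\, \mathrm{exp},$$

a PageRank-style linear system in which $W$ is the symmetric 0/1 adjacency
of the interaction network, $D$ the diagonal degree matrix, and
$d \in [0, 1)$ the damping parameter. The columns of $W D^{-1}$ sum to 1
(or 0 for isolated genes), so the spectral radius of $dWD^{-1}$ is below 1,
the system is nonsingular, and the Neumann series
$r = (1-d) \sum_{k \ge 0} (dWD^{-1})^k \mathrm{exp}$ shows that nonnegative
expression gives nonnegative ranks — which is why the package enforces
nonnegative input at every boundary. $d = 0$ recovers raw expression;
$d = 0.5$ (the default) weights a gene's own expression and its neighbours'
equally.

**Stage 3 — across-time screen and monotone filter.** Within each response
group, a Kruskal-Wallis test per gene compares the weighted values across
the $T$ ordered time points (BH within the group, threshold 0.1). For
survivors, the per-timepoint means $\bar w_1, \dots, \bar w_T$ are checked
for a monotone chain: non-decreasing with at least one strict step is MIE,
non-increasing with at least one strict drop is MDE. The chains are
deliberately non-strict — plateaus are allowed — but an all-equal profile,
which would satisfy both chains at once, is classified as neither.

**Stage 4 — classification.** A MEG whose monotone direction opposes its
DEG direction is drifting back toward control levels: a *good response*
gene. Matching directions mean drifting further away: *bad response*. The
rule is a total, deterministic XOR on the two direction tokens.

## Assumptions worth stating

- Expression is already normalized, log2-scaled, and nonnegative; the
  package performs no probe-level preprocessing.
- The Kruskal-Wallis screen pools repeated measures from the same patients
  as if independent. This follows the procedure the pipeline standardizes,
  and it is anticonservative in principle; `screen_genes(method =
  "friedman")` offers a patient-blocked alternative for sensitivity
  analysis (on the simulated designs both flag planted trends reliably).
- Time points enter as ordered categories only. Unevenly spaced sampling
  times carry no extra weight, matching the rank-based screen and the
  purely ordinal monotone filter.
- The interaction network is unweighted and undirected; interaction
  confidence scores are out of scope.

## Tunable parameters

| Parameter | Default | Units | Why this default |
|---|---|---|---|
| `deg_alpha` | 0.1 | adjusted p | permissive cutoff suited to small-sample screens feeding a downstream filter |
| `kw_alpha` | 0.1 | adjusted p | same reasoning, applied within each response group |
| `damping` (`d`) | 0.5 | dimensionless, $[0,1)$ | equal weight to a gene's own expression and its network context |
| `epsilon` | 0 | log2 intensity | exact ties in floating-point means are measure-zero on real data; a positive value tolerates small dips as plateaus |
| `rank_scope` | `"deg_subgraph"` | — | see below |

The KW threshold is worth varying in practice: marginal genes can enter the
MEG list at 0.2 that are absent at 0.1, so `kw_alpha` is a first-class
argument rather than a constant.

**DEG subgraph versus full network.** Whether the rank system should span
all genes or only the DEGs is genuinely open. The default solves the system
on the DEG-induced subgraph, which matches computing "the GeneRanks of the
DEGs" as DEG-dimension vectors and keeps the system small;
`rank_scope = "full_network"` solves over every gene and then subsets,
letting non-DEG neighbours donate weight. Both modes are exposed; the
choice changes individual rank values but not the shape of the pipeline.
Degree-0 genes are kept (rank $(1-d)\cdot$expression) rather than dropped,
so the DEG set survives end to end. Per-sample expression is not rescaled
before ranking (e.g. to sum to one): raw log2 values enter the system.

## The synthetic-data generator

`sim_config()` fixes the simulated study design; its defaults mirror the
targeted design: 26 cases vs. 18 controls cross-sectionally, two response
groups of 9 patients sampled at 5 ordered time points longitudinally.
Gaussian noise (`noise_sd = 0.5` log2 units) is added to piecewise-constant
means: planted DE genes shift by `de_effect = 1` log2 unit in cases, and
planted monotone genes move `trend_step = 0.5` log2 units per time point in
their group. The interaction network is Erdős–Rényi (`edge_prob = 0.02` on
200 genes, mean degree 4) with a forced isolated subset
(`isolated_fraction = 0.1`) so the degree-0 branch of the rank system is
always exercised; scale-free topology is deliberately not simulated.

Two structural choices matter for interpreting tests:

- **Monotone genes are a subset of the DE genes** (`trend_fraction = 0.5`
  of them per group, drawn from a dedicated substream so cross-sectional
  and longitudinal generators agree when called separately). The pipeline
  can only ever find MEGs inside the DEG set, so planting trends outside it
  would make recovery undefined rather than hard. `trend_mode` controls the
  direction geometry: `"random"` flips a coin per gene, `"discordant"`
  plants the good-response geometry (down-DEGs trend up), `"concordant"`
  the bad-response one.
- **Values are clipped at zero** (with a warning) rather than
  rejection-sampled, guaranteeing the GeneRank nonnegativity precondition;
  with the default `baseline_mean = 7` and `noise_sd = 0.5`, clipping is a
  six-sigma event and effectively never fires.

One master seed drives independent substreams for network, cross-sectional
data, longitudinal data and planted truth, so identical configurations give
byte-identical studies.

What the generator does **not** emulate: probe-level effects, quantile
normalization artefacts, batch effects, dropout, heavy-tailed or
heteroscedastic noise, correlated genes, scale-free topology, or uneven
sampling times. Passing recovery tests therefore demonstrates that the
pipeline's logic is correct under its own model, not that these settings
are optimal for real microarray data.

## Numerical choices

- The rank system is solved by sparse direct factorization (`Matrix`),
  one factorization per system reused across all samples; the residual is
  checked against $10^{-10}\max(1, \lVert \mathrm{exp}\rVert_\infty)$.
  A Jacobi fixed-point iteration of the same system serves as an
  independent oracle in the test suite, never as the production path.
- Trigamma inversion uses a Newton iteration with relative tolerance
  $10^{-10}$ (the test oracle uses log-scale bisection instead, keeping the
  two routes independent).
- Hyperparameter estimation falls back to $d_0 = \infty$ (all posterior
  variances equal to $s_0^2$) when fewer than four genes have positive
  sample variance or when the spread of $\log s_g^2$ does not exceed its
  expected sampling value — the honest limit for homoscedastic data — with
  a logged notice. Genes with zero pooled variance are excluded from moment
  estimation but still tested (moderation keeps $\tilde s_g^2 > 0$ whenever
  $d_0 > 0$; an all-constant matrix yields $t = 0$, $p = 1$ by the
  zero-numerator convention).
- An all-tied Kruskal-Wallis input returns $H = 0$, $p = 1$ rather than the
  0/0 of the tie-correction formula. Exact permutation p-values are a
  non-goal; the chi-square approximation is standard at these group sizes.
- An empty DEG set terminates the pipeline gracefully with empty outputs
  and a logged notice, rather than erroring.
- Writers format numbers at `%.17g`, so TSV round-trips reproduce doubles
  exactly and repeated runs are byte-identical.

## Problem sizes in the test suite

The validation suite simulates 200-gene studies (10 recovery seeds, 20 null
seeds) and 50-gene random systems (20 instances) — sizes chosen so each
property is exercised well away from trivial edge cases while the whole
suite stays interactive; all bounds asserted there (planted-MEG sensitivity
at least 0.7 under `trend_step = 0.5`, `noise_sd = 0.5`; at most 2 MEGs in
at least 18 of 20 null runs) were frozen before being wired into tests and
are comfortably cleared (observed sensitivity ≈ 0.9 with 100% direction
agreement, 0 MEGs in every null run).

## Known limitations

- FDR control bounds the *rate*, not the count, of false discoveries: a
  large DEG set at $\alpha = 0.1$ is expected to carry roughly 10% null
  genes, and network weighting can propagate a strong neighbour's trend
  onto a flat DEG, creating monotone false positives beyond the nominal
  rate. The recovery tests bound sensitivity and direction agreement, not
  false-positive counts at zero.
- With two time points every flagged profile is trivially monotone; the
  design is intended for $T \ge 3$ (five in the motivating design).
- The moderated t assumes exchangeable gene variances around a common
  prior; strong mean-variance trends (as in counts) violate this, and
  count data should be variance-stabilized first.
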