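---
title: "Consensus signatures and network driver prioritization: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus signatures and network driver prioritization: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consignet)
```

`consignet` packages a complete in-silico strategy for extracting stable
cancer gene signatures from small, heterogeneous expression cohorts and
for prioritizing candidate driver proteins on an interaction network.
This vignette explains the statistical models behind each stage, the
parameters that matter, the numerical conventions, and what the synthetic
validation does — and does not — establish.

## The expression model and batch correction

All expression work assumes log2-scale values. The generative model both
the simulator and the batch correction assume is

$$ y_{gjs} = \alpha_g + \beta_g x_j + \gamma_{sg} + \delta_{sg}\,\varepsilon_{gj}, $$

with per-gene baseline $\alpha_g$, case/control effect $\beta_g$ (with
$x_j \in \{0,1\}$), an additive study (batch) offset $\gamma_{sg}$, a
multiplicative batch dispersion $\delta_{sg} > 0$, and Gaussian noise
$\varepsilon$. Correction proceeds in the classical parametric
empirical-Bayes fashion:

1. `fit_standardization()` estimates $\alpha_g$, $\beta_g$ and the
   residual scale $\sigma_g$ by gene-wise least squares on a design with
   one indicator per batch plus the group covariate, and standardizes
   to $z_{gj} = (y_{gj} - \hat\alpha_g - \hat\beta_g x_j)/\hat\sigma_g$.
2. `eb_shrink()` places a normal prior on the per-gene batch means and an
   inverse-gamma prior on the per-gene batch variances, estimates the
   hyperparameters by the method of moments within each batch, and solves
   the conditional-posterior updates for the shrunken effects
   $(\gamma^*_{sg}, \delta^*_{sg})$ iteratively.
3. `apply_correction()` returns
   $\hat\sigma_g/\sqrt{\delta^*} (z - \gamma^*) + \hat\alpha_g + \hat\beta_g x_j$.

Choices worth knowing:

- **The group covariate is protected.** Its fitted effect is removed
  before batch estimation and re-added afterwards. Without this, a group
  imbalance across studies (as in the default design) would let the batch
  model absorb biology. This is a convention, not a mathematical
  necessity, and it assumes the group labels are trustworthy.
- **Confounded designs degrade gracefully**: if the group indicator is
  collinear with the batch indicators, the covariate is dropped and only
  batch structure is modelled.
- **Degenerate genes**: a zero-variance gene gets a floored
  $\sigma_g = 10^{-8}$ and standardized values of exactly 0, so it passes
  through untouched rather than generating NaNs.
- **Convergence**: iterations stop when the largest absolute parameter
  change falls below `tol = 1e-4` (cap 200 iterations; non-convergence is
  an error carrying the last iterate). All shipped fixtures converge in a
  handful of iterations.
- **Single-batch cohorts** short-circuit to a null model
  ($\gamma^* = 0$, $\delta^* = 1$): with one batch there is nothing to
  correct, and forcing the EB machinery through a one-batch prior would
  only inject shrinkage noise.

The test suite validates the implementation by parameter recovery on
simulated cohorts (planted shifts, planted group effects) and by
agreement with the reference empirical-Bayes implementation in `sva` on
a shared fixture.

## Virtual datasets and the SAM consensus

The instability of single-cohort gene lists is addressed by resampling
the integrated cohort into `k` *virtual datasets* (default 8). The
default `mixed` mode mirrors the design the pipeline was modelled on:
`k - n_studies` plans drawn at random across studies — controls and
cases sampled without replacement, sizes uniform on 5–11 controls and
7–16 cases, matching the observed compositions of that design — plus one
plan per study holding all of its samples.

Each plan is scored by the SAM statistic
$d_g = (\bar y_{g,\text{case}} - \bar y_{g,\text{ctrl}})/(s_g + s_0)$,
where $s_g$ is the pooled standard error of the mean difference and
$s_0$ is the exchangeability constant chosen by `choose_s0()`: candidate
values at every 5th percentile of the $s$ distribution are evaluated and
the one minimizing the coefficient of variation of the windowed median
absolute deviation of $d$ wins (windows are quantile bins of $s$, about
one per ten genes, capped at 100). This damping prevents genes with
accidentally tiny scatter from dominating the ranking.

Significance is permutation-calibrated: group labels are permuted
(`B = 200` by default; when the design admits `choose(n, n_ctrl) <= B`
distinct assignments the space is enumerated exhaustively, which makes
the result seed-independent), the ordered observed statistics are
compared with the expected order statistics $\bar d_{(i)}$, and a gene is
called when $|d_{(i)} - \bar d_{(i)}| \ge \delta$ *and* its linear fold
change passes $\max(\mathrm{fc}, 1/\mathrm{fc}) \ge 1.2$. The symmetric
form of the fold-change filter is deliberate: down-regulation passes on
equal terms. The FDR at a threshold is the median over permutations of
the count of permuted statistics beyond the d-scale cutpoints, divided
by the number of called genes and clipped to $[0,1]$. When `delta` is
not supplied it is chosen as the smallest value on a 0.05-step grid with
estimated FDR at most 0.05. Ties in the $d$ ranking are broken by gene
id, so every result is reproducible bit for bit.

A gene is a **consensus signature** when it is called in at least `m` of
the `k` virtual datasets (default 6 of 8) *with the same direction every
time*. Direction conflicts disqualify a gene outright. This m-of-k plus
direction-consistency rule is our operationalization of "robust"; the
design it emulates reported the robust set without stating the exact
rule, so this reading is a documented interpretation. On the default
synthetic conditions it is conservative: precision is favoured over
sensitivity, which is the right trade for a signature that seeds
downstream network analysis.

## Seed networks, topology and the Steiner reduction

Interaction edge tables (SIF or two-column TSV, one or many files) are
unioned with per-edge source tags, deduplicated as unordered pairs, and
self-loops dropped with a tally. `build_seed_network()` keeps the seeds
plus every node within `order` hops (default 1) and **all** interaction
edges among the kept nodes — the induced expansion. An `order = 2`
expansion is available; indirect neighbors inflate networks quickly, and
with the induced-edge convention the first order already captures
interactor–interactor wiring. `clean_network()` removes self-loops,
isolates, and keeps the largest connected component (size ties go to the
component containing the lexicographically smallest node id).

Topology is computed per node: degree $k_n$, the number $e_n$ of edges
among the node's neighbors, and the clustering coefficient
$CC = 2e_n/(k_n(k_n-1))$, defined as 0 when $k_n < 2$ so ranking is a
total function. Roots are ranked by descending $k_n$, then ascending
$CC$, then id. The scientific intuition: a driver that coordinates many
otherwise-unconnected partners shows a large degree with near-zero
clustering, the exact profile the formula isolates.

The Steiner reduction uses the Kou–Markowsky–Berman approximation on
unit edge costs: metric closure over the terminals by shortest paths,
minimum spanning tree of the closure, expansion back to real paths, and
pruning of non-terminal leaves. The result is within $2(1 - 1/t)$ of the
optimum for $t$ terminals; the test suite verifies that bound against an
exhaustive optimum on small graphs. Edges are unweighted because the
interaction sources carry no comparable confidence scale.

## Enrichment, proteomics filter, survival

- **Enrichment** is the right-tailed Fisher exact test: the
  hypergeometric probability of an overlap at least as large as observed,
  evaluated through `phyper` (log-space internally, so stable for large
  universes). The universe defaults to the genes of the integrated
  matrix — the reproducible choice — and Benjamini–Hochberg adjustment is
  reported alongside the raw p, which remains the primary statistic.
- **The proteomics filter** is the two-class paired t-test on log2
  abundances with `p < 0.001`. The reported difference is
  control − treated, so a *negative* difference means the protein is
  higher under treatment and is labelled `up` — the direction convention
  of the design this emulates. Proteins with missing pairs are excluded,
  not imputed. With 3 replicate pairs the test has 2 degrees of freedom;
  the critical |t| at p = 0.001 is about 44.7, so only large, consistent
  shifts survive. The suite checks the realized detection rate against
  the exact noncentral-t power rather than pretending the filter is
  all-powerful.
- **Survival** uses a median split (ties go to the low group — a
  deterministic rule is required and this one keeps the high group
  strictly above the median), Kaplan–Meier product-limit curves, the
  standard Mantel–Cox log-rank chi-square on one degree of freedom, and
  Pearson correlation for gene–gene association. These are standard
  estimators and are delegated to the `survival` package and `cor.test`,
  with hand-enumeration oracles in the tests.

## What the simulators emulate — and what they do not

The generators produce exactly the structures the analysis assumes:
batch-shifted multi-study expression with planted fold changes split
50/50 up/down (so direction-consistency logic is exercised), scale-free
interaction graphs with planted high-degree seed hubs, gene sets with
one planted enriched pathway, exponential survival with a
group-proportional hazard and independent exponential censoring, and
paired log2 abundances with a shared replicate effect.

Default conditions are fixed once: three studies with (control, case)
counts (10, 10), (5, 12), (11, 16); 5% DE genes at 1.5 log2 fold change;
additive batch SD 1.0; lognormal unit-mean dispersion with scale 0.25;
residual SD 0.5. They mirror the integrated three-cohort case/control
design this pipeline was shaped by, at desk scale (2,000 genes rather
than tens of thousands of probes; the statistics are per-gene, so gene
count affects runtime, not validity). The demo and acceptance runs state
their sizes (800 genes, 800 network nodes, B = 100–200) in their own
configs; the demo's planted proteomics responders use shift 4 at noise
0.1 so the 2-df filter retains most of them — with weaker effects the
p < 0.001 rule is nearly silent, which is faithful but makes a poor
demonstration.

What passing on these conditions does **not** show: real microarray
cohorts have correlated genes, probe-level artefacts, heavier tails and
batch effects that are not additive-plus-scale; real interactomes are
noisy, biased toward well-studied proteins and far from scale-free
ideals; real survival cohorts censor informatively. Recovery of planted
truth certifies the machinery, not the biology.

## Known limitations

- The empirical-Bayes correction implements the parametric prior form
  only; no non-parametric variant.
- SAM here is two-class unpaired only — no multi-class, paired, or
  survival-mode scoring, and no local-FDR refinement.
- The permutation FDR follows the classic plug-in estimator without a
  $\pi_0$ correction, so it is conservative when many genes are truly
  differential.
- Steiner reduction assumes unit costs; weighted atlases would need a
  weighted closure, which the KMB scaffold supports but the interface
  does not expose.
- The survival module fits no covariate-adjusted (Cox) models; it is a
  stratified read-out, not a prognostic model.
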