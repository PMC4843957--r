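---
title: "Methods: hierarchical Bayesian models for QFA screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical Bayesian models for QFA screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayesqfa)
```

## Scope and data model

Quantitative fitness analysis (QFA) compares two genome-scale screens of a
gene-deletion library — a control background and a query background — to
find genes whose deletion modifies the query condition's fitness effect.
The data are per-culture cell-density time courses: tidy tables with one
row per photograph of one culture, columns `orf` (gene deletion),
`condition` (0 control / 1 query), `repeat`, `time_days` and `density`.
Densities are scaled so the maximum observable density on a plate is 1;
time is in days. Replicate counts and time grids may be unbalanced.

Growth of each culture follows the logistic model with carrying capacity
$K$ (scaled density units), growth rate $r$ (per day) and inoculum $P$
(scaled density units, shared across cultures — at about 100 cells per
spot the inoculum sits far below the camera's detection threshold, so $P$
is identifiable only by pooling across the whole screen).

## The three models

**SHM** (one screen). Observations are normal about the logistic curve with
gene-specific precision $\nu_l$. Repeat-level $\log K_{lm}$ and
$\log r_{lm}$ are normal about gene-level locations with gene-specific
precisions $\tau^K_l, \tau^r_l$; gene-level natural-scale locations
$\exp(K^o_l), \exp(r^o_l)$ have scaled-t (3 df) population priors, chosen
because deletion libraries contain heavy tails of unusually sick, dead or
missing strains that a normal layer would shrink too aggressively.
Precisions get log-normal priors: the conjugate options are either too
restrictive or not restrictive enough at low variance, and the log-normal
matches prior knowledge over the plausible precision range.

**IHM** (fitness level, stage two of the two-stage path). Per-culture
fitnesses from both screens are normal about
$\exp(\alpha_c + Z_l + \delta_l\gamma_{cl})$ with per-gene-per-condition
precision $\nu_{cl}$. Under multiplicative genetic independence the
query/control ratio is the single constant $e^{\alpha_1}$ — differences in
the two screens' inoculum, temperature or background are absorbed by
$\alpha_1$. The Bernoulli indicator $\delta_l$ (prior probability `p`)
switches a gene-specific deviation on; interaction evidence is its
posterior mean.

**JHM** (one stage). Both screens' raw time courses are modelled jointly;
condition effects $\alpha_1$ (on $\log K$) and $\beta_1$ (on $\log r$) and
a single indicator $\delta_l$ gating a carrying-capacity effect
$\gamma_{1l}$ and a growth-rate effect $\omega_{1l}$. Because the evidence
pools over both growth parameters, interactions expressed in only one
channel — or cancelling in a combined fitness score like DRDP — are still
found. All precision hierarchies are condition-indexed; $P$ is shared
across conditions.

### Truncations

Three hard constraints encode biology and guard identifiability:
$\log K_{lm} \le 0$ (no carrying capacity above the maximum observable
density), $\log r_{lm} \le 3.5$ (no doubling faster than
$\log 2/e^{3.5}$ days $\approx$ 30 minutes), and $\log\tau^K_l \ge 0$
(prevents the repeat-level K layer from absorbing the degeneracy of flat,
dead-culture curves where $K$ and $r$ trade off freely). Truncations are
implemented as bare indicator functions: the parent-dependent normalising
constants are omitted, which defines a coherent (globally renormalised)
joint model and keeps every full conditional a simple density-plus-
indicator. The convention is applied identically in the samplers, the
log-posterior functions and the simulators.

### Precision convention

Every second parameter of a normal, log-normal or scaled-t kernel in this
package is a **precision** (variance $=1/$precision). A few lines of the
published model notation omit the inverse; we read those as precisions too,
for uniformity with the hyperparameter table. This is stated in
`?qfa_kernel` and `?qfa_priors`.

## Hyperparameter defaults

`qfa_priors(model)` ships the fixed hyperparameters for each model,
established from broad historical QFA screens. Because some symbols recur
across models with different values (the IHM and JHM each have their own
$\alpha_\mu/\eta_\alpha$, for instance) the defaults are grouped
explicitly: growth hyperpriors — including the $\sigma_\tau$ layer
$\eta_{\tau,K}, \psi_{\tau,K}, \eta_{\tau,r}, \psi_{\tau,r}$ — are shared
by the SHM and the JHM; the JHM adds the condition and interaction
hyperpriors; the IHM has its own fitness-scale set. Each model requires
its full explicit prior set (nothing is inferred across models silently)
and `load_priors()` accepts per-key overrides from YAML/JSON. The interaction prior `p = 0.05` reflects the
experimenter's belief that about 5% of library genes interact with a
typical query; for a 4294-gene library that is an expectation of
`round(0.05 * 4294) = 215` interactions.

## Inference

All models are fitted by Metropolis-within-Gibbs: each block is updated
once per sweep in a fixed top-down order (population, then condition, gene
and repeat level; the order affects mixing only, not the invariant
distribution). Blocks with conjugate normal full conditionals (the
hyper-means $\nu^p, \tau^{K,p}, \tau^{r,p}$, and in the JHM the condition
effects $\alpha_1, \beta_1$) are drawn directly; everything else uses
scalar or coordinate-wise normal random-walk Metropolis. Coordinates that
are conditionally independent given the rest (repeat-level parameters,
gene-level locations, indicators, per-gene precisions) are proposed and
accepted in parallel, which is what makes a pure-R implementation fast
enough for screen-scale problems.

The indicators $\delta_l$ are drawn **exactly** from their Bernoulli full
conditionals: posterior odds = prior odds $\times$ likelihood ratio of the
gene's query observations with the interaction term on versus off (in the
JHM the ratio aggregates the K and r channels over all query repeats).
When $\delta_l = 0$ the idle effect $\gamma_{1l}$ (and $\omega_{1l}$) is
refreshed from its prior so it stays well defined and the indicator can
switch back on — a standard pseudo-prior treatment; the model definition
is silent on the mechanism and any choice leaving the joint distribution
invariant is valid.

**Proposal adaptation.** During burn-in only, each step size follows a
Robbins–Monro recursion toward acceptance 0.234 (gain $3/\sqrt{i+10}$,
capped), per coordinate for vectorised blocks; proposals are frozen before
sampling so retained draws target the exact posterior. Idle-indicator
effect coordinates do not adapt (their refreshes are not Metropolis
acceptances). There is no canonical proposal scaling for these models;
these choices are implementation-defined and stated here for that reason.

**Initialisation.** Repeat-level $(K, r)$ from per-culture least-squares
fits with $P$ fixed at its prior median $e^{-9.04}$; gene-level locations
from medians of their children; precisions by method of moments (clamped
into support); $P$ at the prior median. Initial states violating a
truncation are clamped inside it; `run_chain()` refuses a non-finite
initial log posterior and names the offending block.

**Diagnostics.** `mcmc_diagnostics()` reports per-parameter posterior mean
and SD, effective sample size (Geyer initial-positive-sequence estimator),
a Geweke-style z score comparing the first 10% and last 50% of the chain,
and lag-1 autocorrelation, flagging $|z| > 2$ or ESS < 10% of draws. These
replace the older Heidelberger–Welch and Raftery–Lewis criteria with
equivalent, simpler checks; constant chains (legitimate for indicators)
are flagged, not errors.

## Fitness measures and calls

`DR` is derived as the reciprocal of the first time the curve reaches
$2P$, giving $DR = r / \log\{2(K-P)/(K-2P)\}$ with the natural logarithm
(the test suite asserts the first-passage identity by bisection to
1e-10); `DP` $= \log_2(K/P)$. Cultures whose summarised curve cannot
double ($K \le 2P$) or whose fitted plateau sits within 5% of the minimum
observed density are flagged dead and given $DR = F = 0$, mirroring
standard QFA post-processing. Screen scaling for the frequentist baseline
averages per gene first and then across genes, so unequal replicate counts
cannot tilt the screen mean; the operation is idempotent.

Calls: a gene is significant iff $\hat\delta_l > 0.5$ strictly. For a
deleterious query, positive deviation from the independence line is a
suppressor and negative an enhancer (configurable for beneficial queries).
IHM strength is the posterior mean of $\delta_l\gamma_{1l}$; the JHM
reports per-channel strengths (posterior means of $\delta\gamma$ and
$\delta\omega$) plus a combined fitness shift, since a gene can be a
suppressor in terms of $K$ and an enhancer in terms of $r$.

## Simulators: what they emulate and what they do not

`simulate_shm` / `simulate_ihm` / `simulate_jhm` are the generative twins
of the three models: ancestral sampling down the hierarchy with rejection
sampling honouring every truncation (capped at 1e4 tries per draw, then an
error suggesting the prior be adjusted). Default conditions describe a
realistically scaled-down screen: carrying capacities near 0.13, growth
rates near 2.6/day, inoculum $e^{-9.04} \approx 1.2\times10^{-4}$, about
5% biological scatter between replicates ($\tau$ layers around $e^6$),
measurement noise precision around $e^{19.82}$ (the prior mean — tiny
relative to the plateau, comparable to the inoculum), and a deleterious
query ($\alpha_1 = -0.1$, $\beta_1 = -0.3$). Default designs are L = 50
genes × M = 8 replicates (the median replicate count of genome-scale QFA)
× N = 12 time points over 4 days.

One deliberate deviation from the model: simulated observation noise is
truncated to the valid density scale $[0, 1]$ so that emitted datasets
always pass schema validation; at the default noise level the truncation
affects well under 1% of draws and is negligible for inference. The
simulators do not emulate plate-position or edge effects, contamination,
agar artefacts, or camera detection thresholds — so passing recovery tests
shows correctness of the inference machinery under the model, not
robustness to the full mess of real screens.

## Problem sizes and numerical choices in the test suite

Recovery checks use scaled-down designs chosen to exercise every level of
the hierarchy while keeping the default suite quick: SHM at L = 20, M = 4,
N = 10 (≥90% of gene-level parameters within 10%, shared $P$ within 20%);
IHM at L = 100 with 10 designated interactors of log-effect ±0.6
(sensitivity ≥80%, false positives ≤10%); JHM at L = 50, M = 4, N = 10
with 5 K-only and 5 r-only interactors of effect ±0.5. Chains run 3000
burn-in sweeps and 1000 retained draws thinned by 2, which pilot
diagnostics showed is comfortably past convergence at these sizes
(acceptance rates near target, ESS well above the flag threshold).
A constructed cancellation case — a carrying-capacity effect $\gamma=-0.5$
paired with the growth-rate effect $\omega$ solved so DRDP is unchanged —
demonstrates the JHM's unique detection: the joint fit calls the gene with
$\hat\delta \approx 1$ while the two-stage DRDP path leaves it near 0.

## Known limitations

- Genome-scale data (thousands of genes, hundreds of thousands of
  parameters) will run for days in this pure-R implementation, as expected
  for these models; the vectorised blocks keep desk-scale screens to
  seconds or minutes.
- Population-level parameters ($K^p$, $\alpha_1$, shared $P$) mix the
  slowest; check the diagnostics table before trusting small differences
  in condition effects.
- The multiplicative model of independence is the only epistasis
  definition implemented (additive-on-log-scale equivalent); minimum and
  additive raw-scale definitions are out of scope.
- A single indicator gates both JHM channels: the model cannot represent a
  gene interacting in K with probability different from r; per-channel
  strengths are reported for interpretation instead.
- The frequentist random-effects alternative is not implemented (it is
  impractical at scale); the per-gene linear model with
  Benjamini–Hochberg correction is the comparator.
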