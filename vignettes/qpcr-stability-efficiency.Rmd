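---
title: "Reference-gene stability, amplification efficiency and normalization for qPCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-gene stability, amplification efficiency and normalization for qPCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpcrstab)
```

## The problem

Relative quantification by real-time PCR expresses a target gene's
quantification cycle (Cq) against one or more reference genes assumed to
be stably expressed. Two methodological choices dominate the quality of
the result: *which* reference genes to use, and *what amplification
efficiency* to assume when converting cycle differences into fold
changes. `qpcrstab` implements the standard toolbox for both decisions —
four reference-gene stability statistics, four single-reaction
efficiency estimators, efficiency-corrected normalization — together
with a ground-truth simulator and a subsampling protocol that measures
how robust each stability ranking is when few samples are available.

The simulator's default design emulates a developmental study of fish
gonads: 8 sampling ages (30–135 days post fertilization) × 3 rearing
temperatures × 10 individuals = 240 samples across 24 experimental
groups; six candidate reference genes (RPS4, RPL17, GAPDH, ACTB, UBQ,
B2M) and six sex-differentiation targets (CYP19a, AMH, SOX9, SOX19,
SOX17, VASA); duplicate reactions; and three interplate calibrator
samples run in triplicate on every plate.

## The generative Cq model

Every simulated replicate-level Cq is additive on the cycle (log2
quantity) scale:

$$
Cq_{g,s,r} \;=\; \beta_g \;+\; L_s \;+\; b_{g,s} \;+\; \delta_{g,\,
\mathrm{grp}(s)} \;+\; \sigma_{g,\mathrm{sex}(s)} \;+\;
\sum_{p \ni g} z_{p,s} \;+\; \pi_{g,\mathrm{plate}} \;+\;
\varepsilon_{g,s,r}
$$

* $\beta_g$ — per-gene baseline Cq (defaults on the scale of real gonad
  panels, means 15.9–31.9 cycles).
* $L_s \sim N(0, \sigma_L^2)$ — a **loading effect** shared by every
  gene in a sample (RNA input, RNA quality, RT yield). This is exactly
  the technical noise normalization is meant to cancel; default
  $\sigma_L = 0.9$ cycles.
* $b_{g,s} \sim N(0, \sigma_{b,g}^2)$ — gene-specific biological
  scatter. This field is deliberately present even though the minimal
  variance decomposition does not require it: without a gene-level
  component all genes would have identical marginal SDs and the
  SD-based rankings would be exchangeable. Defaults 0.45–1.05 cycles
  for references, 1.0–2.0 for targets.
* $\delta_{g,j}$ — fixed regulation offsets per experimental group; a
  gene with all-zero offsets is "stable" by construction. The default
  truth regulates B2M with temperature (±0.6 cycles) and the targets
  more strongly.
* $\sigma_{g,\mathrm{sex}}$ — sex offsets for the targets (e.g. CYP19a
  ∓3.5 cycles between females and males), giving the sex-group tables
  something real to measure.
* $z_{p,s}$ — co-regulation latents shared by gene pairs (defaults link
  RPS4 with UBQ/GAPDH/RPL17, and VASA with B2M so that normalizing VASA
  by the *unstable* B2M spuriously shrinks its spread).
* $\pi_{g,\mathrm{plate}} \sim N(0, 0.15^2)$ — plate offsets, removable
  by interplate calibration.
* $\varepsilon \sim N(0, 0.15^2)$ — technical replicate noise. Noise is
  Gaussian on the Cq scale, consistent with treating observed Cq
  distributions as approximately normal.

A small per-replicate failure rate (0.5%, half missing values, half
gross 1.2–3-cycle outliers) reproduces the realistic situation in which
a whole-sample replicate-QC filter removes on the order of 10% of
samples from a 240-sample study.

What the generator does **not** emulate: RNA degradation, primer-dimer
artifacts, melting-curve behaviour, inhibitor gradients, or
non-Gaussian heavy-tailed Cq noise. Passing tests therefore demonstrate
algorithmic correctness under a plausible variance structure, not
performance on any particular real instrument's quirks.

## Preprocessing

`interplate_calibrate()` subtracts, per plate and gene, the difference
between the plate's calibrator mean and the overall calibrator mean.
The operation is idempotent and preserves within-plate differences
exactly. Calibration runs **before** replicate QC so that plate offsets
cannot inflate replicate deltas. `filter_replicates()` then removes a
sample *entirely* — all genes — if any reaction has a missing Cq or a
replicate range above 1 cycle (the stability methods need a complete
matrix). `average_replicates()` collapses duplicates to the arithmetic
mean, and `describe_cq()` reports per-gene N/mean/SD/min/max plus a
Lilliefors-corrected Kolmogorov–Smirnov normality p-value. The
Lilliefors variant is used because the reference parameters are
estimated from the data; the classical KS test would be
anti-conservative. The variant is recorded in the output's metadata
since p-values differ between the two.

## The four stability methods

All four run on the calibrated, averaged Cq matrix; smaller values mean
more stable genes.

**Comparative delta-Ct** (`delta_ct_stability()`): the stability of
gene $g$ is the mean over partners $h$ of
$\mathrm{SD}_s(Cq_g - Cq_h)$. Shared sample effects cancel in the
differences, so the method is invariant to per-sample constants.

**BestKeeper-style descriptives** (`bestkeeper()`): raw per-gene SD and
CV% (100·SD/mean) plus all-pairs Pearson correlations with two-sided
t-based p-values. Genes with SD > 1 cycle are flagged. The index
(geometric mean of Cqs) and its regressions are omitted: only the SD,
CV and correlations feed the comparisons this package supports.

**Model-based decomposition** (`normfinder()`): per-sample means are
removed (absorbing the loading effect), then for each gene and group
the deviation $d_{gj}$ and within-group SD $s_{gj}$ are estimated.
Deviations are shrunken by their sampling noise,
$\tilde d_{gj} = d_{gj}\,\gamma^2/(\gamma^2 + s_{gj}^2/n_j)$ with
$\gamma^2 = \mathrm{Var}_j(d_{gj})$, and the stability value is
$\rho_g = \mathrm{mean}_j\big(|\tilde d_{gj}| + s_{gj}/\sqrt{n_j}\big)$,
combining systematic between-group regulation with within-group
scatter. The best two-gene combination minimizes the analogous
quantity with pair deviation $(\tilde d_g + \tilde d_h)/2$ and pair
variance $(s_g^2 + s_h^2)/4$. This estimator follows the published
intra/inter-group variation idea; the exact shrinkage constants of the
original software are not reproduced decimal-for-decimal, so tests
assert rankings and limiting behaviour rather than third-party output
equality. Input is the Cq scale throughout.

**Stepwise exclusion** (`genorm()`): the M-value of a gene is its mean
pairwise SD within the *current* gene set — identical to the
comparative delta-Ct value in round one (the package asserts this
equivalence against a brute-force oracle at 1e-10). The gene with the
highest M is excluded and M recomputed until two genes remain; the
final pair is checked against the conventional acceptability cutoff of
1.5. Exact ties for the highest M are broken by removing the gene
later in input order, and every tie is logged. The pairwise-variation
$V_{n/n+1}$ statistic for choosing the number of genes is *not*
computed; `set_m_value()` provides the set-wise mean M of any candidate
combination instead.

Design note: "geometric mean of reference quantities" on the linear
scale is the arithmetic mean on the Cq scale; all normalization-factor
arithmetic in this package is therefore the arithmetic mean of
(efficiency-corrected) Cqs. No cross-method consensus ranking is
offered: the four methods share information and weighting them equally
has no statistical justification.

`compare_normalization_factors()` quantifies what a candidate
combination does to the *target* genes: the average within-group SD,
the SD of group means, and per-sex SDs of the normalized values,
averaged over targets. "Inter-group SD" is implemented as the SD of
group means (not the mean of per-group SDs of means) — an explicit,
recorded choice where conventions vary.

## Efficiency estimation from single reactions

The amplification-curve simulator generates product by
$N_c = N_{c-1} E_c$ with per-cycle efficiency
$E_c = 1 + (E_0 - 1)(1 - N_{c-1}/N_{\max})$: geometric growth at
amplification factor $E_0 \in (1, 2]$ far from the plateau, with
efficiency decaying linearly in product as reagents deplete (a
logistic-like plateau whose ground-truth $E_0$ is defined at the
single-molecule limit, rather than a fitted sigmoid). Observed
fluorescence adds a baseline with linear drift and Gaussian read noise;
defaults (40 cycles, plateau 30000, baseline 3000 + 2/cycle, noise SD
30, F0 = 0.02) put the mid-rise near cycle 20 on a typical
SYBR-instrument scale. Raw, un-baselined fluorescence is the input to
every estimator.

Four estimator families are implemented. The algorithmic outlines
follow the published descriptions of the corresponding software
families, but those descriptions are not full specifications; each
concrete choice below is this package's committed dialect, logged in
the estimate metadata.

* **`estimate_linreg()`** — window-of-linearity regression. The
  baseline (with drift) is anchored to a linear fit of the pre-lift-off
  cycles, then a constant offset is iterated (grid ± golden-section) to
  maximize the R² of the best 4–6-cycle window of log(F − baseline),
  restricted to the rising region between the noise floor and 25% of
  the maximum signal. E = exp(slope). Anchoring matters: iterating an
  unconstrained baseline to maximize R² has a degenerate attractor in
  which an under-subtracted baseline produces a *flat but perfectly
  straight* log-curve, and the restriction to the rising region stops
  near-plateau windows (where efficiency has already decayed) from
  winning the R² contest.
* **`estimate_dart()`** — baseline from a saturation-function fit
  $F = a\,c/(b+c) + d$ to cycles 2–10 (falling back to their mean, with
  a flag, if the fit diverges or swallows the amplification signal);
  exponential-phase midpoint at the first cycle exceeding the
  early-cycle mean + 10 SD (with a 1%-of-maximum floor so noiseless
  input is defined); log-linear regression over the cycles spanning a
  10-fold signal range centred on that midpoint.
* **`estimate_miner()`** — four-parameter logistic fit (three
  deterministic multi-starts, Levenberg–Marquardt), then a
  three-parameter exponential $F = F_b' + F_0 E^c$ fitted to the cycles
  where the fitted sigmoid lies between 0.5% and 5% of the plateau
  amplitude. Ending the phase at the sigmoid midpoint — a common
  reading of this algorithm family — underestimates E badly here,
  because the absolute-scale least-squares fit is dominated by the top
  cycles where efficiency has already decayed; the 0.5–5% band keeps
  the fit in the near-geometric region. The exponential is
  reparameterized around the window centre ($A\,E^{c-c_0}$) because the
  raw $F_0 E^c$ Jacobian spans ~12 decades and goes numerically
  singular.
* **`estimate_lre()`** — baseline from the mean of cycles 6–12;
  per-cycle efficiencies $E_c = F_c/F_{c-1}$ regressed on fluorescence
  over a window grown outward from the mid-rise while R² ≥ 0.99; the
  maximum efficiency is the regression *intercept*, i.e. the efficiency
  extrapolated to zero product.

E is stored as an amplification factor throughout (1 = none, 2 =
perfect doubling); percent efficiency appears only in reporting
tables, avoiding the 90%-vs-1.90 ambiguity. Estimates with E > 2 are
flagged (they are theoretically impossible and diagnostic of
overestimation); estimates with E ≤ 1 are invalid. Estimation is per
reaction and averaged per gene — never from pooled curves.

Under the default simulation conditions (100 curves per truth value,
$E_0 \in \{1.80, 1.90, 2.00\}$), all four estimators recover the mean
amplification factor within ±0.08, with the linear-fit families
(linreg, dart) biased slightly low and the zero-product extrapolation
(lre) biased slightly high — the directions reported for the
corresponding software families on real data. Noiseless geometric
input is recovered to 1e-3 by all four. Standard-curve (dilution
series) efficiency estimation is intentionally out of scope.

## Efficiency correction and normalization

`efficiency_correct()` rescales a Cq measured under amplification
factor E onto the perfect-doubling scale:
$Cq' = Cq \cdot \log E / \log 2$ (identity at E = 2).
`normalize_targets()` corrects every Cq (references and targets) with
its gene's **mean** efficiency, subtracts the arithmetic mean of the
reference combination's corrected Cqs, and mean-centres each target
across samples. Per-gene mean E (not per-reaction E) is the default
because per-reaction correction injects estimator noise into every
ΔCq; the function accepts any named efficiency vector if per-reaction
correction is wanted. Centring is applied after normalization and
before group summaries, and is recorded in the provenance. With all
E = 2 the pipeline reduces exactly to classic ΔCq normalization.

## Robustness protocol

`robustness_summary()` redraws stratified subsets (default 25 subsets
of 3 samples per group and 25 of 2 per group — 72 and 48 samples under
the default 24-group design), reruns each stability method, and
classifies each subset ranking against the full-data ranking as
*identical*, *top3 reordered* (same first-three set, different order),
or *different*. Subsets are drawn without replacement within groups.
For the stepwise-exclusion method, whose natural output ends in an
unordered pair, the comparison ranking places the final pair first (in
input order) followed by the reverse exclusion order; the model-based
method is compared on its single-gene ranking, and the SD ranking is
used for the descriptive method. Method failures on a subset are
recorded and excluded from percentages with a warning.

## Numerical choices and degenerate inputs

* Sample SD (n−1) everywhere, including CV% and the descriptive table.
* Constant Cq columns: KS p-value reported as NA, never an error.
* Zero within-window variance in the per-cycle-ratio regression is
  treated as a perfect fit (R² = 1), so exactly geometric curves are
  handled.
* Nonlinear fits: `minpack.lm::nlsLM`, ≤300 iterations, ftol 1e-8,
  three deterministic starts derived from curve heuristics; starts are
  deliberately perturbed away from exact interpolation (R's nls model
  machinery rejects a start that already fits the data exactly).
* Stepwise-exclusion ties: remove the gene later in input order; log.
* Seeds: every stochastic function takes an explicit seed and restores
  the caller's RNG state.

## Problem sizes

The test-suite and acceptance runs use the full 240-sample default
design for design-count and robustness checks, 100 random 5 × 20
matrices for the pairwise-SD oracle, 100 simulated curves per truth
value for efficiency recovery, 100 seeded replicates for the
regulated-gene discrimination check, and n = 5000 for the
exchangeable-gene limit; the bundled demo (`run_demo()`) runs the whole
pipeline with 3 curves per gene and 50 robustness subsets in well under
five minutes on a single CPU.

## Known limitations

* The stability estimators reproduce the published *statistics*, not
  the byte-level behaviour of the original third-party programs
  (outlier-removal heuristics, GUI-era rounding, etc.).
* The model-based decomposition assumes groups large enough to
  estimate within-group SDs; groups of one are rejected.
* The efficiency ground truth is a single-mechanism plateau model;
  estimator biases measured here should be read as *directions and
  orders of magnitude*, not as predictions of any instrument's bias.
* Fold-change inference and significance testing between groups are
  out of scope; the package stops at normalized values and their
  group summaries.
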