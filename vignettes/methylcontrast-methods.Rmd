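---
title: "Models and methods in methylcontrast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in methylcontrast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

methylcontrast contrasts DNA methylation array cohorts of two tumour
groups (by convention labelled CNF and PNF, cutaneous and plexiform
neurofibroma) with a pipeline of five statistical stages plus a
synthetic-cohort generator. This vignette explains each model, its
assumptions, the tunable parameters, and the design choices made where
the design was genuinely open. It states no empirical result that the
test suite does not itself compute.

## 1. The per-probe model

Methylation at a CpG probe is a fraction $\beta \in (0,1)$. For each
probe we model the beta values directly with a beta likelihood and a
natural-logit link:

$$ y_{ij} \sim \mathrm{Beta}(\mu_{ij}\phi,\ (1-\mu_{ij})\phi), \qquad
   \mathrm{logit}(\mu_{ij}) = \mathbf{x}_{ij}^\top\boldsymbol\beta
   + u_{s(ij)} + v_{p(ij)} $$

with fixed effects for group, age and sex, a random intercept per array
slide $u_s \sim N(0, \sigma_s^2)$ and per patient nested within slide
$v_p \sim N(0, \sigma_p^2)$ (patients are repeatedly sampled; every
sample of a patient sits on that patient's slide). The precision $\phi$
is probe-specific. The group coefficient on the natural-logit scale is
the effect size; its exponential is the odds ratio.

**Estimation.** The random-effect integral is handled by a Laplace
approximation: an inner damped-Newton search for the joint mode of the
random-effect vector, and an outer bounded quasi-Newton (`nlminb`) over
fixed effects, $\log\sigma_s$, $\log\sigma_p$ and $\log\phi$. Two
implementation details matter in practice and are tested:

* the outer gradient is computed **analytically** by implicit
  differentiation through the inner mode (third derivatives of the beta
  log-likelihood enter via the log-determinant term); it is verified
  against central finite differences;
* design columns are standardised internally before optimisation and
  the estimates mapped back exactly. Without this, a covariate such as
  age in years makes the objective's condition number around $10^5$ and
  the optimiser stalls on a few percent of probes, which silently
  corrupts likelihood-ratio calibration.

Convergence is certified by the optimiser's own code or by a KKT check
on the analytic gradient (projected gradient below $10^{-2}$); a probe
that fails remains in the output flagged `converged = FALSE` and is
excluded from downstream selection, never thrown as an error. Boundary
beta values are squeezed with $(\beta(n-1)+0.5)/n$ before fitting.

**Testing.** Group significance is a likelihood-ratio test against the
same model without the group term (df = 1), BH-adjusted across probes.
DMPs are `q < 0.05` (strict); the high-effect subset uses
`|log OR| > log 4`, two-sided on the log scale because both hyper- and
hypomethylation are of interest. In the limit
$\sigma_s, \sigma_p \to 0$ the fit coincides with plain fixed-effect
beta regression; the test suite checks this against an independent
implementation (different likelihood code, different optimiser) to
$10^{-3}$ log-likelihood units per observation and 3 decimals on
coefficients.

## 2. Region calling

Per-probe Wald statistics $t_i$ are aggregated spatially with a
Gaussian kernel of bandwidth $\sigma = \lambda / C$
($\lambda = 1000$ bp, $C = 2$ by default):

$$ S_i = \frac{\sum_j w_{ij} t_j^2}{\sum_j w_{ij}}, \qquad
   w_{ij} = e^{-(p_i-p_j)^2 / 2\sigma^2}. $$

$S_i$ is a weighted mean of (approximately) $\chi^2_1$ variables, so we
attach a Satterthwaite effective df
$\nu_i = (\sum_j w_{ij})^2 / \sum_j w_{ij}^2$ and refer $\nu_i S_i$ to
$\chi^2_{\nu_i}$. After BH adjustment, significant probes at most `gap`
bp apart (default $\lambda$) are chained into regions; runs with fewer
than `min_cpgs = 2` probes are dropped. The region effect size is the
member quasi-beta fold-change (exponentiated model estimate) furthest
from 1 on the log scale; the two-fold filter is applied symmetrically
(`> 2` or `< 1/2`). Region significance is summarised as the minimum
member q; Stouffer and harmonic-mean combiners are available via the
`combine` argument because the choice is not dictated by the method
itself.

This module re-implements the published kernel-aggregation idea; exact
numerical parity with external region callers is a non-goal — planted
region recovery (interval Jaccard) is the test surface.

## 3. A/B compartments

Open-sea probes (at least 4 kb from an annotated island) are converted
to M-values, probes observed in at least half the samples are completed
by k-nearest-neighbour imputation (k = 10, Euclidean distance on shared
observed columns) and median-summarised in 100 kb genome-anchored bins.
Per group and chromosome, the first eigenvector of the bin-bin Pearson
correlation matrix gives the compartment track: positive entries are A
(open), negative B (closed).

Design choices a reader should know:

* **Per-sample centering.** Binned M-values are column-centred before
  the correlation. Sample-level global offsets (slide, patient, global
  methylation level) otherwise contribute an all-positive rank-one
  component that can dominate the leading eigenvector. Verified
  empirically in the test suite: without centering, planted block signs
  are recovered at chance; with it, near-perfectly.
* **Orientation.** The sign of an eigenvector is arbitrary. The track
  is oriented to correlate positively with per-bin probe density, a
  proxy for gene/CpG-dense open chromatin; when that correlation is
  negligible (|r| < 0.1, as in the synthetic world where density is
  uniform) the first informative bin is made positive. Both groups
  anchor identically, which is what cross-group sign comparison needs;
  the generator keeps the first block of every chromosome concordant so
  the anchor is well-defined.
* **Discordance.** Bins with $|e| < 0.02$ in either group are
  `filtered`; among the rest, opposite signs are `discordant`. The
  concordance fraction is concordant / (concordant + discordant).
  Bins with no probes are missing, never zero-filled. X and Y are
  excluded.
* The bin convention follows half-open 100 kb intervals anchored at
  coordinate zero, with a position at an exact bin multiple opening the
  next bin (so position 100,000 is the first position of the second
  bin).

## 4. Tumour-size association

Within the sized group (CNF), each probe gets a beta GLMM with size in
millimetres as a linear fixed effect, age and sex as covariates, and a
patient random intercept only (deliberately not slide-nested — repeated
sampling is the concern here). Probes significant by LRT + BH are then
rank-correlated with size using Kendall's tau-b (tie-corrected;
two-sided p exact by enumeration for $n \le 8$ without ties, normal
approximation otherwise), BH again, and finally filtered on
delta-beta = max − min beta strictly greater than 0.2. All three
per-probe quantities are recorded so the composition is auditable in
any order.

## 5. Bias-aware enrichment

Arrays cover genes with very different probe counts, so a gene with
more probes is more likely to harbour a significant probe by chance.
Gene-set over-representation therefore uses the Wallenius noncentral
hypergeometric urn: genes inside the tested set draw with odds equal to
the ratio of mean per-gene probe counts inside versus outside the set.
The pmf is computed by the exact sequential-weighted-draw dynamic
program (not the integral representation, which is numerically fragile
for peaked cases); at equal weights it reduces to the central
hypergeometric to machine precision, which the suite checks against a
one-sided Fisher oracle at $10^{-6}$.

## 6. The synthetic world

`sim_config()` / `simulate_cohort()` generate an EPIC-like cohort with
a full planted-truth record. The defaults are the stated world of the
test suite; they were chosen once, from the cohort structure the
pipeline targets, and are not tuned to test outcomes:

| parameter | default | why |
|---|---|---|
| patients per group × tumours | 15 × 2 | two-group cohort of ~60 samples with repeated sampling |
| slides | 8 | EPIC slides hold 8 samples; patients nested in slides |
| $\sigma_{slide}, \sigma_{patient}$ | 0.3, 0.3 logits | moderate technical + subject variation |
| $\phi$ | 50 | beta-value noise sd ≈ 0.07 at $\mu = 0.5$, typical for arrays |
| group effect $\delta$ | 1.5 logits (random sign) | a clear but not trivial DMP effect |
| fraction DMP | 5% | sparse signal |
| islands | 1 kb every 50 kb, 30% of probes packed inside | EPIC-like island-dense, open-sea-sparse coverage; region calling at $\lambda = 1$ kb needs it |
| compartment blocks | 500 kb, alternating, 15% discordant | matches the 80–85% concordance regime |
| detection failures | 0.5% of entries | realistic failed-probe rate |

Random intercepts are drawn **independently per probe** — the exact
data-generating process the per-probe model assumes. A single shared
draw across probes would couple every probe's group estimate to one
realised patient imbalance, making single-cohort calibration tests
meaningless (verified with an independent mixed-model implementation).
Sample-level structure shared across probes is carried instead by the
compartment latents: a per-block latent (within-block correlation) and
a chromosome-wide anticorrelated A/B latent whose sign flips between
groups in discordant blocks.

What the generator does **not** emulate: two-channel intensities and
their normalisation, probe-sequence biases, cell-type mixtures,
copy-number contamination, spatially varying probe density beyond the
island clusters. A green test therefore establishes that the
statistical machinery recovers planted truth under the model's own
assumptions — not that the upstream normalisation of a real cohort is
handled.

## 7. Numerical conventions and degenerate inputs

* Coordinates are 1-based inclusive internally; BED/bedGraph exports
  convert to 0-based half-open at the boundary.
* Detection p-values pass strictly below 0.01; sample dropping is
  strictly above 10% failed; DMP/q thresholds are strict `<`;
  delta-beta is strict `>`; the eigenvalue filter retains `>= 0.02`.
* BH ties are broken by stable sort (input order); q-values are capped
  at 1 and reinserted as `NA` for skipped fits.
* Degenerate inputs (empty cohorts, all-blacklisted matrices, constant
  size vectors, singular designs, zero-variance bins) yield empty
  results, skipped-fit records, or named errors — never crashes deep in
  a stage.
* Identical `(config, seed)` pairs regenerate byte-identical cohorts,
  and the full pipeline at a fixed seed writes byte-identical outputs.

## Known limitations

* The Laplace approximation can be optimistic for very small groups or
  extreme $\phi$; no adaptive quadrature fallback is provided.
* Region significance via minimum member q is anti-conservative as a
  *p*-value; it is used as a ranking/selection device, as in the
  source methodology, with alternative combiners exposed.
* The enrichment bias correction uses a single odds parameter (mean
  probe count in vs out of set), the standard approximation; a fully
  per-gene-weight urn is not implemented.
* The Shapiro-Wilk gate in `correlate()` uses alpha = 0.05 per vector;
  with many correlations this gate is itself a multiple-testing event
  the caller should be aware of.
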