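---
title: "Proteome-wide two-sample MR: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteome-wide two-sample MR: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pqtlmr implements the analysis machinery for asking, at proteome scale,
whether circulating protein levels causally influence disease risk or a
quantitative trait. The design is two-sample Mendelian randomization:
protein quantitative trait loci (pQTLs) estimated in one sample serve as
instruments, and their associations with the outcome phenotype come from an
independent GWAS. Because instruments are germline variants, the resulting
estimates are immune to the reverse causation and treatment confounding
that plague case-control biomarker studies — provided the instrumental
assumptions hold, which is exactly what the sensitivity battery interrogates.

This vignette records the models, the tunable parameters and their
defaults, what the synthetic generator does and does not emulate, and the
design decisions taken where more than one defensible choice existed.

## The causal model and the primary estimator

For instrument $j$, let $\hat\beta_{Xj}$ (SE $\sigma_{Xj}$) be its
per-allele effect on standardized protein level and $\hat\beta_{Yj}$ (SE
$\sigma_{Yj}$) its effect on the outcome (log-odds for case-control
phenotypes). Under the instrumental assumptions each ratio
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the causal effect
$\theta$. The primary estimator is the inverse-variance-weighted (IVW)
average of the ratios,

$$\hat\theta = \frac{\sum_j w_j \hat\theta_j}{\sum_j w_j}, \qquad
  w_j = \mathrm{Var}(\hat\theta_j)^{-1},$$

with the second-order delta-method variance
$\mathrm{Var}(\hat\theta_j) = \sigma_{Yj}^2/\hat\beta_{Xj}^2 +
\hat\beta_{Yj}^2\sigma_{Xj}^2/\hat\beta_{Xj}^4$ (first-order weights are
available by flag; with first-order weights IVW is identical to the
weighted least-squares slope of $\hat\beta_Y$ on $\hat\beta_X$ through the
origin, which the test suite exploits as an independent oracle). A single
usable instrument routes to the Wald ratio instead; roughly 40% of
cis-pQTL analyses in practice end up there, so the pipeline treats it as a
first-class path with its own flag.

Heterogeneity is measured by Cochran's
$Q = \sum_j w_j(\hat\theta_j - \hat\theta)^2$ against $\chi^2_{J-1}$.
Under `random_effects = "auto"` (the default) the IVW SE is inflated
multiplicatively by $\max(1, \sqrt{Q/(J-1)})$ when $J \ge 4$, and left at
fixed effects for smaller sets, where the inflation estimate is too noisy
to help. The floor at 1 means heterogeneity can only widen, never narrow,
confidence intervals.

## The sensitivity battery

Each method trades efficiency for robustness to a different violation:

* **Robust IVW** (`mr_ivw_robust`) — through-origin M-estimation of
  $\hat\beta_Y/\sigma_Y$ on $\hat\beta_X/\sigma_Y$ with the Tukey biweight
  (tuning 4.685, 95% efficiency under normality), sandwich SE. Downweights
  a few outlying ratios without modelling them.
* **MR-Egger** (`mr_egger`) — weighted regression *with* an intercept
  after orienting all instruments to $\hat\beta_X \ge 0$. The slope is
  consistent under InSIDE even when every instrument is pleiotropic; the
  intercept estimates the mean direct effect and its test is the standard
  directional-pleiotropy diagnostic. Solved in closed form from the
  weighted normal equations; the residual dispersion multiplier is floored
  at 1 like the IVW inflation.
* **Weighted median** (`mr_weighted_median`) — consistent while valid
  instruments carry more than half the total weight. The point estimate
  interpolates the weighted 0.5-quantile of the ordered ratios; the SE is
  a seeded parametric bootstrap that redraws both $\hat\beta_X$ and
  $\hat\beta_Y$ from their sampling distributions.
* **Weighted mode** (`mr_weighted_mode`) — the argmax of a weighted
  normal-kernel density over the ratios, bandwidth
  $\varphi \cdot 0.9\min(\mathrm{sd},\mathrm{mad})J^{-1/5}$; consistent
  when the largest homogeneous cluster is valid.
* **Contamination mixture** (`mr_conmix`) — each instrument is explained
  by a valid component $N(\theta, \mathrm{Var}(\hat\theta_j))$ or an
  invalid component $N(0, \mathrm{Var}(\hat\theta_j) + \psi^2)$; the
  profile log-likelihood is maximized over a grid of $\theta$ and the 95%
  CI collects grid points within $\chi^2_1(0.95)/2$ of the maximum.
* **MR-PRESSO** (`mr_presso`) — a global residual-sum-of-squares test
  against a parametric null built from leave-one-out IVW predictions,
  per-instrument outlier tests (Bonferroni across instruments), an
  outlier-corrected IVW, and a distortion test comparing the observed
  raw-vs-corrected shift with the shift from removing random subsets.
* **Constrained ML** (`mr_cml`) — exactly $K$ instruments receive free
  pleiotropy parameters; coordinate ascent alternates "pick the $K$
  largest standardized residuals" with "re-estimate $\theta$ from the
  valid set", and $K$ is chosen by BIC. This is the BIC-selection variant
  without model averaging or data perturbation.

**Directionality.** The Steiger test sums per-variant variance explained
on both sides, $r^2_j = \beta_j^2 / (\beta_j^2 + \sigma_j^2 n)$ (the
$2p(1-p)$ heterozygosity factors cancel), converts both sums to
correlations and compares them with a two-sample Fisher-z statistic. A
non-significant Steiger verdict triggers reverse MR: the phenotype's own
genome-wide-significant variants become instruments against the protein.
For binary outcomes the observed-scale approximation is used and flagged
as approximate in the result.

## Instrument selection

The selection pipeline is significance filter → cis/trans classification →
greedy LD clumping → weak-instrument screen, with per-stage counts
retained. Defaults, all surfaced in `instrument_config()`:

| parameter | default | rationale |
|---|---|---|
| `p_threshold` | 5e-8 | genome-wide significance |
| `cis_window_bp` | 1e6 | ±1 Mb around the gene body; the conventional cis definition |
| `clump_r2` | 0.01 | near-independence, as the IVW likelihood assumes |
| `clump_window_bp` | 1e7 | clumping horizon |
| `min_f` | 10 | conventional weak-instrument bar, $F \approx (\hat\beta/\sigma)^2$ |

Clumping is greedy best-p-first with a total tie-break (p-value, then
variant id), so selection is fully deterministic. Variants absent from the
LD panel are treated as unlinked with a warning — partial panels are the
norm. The $F$ statistic uses the $(\hat\beta/\sigma)^2$ summary
approximation because individual-level $r^2$ is unavailable.

**Harmonization.** Outcome records are aligned to the exposure's effect
allele by swap-and-sign-flip and/or strand complement. Palindromic (A/T,
C/G) variants are kept only when both allele frequencies are known, on the
same side of 0.5, and outside [0.42, 0.58]; anything else is retained with
`drop_reason = "palindromic_ambiguous"` and excluded from estimation. This
conservative policy is a documented default, not a universal standard;
0.42 is adjustable. Missing outcome frequency is tolerated for
non-palindromic variants, where alleles alone identify the orientation.

## Multiple testing and meta-analysis

Tests are counted separately for cis and trans runs; the Bonferroni level
is $0.05/m_{\text{class}}$ with the realized denominator printed in the
run manifest, because the tested fraction of the proteome is
study-specific. Benjamini–Hochberg FDR runs within each phenotype × class
stratum and the realized per-stratum p-value threshold is reported, so a
study can quote "FDR significant below $p = \dots$" per phenotype. Because
every stratum is a subset of its class, Bonferroni significance implies
FDR significance — the tier ordering is structural, and the tests assert
it on every run.

Cross-cohort combination is fixed-effect inverse-variance on the causal
effect estimates, matched by gene symbol (assay ids differ across
platforms); multi-assay collisions keep the assay with the most
instruments and log the fact. With only two cohorts a random-effects
between-cohort variance is not estimable with any stability, hence
fixed-effect; this is a documented choice, as is combining effects rather
than p-values.

## The synthetic generator

`mr_scenario()` + `simulate_protein_scenario()` generate summary
statistics with known ground truth; `simulate_study()` assembles a full
two-cohort, four-phenotype study bundle (TSVs + YAML config) whose shape
mirrors the real design: exposure panels of 34,557 and 35,559 individuals,
case-control outcomes of 67,323/93,456 (SCZ-like), 40,463/313,436
(BIP-like), 166,773/507,679 (MDD-like) and a quantitative outcome of
215,333 (CTP-like). Defaults: J = 30 instruments jointly explaining 5% of
protein variance, allele frequencies uniform on (0.05, 0.5), no
pleiotropy, between-cohort effect correlation 0.5.

Generative model: variance-explained shares are drawn and scaled so the
true per-variant effects $b_j$ on the unit-variance protein hit the target
$\sum_j 2p_j(1-p_j)b_j^2$ exactly; observed effects add
$N(0, \sigma^2)$ noise with $\sigma = (2p(1-p)n)^{-1/2}$ (log-odds scale
SEs use $n_{\text{case}}n_{\text{control}}/n$ in place of $n$). Outcome
effects are $\theta b_j + \alpha_j$. Pleiotropy regimes: `balanced`
($\alpha \sim N(0,\sigma_\alpha^2)$), `directional`
($\alpha$ drawn around $\mu_\alpha$ and aligned with the
exposure-increasing allele, i.e. multiplied by $\mathrm{sign}(b_j)$ — a
direct effect that is "directional" regardless of allele coding, which is
what makes the Egger intercept estimate $\mu_\alpha$ after orientation),
and `correlated` ($\alpha_j \propto b_j$ plus noise, violating InSIDE).
`reverse_causal = TRUE` flips the arrow: variants act on the outcome and
the protein responds with coefficient $\theta$, so variance explained
concentrates on the outcome side and Steiger should flip.

In `simulate_study()` each cohort gets a disjoint variant panel (different
platforms index different variants), one outcome file per phenotype stacks
all panels, and per-protein causal effects are drawn per phenotype —
null with probability `prop_null`, otherwise $N(0, \theta_{sd}^2)$ with
correlation $\rho_c$ across cohorts. That correlation at the *effect*
level is what cross-platform concordance of per-protein MR estimates
recovers; with strong instruments the estimation noise attenuates it only
marginally. Per-protein seeds derive from (master seed, protein index), so
extending a study never perturbs existing proteins.

What the generator does **not** emulate: linkage disequilibrium beyond an
optional block mode with one r² = 0.9 shadow per instrument (estimators
assume post-clumping independence anyway); sample overlap between exposure
and outcome GWAS; allele-frequency mismatch between cohorts; population
stratification; winner's-curse correlation between selection and effect
estimates beyond what the significance filter itself induces; liability
versus observed-scale subtleties for binary traits beyond the log-odds SE
approximation. Passing tests on synthetic data therefore demonstrate
estimator and pipeline correctness under the stated model, not robustness
to every artefact of real GWAS data.

## Numerical choices and degenerate inputs

* **ConMix grid.** `theta_grid = c(-2, 2, 0.001)` is interpreted on a
  standardized scale: the evaluated grid is
  $\bar\theta_w + z\,\mathrm{sd}(\hat\theta_j)$, centred on the weighted
  ratio mean so that a non-zero causal effect is always coverable; hitting
  a boundary warns. $\psi$ defaults to $1.5\,\mathrm{sd}(\hat\theta_j)$.
* **cML BIC penalty.** $K\log n$ with $n$ the smaller GWAS sample size.
  Penalizing by $\log J$ would sit below the expected maximal residual
  reduction ($\approx 2\log J$) and inflate $K$ on clean data; the
  sample-size penalty restores consistent selection.
* **MR-PRESSO resolution.** Outlier p-values are Bonferroni-multiplied by
  $J$, so `n_sim` must exceed $J/\alpha$ for any outlier to be flaggable;
  with the default `n_sim = 1000` and $J \le 50$ that holds at
  $\alpha = 0.05$. Empirical p-values use the $(1+\#)/(n+1)$ form and can
  never be exactly zero.
* **Egger and weak instruments.** The intercept estimates the mean direct
  effect only when slope attenuation from instrument noise is negligible;
  the recovery simulations therefore use mean $F \approx 60$. At
  $F \approx 15$ the attenuation transfers visibly into the intercept.
* **Weighted-median SE.** The parametric bootstrap is mildly conservative:
  across 800 null replicates its mean SE exceeded the empirical sampling
  SD by ~14%, putting the nominal-0.05 rejection rate near 0.025–0.03.
  This is a property of the bootstrap itself (shared by the standard
  implementations), and is left as is rather than rescaled.
* **Selection-induced attenuation.** Applying the 5e-8 filter to
  borderline instruments (per-variant $z \approx 6$–7) induces
  winner's-curse attenuation of every downstream estimator. Recovery
  properties are therefore evaluated on instruments as given, or with
  instrument strength high enough (total $r^2 = 0.15$ at $J = 50$) that
  selection is neutral; this is a statement about study design, not a
  software tolerance.
* **Ties and determinism.** All orderings have total tie-breaks; every
  stochastic step takes a seed derived from the run-level master seed and
  stable string labels via a 31-bit multiplicative hash, so runs are
  bit-reproducible and insensitive to protein ordering. Sign-flipping an
  instrument's alleles leaves every point estimate unchanged; bootstrap
  SEs are flip-invariant in distribution only, since the RNG stream maps
  onto different instruments.
* **p-value floor.** Two-sided normal p-values are floored at 1e-300 so
  extreme signals survive text round-trips without denormal-parsing
  artefacts.

## Problem sizes used by the checks

The packaged property checks run at: calibration 1000 replicates (J = 30,
n = 30,000 per side; MR-PRESSO 500 replicates at 300 simulations);
recovery and pleiotropy robustness 500 replicates (J = 50, total
$r^2 = 0.15$, 30% invalid at $\mu_\alpha = 0.05$); Egger-intercept
recovery 200 replicates (J = 100, all instruments pleiotropic);
directionality 300 forward and 200 reverse replicates; determinism on a
bundled 20-protein, four-phenotype, two-cohort study (bootstrap 500,
PRESSO 200 in the bundled config); concordance on 300 proteins at
$\rho_c = 0.5$. These sizes keep Monte-Carlo error comfortably inside the
asserted bands.

## Known limitations

* No multivariable MR, MR-RAPS, CAUSE, or Egger-robust hybrid; the battery
  is the ratio-based suite described above.
* Confounder and PheWAS filtering consume user-supplied variant lists;
  there are no live database queries.
* LD handling is clumping against a supplied r² matrix; no reference-panel
  computation or proxy search.
* Binary-outcome Steiger uses an observed-scale approximation.
* The enrichment module is the generic hypergeometric/Fisher statistic
  over GMT collections with BH correction — network-aware (PPI edge)
  enrichment needs a graph null model and is out of scope. The default
  background is the set of proteins actually tested, not the genome;
  using the genome would overstate enrichment because the assay panel is
  already biased toward disease-relevant proteins.
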