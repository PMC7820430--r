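---
title: "Constructing soil health indices for split-factorial saline irrigation trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing soil health indices for split-factorial saline irrigation trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilhealth)
```

## The problem

Salt-affected soils under saline irrigation respond to management —
tillage intensity, deficit irrigation, residue mulching — through many
partially redundant chemical and biological attributes. A soil health
index (SHI) compresses a 14-attribute profile (pH_s, EC_e, organic C,
available N/P/K, microbial biomass C/N and their ratio, five enzyme
activities) into a single bounded score per plot so that treatments can be
ranked and related to yield. This package implements that construction
together with the split-plot statistics such trials require.

## The index model

Per crop season (sorghum and wheat are always analysed separately, since
their soil environments differ systematically):

1. **Standardization.** Each attribute is centered and scaled to unit SD
   (denominator $n-1$), so the PCA operates on the correlation matrix and
   no attribute dominates through its units.
2. **PCA.** Eigendecomposition of the sample correlation matrix.
   Eigenvalues sum to the number of attributes (checked at every run);
   loadings are unit eigenvectors. The sign of each PC is fixed so that
   its largest-magnitude loading is positive — eigenvectors are only
   defined up to sign, and without this convention the selected indicator
   set could depend on the eigensolver.
3. **Retention.** PCs with eigenvalue $\ge$ `eigen_min` (default 1.0)
   *and* variance share strictly above `var_min` (default 0.05) are
   retained. The eigenvalue gate is the Kaiser-type rule standard in
   index construction; `eigen_min = 0.99` expresses the slightly laxer
   "eigenvalue > 0.99" variant some analyses use, and both are plain
   configuration values.
4. **Minimum data set.** Per retained PC in order, the attribute with
   the highest $|$loading$|$ is selected together with every attribute
   whose $|$loading$|$ is within `within_frac` (default 10 %) of that
   maximum, boundary inclusive; ties keep input-attribute order so the
   selection is deterministic. An attribute already selected from an
   earlier PC is removed from later PCs' candidate sets — each PC then
   contributes the strongest *new* information rather than re-nominating
   the same attribute. Optional redundancy pruning (`redundancy_r`)
   drops, among co-selected attributes of one PC correlated above the
   cutoff, all but the highest loader; it is **off** by default because
   strongly correlated co-selections (e.g. a salinity marker and a
   microbial attribute) are frequently retained together in practice.
5. **Scoring.** Linear 0–1 scoring functions:
   *more is better* $s = (x - x_{\min})/(x_{\max} - x_{\min})$,
   *less is better* $s = (x_{\max} - x)/(x_{\max} - x_{\min})$,
   *optimum* rising linearly to 1 at a midpoint and falling beyond, with
   the half-width taken to the farther observed bound so the extremes
   score 0. Bounds default to the observed per-season minimum/maximum
   (each indicator then attains both 0 and 1) and can be fixed via
   `bounds` for cross-study comparability. A ratio variant
   ($x/x_{\max}$, $x_{\min}/x$) sits behind `method = "ratio"` for
   sensitivity analysis only.
6. **Weights.** Every indicator selected from a PC receives that PC's
   full variance share as $w_i$; weights are *not* split among
   co-selected indicators and are *not* normalized by default, so
   $\sum w_i$ generally differs from 1 and the index maximum is
   $\sum w_i$, reported alongside the index. `normalize = TRUE` divides
   by the cumulative share of the retained PCs, making the distinct PC
   weights sum to 1. Un-normalized shares are the default because that is
   the convention under which published index weights are typically
   printed; forcing normalization would silently change the index scale.
7. **Index.** $\mathrm{SHI} = \sum_i w_i s_i$ per plot, so
   $0 \le \mathrm{SHI} \le \sum_i w_i$ with both bounds attained at
   all-extreme plots. Treatment means and Tukey letters are computed
   *after* the plot-level index, and the plot-level values feed the same
   split-factorial ANOVA as any measured attribute.

### Scoring directions

Directions are a scientific prior, not a measurement, so they are
defaults and flagged as such: EC_e and pH_s are stressors in
salt-affected soil (*less is better*); organic C, available N/P/K,
microbial biomass and all enzyme activities indicate function (*more is
better*). The MBC:MBN ratio has no monotone interpretation — both very
wide and very narrow microbial C:N suggest a perturbed community — so it
defaults to *optimum* at the observed median. All directions and the
optimum midpoint are overridable in `scoring_spec()`.

### A note on monotonicity

With observed-bounds scoring the index is *relative to the sampled
plots*: lowering one plot's EC_e can move the observed bounds and thereby
lower another plot's score. The intuitive monotonicity property — lower
salinity never hurts any plot's index — holds exactly under fixed
(configured) bounds, and that is how the property is verified in the test
suite.

## The split-factorial ANOVA

Tillage sits on main plots within blocks and is crossed with year;
irrigation × mulch sits on subplots. Replication, year, tillage and
year × tillage are therefore tested against the whole-plot residual
("Error (a)"; 10 df in the reference 3-block × 2-year × 3-tillage
design), and every term involving irrigation or mulch against the subplot
residual (60 df). Design decisions, chosen to reproduce the reference
df skeleton exactly:

* **Year is a crossed fixed whole-plot factor**, not a repeated measure
  with autocorrelation. A short two-year series gives no basis for
  estimating a serial-correlation structure, and the fixed-crossed layout
  is what the reference df table implies.
* **Replication (block) is a fixed whole-plot term** (2 df); no
  random-effects machinery is used anywhere.
* **Only balanced complete data are supported**; imbalance is a hard
  error rather than a silent fall-back to Type-III sums of squares,
  because the balanced decomposition is exact and unambiguous.
* **Tukey letters for a factor use the stratum-appropriate error mean
  square**, and the effective $n$ per level counts all plot-level
  observations contributing to the mean (36 per tillage or irrigation
  level, 54 per mulch level in the reference design) — matching how
  single-letter main-effect displays are printed in trial reports. This
  is a display convention, configurable through `tukey_hsd()` directly.
* Compact letters come from the insert-and-absorb procedure; with a
  single common threshold (HSD or LSD) non-separation is an interval
  property on the sorted means, which the implementation exploits and
  the test suite cross-checks against brute-force all-pairs comparisons.

The sums of squares themselves are computed through `stats::aov` with an
`Error(block:year:tillage)` stratum — the standard balanced split-plot
projection — and are verified in the tests against an independent
brute-force marginal-means decomposition.

## What the synthetic generator emulates

`synthetic_config()` encodes the reference trial: 3 blocks × 2 years ×
3 tillage (CT/RT/ZT) × 3 saline-irrigation levels (100/80/60 % of wheat
crop water requirement) × 2 mulch levels, 108 plots per season. Each
attribute is

$$x = \mu + \textstyle\sum \text{factor deviations} + b_{\text{block}}
      + c\,\sigma\, Z_{\text{plot}} + \sqrt{1-c^2}\,\sigma\,\varepsilon$$

with a single latent plot-salinity variable $Z$ shared by all attributes
of a plot-season. The parameterization keeps every attribute's residual
SD at $\sigma$ while giving exactly $\mathrm{corr}(i,j) = c_i c_j$, so
positive-definiteness reduces to $|c_i| < 1$ and the implied correlations
have a closed form (`ground_truth()`).

Default anchoring, chosen once:

* **Baselines and treatment deviations** for pH_s, EC_e, organic C and
  N/P/K come from the published per-level treatment means shipped in
  `inst/extdata/reference_treatment_means.csv` — e.g. the EC_e
  irrigation contrast of ≈ 0.73 dS m⁻¹ after sorghum and ≈ 1.19 dS m⁻¹
  after wheat, the mulch-driven salinity reduction after wheat, and the
  tillage shifts in Olsen's P and extractable K.
* **Residual SDs** follow the stated rule SD ≈ SE_m × √n from the
  published standard errors of treatment means (n = 36 plots per
  irrigation level).
* **Microbial and enzyme baselines** are not printed numerically in the
  reference tables (figures only), so field-typical values consistent
  with the reported MBC:MBN ranges (≈ 7.8–8.4 after sorghum, ≈ 7.4–8.0
  after wheat) were fixed once; they are in assay units and only their
  relative structure matters downstream.
* **Couplings** default to $c_{EC_e} = 0.7$ against $-0.3$ to $-0.5$ on
  MBC, MBN, DHA, urease, alkaline phosphatase and β-glucosidase, giving
  implied residual correlations of about $-0.2$ to $-0.35$ — the
  magnitude reported for EC_e–microbial relationships in saline trials.
* **Year effects** (salinity lower, microbial N higher in year 2) and
  small Gaussian block intercepts keep the Year and Replication ANOVA
  terms non-trivial.
* **Yields** are linear in attribute deviations (dominated by EC_e,
  negatively) plus Gaussian noise, so the SHI–yield regression has a
  positive true slope in both seasons.

Attributes are truncated at zero with a message; default SDs make
truncation rare. MBC:MBN is always computed as MBC/MBN, never sampled.

What the generator does **not** emulate: mechanistic soil–water–salt
balance, weather drivers, spatial autocorrelation between neighbouring
plots, non-Gaussian tails, and measurement error structure per assay.
Passing tests therefore demonstrate that the *pipeline* behaves correctly
on data with the assumed covariance and design structure — not that any
particular field result is reproduced. In particular the published PCA
loadings, variance shares and treatment SHI values depend on unpublished
plot-level data and are checked structurally (same rules, same df
skeleton, same contrast arithmetic), not numerically.

## Numerical choices and degenerate inputs

* Eigendecomposition uses `eigen(symmetric = TRUE)`; eigenvalues are
  clipped at zero against round-off.
* Zero-variance attributes abort standardization by name; degenerate
  scoring bounds ($x_{\max} = x_{\min}$) abort scoring.
* The within-10 % boundary comparison is inclusive ($\ge$), with stable
  input-attribute order on ties.
* $R^2$ of the SHI–yield regression is computed as
  $1 - SS_{res}/SS_{tot}$ directly, with the convention $R^2 = 0$ for a
  constant yield; the slope test is a plain $t$ on $n-2$ df.
* Validated tables recompute MBC:MBN from its components and warn when a
  supplied column disagrees by more than 1 %; numeric round trips through
  the text format are exact to better than $10^{-9}$ relative (15
  significant digits written).
* All randomness flows through a single integer seed; identical
  configuration and seed give byte-identical report bundles.

## Problem sizes used in the checks

The test suite exercises the reference design (108 plots per season), a
50-block variant for effect-recovery consistency, 1000 null-generator
replicates for the type-I error of both ANOVA strata (accepted band
0.03–0.07 at $\alpha = 0.05$), and 200 seeded tables with planted
two-latent-factor structure (within-pair correlations 0.90 and 0.72 at a
pooled two-season size of 216 observations) for minimum-data-set
recovery, which must succeed in at least 95 % of seeds. The acceptance
script repeats the simulation-based checks at 500 replicates.

## Known limitations

* No varimax or other factor rotation; selection operates on raw PCs.
* No nonlinear (sigmoid curve-family) scoring; the linear forms above
  are the only built-ins.
* No mixed-model/REML path and no unbalanced designs — by construction.
* Scoring bounds default to per-season observed ranges; indices are
  comparable across studies only with configured bounds.
* The MBC:MBN *optimum* direction is a package default on an attribute
  whose ideal is genuinely uncertain; sensitivity to it should be checked
  via `scoring_spec()` overrides when it enters an MDS.
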