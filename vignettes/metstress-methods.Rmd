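---
title: "Methods: multi-environment stress-tolerance analysis with metstress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-environment stress-tolerance analysis with metstress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metstress)
```

## The problem

Terminal heat and combined heat–drought stress are the dominant yield
constraints for wheat sown in hot, semi-arid regions. The standard field
protocol contrasts a timely-sown, irrigated crop (the optimum environment,
OE) with a late-sown irrigated crop (heat stress, HSE) and a late-sown crop
with irrigation withheld during the reproductive phase (combined
heat–drought stress, HDSE), replicated across locations and seasons in an
alpha-lattice design. `metstress` implements the complete analysis of such
a trial: validated long-format data handling, descriptive statistics,
factorial ANOVA with variance components and broad-sense heritability,
percent reductions under stress, per-environment trait association, and
selection of tolerant genotypes through stress indices.

## Data model

The canonical exchange format is a tidy, plot-level CSV: one row per
genotype × location × year × environment × replicate × block, with eleven
trait columns (`DFF`, `DM`, `PH`, `NT`, `SL`, `NSS`, `NGS`, `TKW`, `BY`,
`HI`, `SY`). Design notes:

* **Year is an opaque season label** (`"2020-21"`), never parsed
  numerically, because winter-wheat seasons straddle calendar years.
* **Missing trait values propagate as missing**; nothing is imputed as
  zero, and every operation states its own missing-data policy (e.g.
  genotypes missing one arm of a stress contrast are excluded with a
  warning).
* `TKW` is stored as an opaque kernel weight in grams; the package does not
  rescale between 100-kernel and 1000-kernel conventions.
* `HI` is a measured trait but is definitionally `100 * SY / BY`; when all
  three are present and the stored value deviates by more than 0.5
  percentage points, validation warns and keeps the stored value.

## Stress indices

With $Y_p$ and $Y_s$ a genotype's mean yield under optimum and stress
conditions (years and replicates pooled, per location) and
$\bar{Y}_p, \bar{Y}_s$ the means over all entries:

$$\mathrm{STI} = \frac{Y_p Y_s}{\bar{Y}_p^2}, \qquad
  \mathrm{SSI} = \frac{1 - Y_s/Y_p}{1 - \bar{Y}_s/\bar{Y}_p}, \qquad
  \mathrm{MP} = \frac{Y_p + Y_s}{2},$$
$$\mathrm{TOL} = Y_p - Y_s, \qquad
  \mathrm{MSTI} = \frac{Y_s^2}{\bar{Y}_s^2}\,\mathrm{STI}, \qquad
  \mathrm{GMP} = \sqrt{Y_p Y_s}.$$

The denominator of SSI is the stress intensity
$SI = 1 - \bar{Y}_s/\bar{Y}_p$; a non-positive $SI$ means the "stress"
environment did not yield below the optimum and the contrast is refused
rather than silently inverted. GMP carries no printed formula in the trial
reports this package mirrors; the standard geometric-mean definition is
adopted and the column is marked a convention. Population means include
only genotypes with both arms observed, unweighted. Negative TOL (a yield
gain under stress) is flagged, never clamped.

Selection takes the top *k* (default 5) by descending STI as tolerant and
the top *k* by descending SSI as susceptible; ties break by higher stress
yield, then genotype identifier. Report rows are rounded
half-away-from-zero at the conventional precisions (yields, MP, TOL, GMP to
integers; STI and SSI to 2 decimals; MSTI to 1); all internal computation
is full precision.

## ANOVA, variance components and heritability

All factors are **fixed at the estimation step**: ordinary least squares
with sequential (type-I) sums of squares in the canonical term order
(Location, Year, Env, Gen, their interactions with genotype, Rep,
Block(Rep)), and F tests against the residual mean square. This reproduces
the classical mean-squares layout of alpha-lattice trial reports; a
REML/mixed-model fit would not yield a sum-of-squares decomposition. On
balanced data the main-effect SS are order-invariant. Unbalanced data are
rejected explicitly — there is no silent switch to another SS type. Blocks
are fixed and nested in replicates (`Block(Rep)`), i.e. the intra-block
analysis of the lattice; inter-block information recovery is not
identifiable from the reported layouts and is out of scope.

The random nature of locations, years and environments is honoured
downstream. With $l$ locations, $y$ years, $e$ environments, $r$
replicates, the expected-mean-squares (method-of-moments) solve gives

$$\hat\sigma^2_{GL} = \frac{MS_{GL} - MS_e}{y e r},\quad
  \hat\sigma^2_{GY} = \frac{MS_{GY} - MS_e}{l e r},\quad
  \hat\sigma^2_{GE} = \frac{MS_{GE} - MS_e}{l y r},$$
$$\hat\sigma^2_{G} = \frac{MS_G - MS_{GL} - MS_{GY} - MS_{GE} + 2 MS_e}{l y e r},$$

with negative solutions truncated to zero and flagged. Broad-sense
heritability is the entry-mean form

$$H^2 = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_{GL}/l + \sigma^2_{GY}/y +
  \sigma^2_{GE}/e + \sigma^2_\varepsilon/(lyer)} \times 100,$$

clamped to $[0, 100]$. This is a documented convention: published trial
tables print an H² row without stating a formula, so the package's value is
its own, internally consistent definition rather than a reproduction.

Post-hoc comparisons support LSD
($t_{1-\alpha/2,df_e}\sqrt{2MS_e/n}$) and Tukey HSD
($q_{\alpha,k,df_e}\sqrt{MS_e/n}$) on balanced groups, with strict
inequality at the critical value and a compact letter display. Because the
critical value is common to all pairs in a balanced layout, letter groups
are exactly the maximal runs of the sorted means whose range does not
exceed it.

## Percent reductions and association

Reductions are computed per genotype on pooled genotype × environment
means, then summarised across genotypes: the reported mean is the
**mean of per-genotype ratios**, not the ratio of population means. The two
differ on heterogeneous material, and a regression test pins the choice.
Computing on pooled means (rather than per plot) avoids pairing arbitrary
replicates across environments.

Trait association works on genotype means within one environment, pooled
over locations and years (n = number of genotypes): pairwise-complete
Pearson correlations with two-sided t-tests on $n-2$ df, starred at 0.05
and 0.01 without multiple-testing correction (mirroring conventional trial
reports; 55 pairs at $\alpha = 0.05$ imply a few false stars under the
null, which the type-I-error tests quantify). Single-predictor OLS
regressions of seed yield, ranked by $R^2$, identify the traits that carry
yield under each environment. Plot-level correlation is available behind
`unit = "plot"`.

## The synthetic trial generator

Raw plot data for trials of this kind are rarely deposited, so the package
ships a seeded generator whose defaults emulate the study design it
mirrors: 34 genotypes × 2 locations × 2 seasons × 3 environments × 2
replicates, each replicate split into 2 incomplete blocks (816 plots). For
a yield-type trait the plot value is

$$x = (\mu_{tj} + y_{tk} + g_{ti} + gl_{tij} + gy_{tik} + ge_{tim} +
  \text{rep} + \text{block} + \varepsilon)\; m_{tim},$$

with all effects Gaussian and the stress multiplier
$m_{tim} = 1 - (1 - \text{mult}_{tm})\, s_i$. Phenology responds by
additive shifts instead (flowering earlier, maturity gap shorter under
stress), biological yield is generated as seed yield plus a positive straw
component so the derived harvest index always lies in (0, 100), and
physical traits are truncated at zero with a warning if truncation exceeds
1% of draws.

Key default choices, each fixed once at design time:

* **Trait means and SDs** are anchored to the published magnitudes of such
  trials (seed yield 790 g/plot, SD 242 g at the higher-yielding location
  under OE; 598 g at the other).
* **Stress multipliers** for seed yield are 0.80 (HSE) and 0.64 (HDSE),
  i.e. expected reductions of 20% and 36%; the other multiplicative traits
  use the corresponding published mean reductions. One global multiplier
  set is used for both locations.
* **Variance split**: fractions of each trait SD — genotype 0.25,
  genotype × location 0.08, genotype × year 0.08, genotype × environment
  0.11, plot error 0.33, year 0.40, block 0.06, replicate 0.04. Under this
  split the entry-mean heritability of seed yield is in the 70–85% range
  typical of replicated yield trials.
* **Susceptibility factors** $s_i$ jitter around 1 (SD 0.03) and are
  centred so the population-mean multiplier equals the nominal one — hence
  the realised stress intensity equals $1-\text{mult}$ in expectation,
  exactly.
* **Planted tolerance**: 5 genotypes receive a tolerance bonus of 0.8
  (four-fifths of the stress penalty removed before centring). The bonus
  was chosen by an a-priori design simulation: it is the scale at which
  planted tolerance is detectable by STI against the genotype
  yield-potential variance of a 34-entry trial. At the combined
  heat–drought contrast, the top-5 by STI then captures at least 3 of the
  5 planted tolerants in well over 80% of seeds; at the heat-only contrast
  (multiplier 0.80) the STI signal is genuinely dominated by yield
  potential and recovery is much weaker — a property of the index, not of
  the implementation, so recovery guarantees are stated at HDSE.
* **Trait correlation** runs through a single latent "sink strength"
  factor loading on seed yield (0.85), grains per spike (0.80), kernel
  weight (0.50) and straw (0.30), which reproduces the published pattern
  of NGS and TKW as the main yield-carrying traits.

One master stream (from the single `seed`) draws genotype- and year-level
effects; per-location sub-seeds drawn from it drive location-specific
draws. Identical `(config, seed)` pairs are bit-reproducible.

What the generator does **not** emulate: weather processes, spatial field
trend, non-Gaussian effects, location-specific stress severities (the
published trial shows substantially harsher stress at one location), or
measurement error structure. Passing recovery tests therefore demonstrate
the estimators' correctness under the stated model, not robustness to
real-data pathologies.

## Numerical and testing choices

* A stress contrast with $SI \le 0$, a zero population mean, zero optimum
  yield (for SSI) or zero biological yield (for HI) raise classed errors;
  they are degenerate inputs, not computable cases.
* Report rounding is half-away-from-zero (base R's `round()` is
  half-to-even, which disagrees with printed trial tables at e.g. 1.745).
* The test and validation suite uses these problem sizes, chosen to make
  sampling error negligible at single-CPU desk scale: 200 seeds for
  variance-component and tolerant-recovery checks, 1,000 permutations for
  the ANOVA-F and correlation-star type-I error rates (accepted band
  0.03–0.07 at $\alpha = 0.05$), 12 seeds for stress-intensity recovery,
  and 30–40 seeds for monotone noise-degradation checks.
* Where an established implementation exists for a step, it is the
  independent cross-check, not the implementation: Tukey decisions are
  verified against `stats::TukeyHSD`, sequential SS against explicit
  group-mean decompositions, and every index against a scalar re-derivation
  at `1e-12`.

## Known limitations

* No REML or mixed-model machinery; unbalanced trials are rejected rather
  than approximated. No type-III sums of squares.
* No inter-block information recovery for the lattice; blocks are an
  intra-block fixed nuisance term.
* Under multiplicative stress the genotype variance seen by the pooled
  ANOVA is environment-dependent; the EMS estimator then targets the
  design-average (the genotype main effect is attenuated by the squared
  mean multiplier), so exact variance-component recovery is asserted under
  the no-stress configuration and the attenuation itself is asserted under
  stress.
* Indices beyond the six implemented (YSI, DSI variants, K1/K2), bootstrap
  confidence intervals on ranks, path analysis and PCA are out of scope.
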