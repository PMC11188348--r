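---
title: "Fuzzy inference assessment of urban environmental health risk: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy inference assessment of urban environmental health risk: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbanhealth)
```

## The assessment problem

Urban residents are exposed simultaneously through several environmental
media: ambient air (PM2.5, NO2, PM10, O3), water (heavy metals, dissolved
oxygen, pH), soil (organic matter, nitrogen/phosphorus) and noise. No single
medium tells the whole story, and the relation between any one variable and
"health risk" is vague rather than sharp — 34 and 36 µg/m³ of PM2.5 are not
categorically different exposures. `urbanhealth` therefore treats the
aggregation problem with fuzzy logic: each monitoring variable is mapped
into linguistic terms with graded membership, expert-style rules combine the
terms, and a defuzzification step returns a crisp comprehensive health risk
index on $[0, 1]$.

## Formula-defined indices

Four conventional indices are computed alongside the fuzzy assessment and
feed the evaluation protocol.

**Air-quality sub-index.** For a pollutant with monitored concentration $C$
falling in the graded interval $[C_{low}, C_{high}]$ with index bounds
$[I_{low}, I_{high}]$,

$$\mathrm{IAQI} \;=\; \frac{I_{high}-I_{low}}{C_{high}-C_{low}}\,(C-C_{low}) + I_{low}.$$

The shipped breakpoint tables follow the Chinese ambient air-quality grading
(index levels 0/50/100/150/200/300/400/500); they live in a versioned YAML
file and are fully user-overridable, with units fixed per pollutant and
validated at load. Concentrations above the top interval raise a structured
`above_scale` error carrying the maximum index — silent capping is a caller
decision (the CLI and the batch assessor cap with a warning). Across
pollutants the overall index is the maximum sub-index, the universal
aggregation convention; the attaining pollutant is reported as dominant.

**Thermal comfort.** The thermal comfort index combines temperature $T$
(°C), wind speed $V$ (m/s) and relative humidity $RH$ (%):

$$\mathrm{TCI} \;=\; \frac{T-14.3}{1 + 0.0216\,V\,(T-14.3)} + \bigl(1 - 0.01\,|70.5-RH|\bigr),$$

higher values meaning greater comfort. The wind term is read as a
*correction* of the temperature deviation — a denominator that damps the
felt deviation from the 14.3 °C reference as wind increases — because that
is the only reading under which the three named effects (temperature
deviation, wind correction, humidity deviation from the 70.5 % optimum)
compose sensibly. The source formula typography admits a purely additive
reading too; it is implemented behind `form = "additive"` and neither
reading is asserted as canonical. With the ratio form the denominator can
vanish for cold, windy conditions ($T < 14.3$, large $V$); denominators
within `eps` (default `1e-8`) of zero raise a `degenerate_input` error
rather than returning an arbitrarily large value.

**Noise pollution.** With per-source contribution rates $p_i$ and decibel
levels $d_i$,

$$\mathrm{NPI} = \frac{\sum_i p_i\,d_i}{\sum_i p_i},$$

a weighted mean that is invariant to rescaling all $p_i$ and bounded by the
extreme source levels.

**Composite air-quality index.** $I_{sum} = \sum_p C_p / S_p$ over the
pollutants present, with $S_p$ the secondary standard concentration (annual
for SO2/NO2/PM10/PM2.5, daily for CO, 8-hour for O3; defaults 60/40/70/35,
4 mg/m³ and 160 µg/m³). Larger values indicate heavier overall pollution;
the index is linear and additive in the concentrations.

## The fuzzy inference engine

Input terms use the sigmoid membership

$$\mu(x) = \frac{1}{1+\exp(-c\,(x-a)/b)},$$

with center $a$ (the 0.5 crossing), steepness $c$ (sign gives direction) and
base $b$ rescaling the axis; $b$ defaults to 1 so $c$ alone sets steepness.
The exact grouping of $(x-a)$, $b$ and $c$ is a design decision here: $a$ is
defined as the center and $c$ as the steepness control, which forces the
argument to be proportional to $(x-a)$ and leaves $b$ as a scale.
Output terms are Gaussian, $\mu(y)=\exp(-(y-b)^2/2\sigma^2)$, peaking at 1
exactly at the center; triangular terms are also available and selectable
per term in configuration, since "triangular-shaped" descriptions and
Gaussian formulas are both current in the fuzzy-risk literature.

Rules are conjunctions of (variable, label) pairs with a nonnegative weight.
The AND operator defaults to `product` (smooth and differentiable, which
makes the monotonicity of the shipped tree provable by separability); `min`
is available per system. OR connectives are deliberately not supported — the
rule bases used here never need them, and their absence keeps firing
strengths multiplicative.

Defuzzification is the weighted average

$$\mathrm{Output} = \frac{\sum_i w_i\,\mathrm{Output}_i}{\sum_i w_i},$$

with $w_i$ the firing strength and $\mathrm{Output}_i$ a *crisp* consequent
level — the zero-order Takagi–Sugeno reading. A linguistic consequent's
level is the center of its output membership function; rules may also carry
numeric consequents directly. Centroid-of-area defuzzification over the
aggregated output surface is out of scope. The output is therefore always a
convex combination of the fired consequent levels, which yields the
boundedness guarantee `risk` $\in [0,1]$ for free. If no rule fires (all
strengths zero) the engine raises `no_rule_fired` instead of inventing a
neutral value; the shipped tree cannot reach this state because sigmoid and
Gaussian memberships are strictly positive.

Values outside a variable's declared universe are clamped with a warning by
default (monitoring data contain excursions); `clamp = FALSE` turns
excursions into hard errors.

## The hierarchical tree

A flat system over all ten variables with three terms each would need
$3^{10}$ rules. The shipped default instead uses a tree: one fuzzy system
per medium (air: 81 rules, water: 27, soil: 9, noise: 3) producing a
sub-score on $[0,1]$, and a root system (81 rules) over the four
sub-scores producing the risk index. Rule bases are full monotone grids:
each cell's crisp consequent is affine in the (weighted) mean *severity* of
its terms, $L = 0.1 + 0.8\,\overline{s}$, where term severities are
0/0.5/1 (benign/medium/harmful) oriented by each variable's direction —
increasing-harm for the pollutants, soil variables and noise, decreasing for
dissolved oxygen, and V-shaped for pH (acidic and alkaline terms harmful,
a Gaussian neutral term centered at 7.5 benign, encoding distance from the
6.5–8.5 neutral band).

Under product-AND this construction is *separable*: along any one variable
the output is an affine function of that variable's severity profile
$g(x) = \sum_t \mu_t(x)\,s_t / \sum_t \mu_t(x)$, so monotonicity of the
whole tree reduces to monotonicity of $g$ per variable, which holds for the
shipped term placement (opposed sigmoids at 30 %/70 % of the universe,
slope parameter 8 on the normalised axis, Gaussian medium with
$\sigma = 0.12$ of the span). `tree_monotonicity()` verifies this on a grid
and is part of the test suite.

Root media weights are 0.35 (air), 0.35 (noise), 0.17 (water), 0.13 (soil).
The ordering follows the consensus ranking of urban environmental health
burdens — ambient air pollution first and community noise second among
environmental exposures, with within-city water and soil variation
contributing less at monthly timescales. Universes (e.g. PM2.5 on
[0, 100] µg/m³, noise on [40, 90] dB) are set to plausible urban monitoring
ranges so that realistic data exercise the responsive part of the terms.

The tree is an explicit, documented default, not a claim about any city's
true rule base: no published rule base or membership parameters exist for
this problem, so every assessment and evaluation function takes the tree as
a parameter and trees serialize to YAML (`write_fis_tree()`) for
substitution, review and versioning. Consequent levels for low/medium/high
sit at 0.1/0.5/0.9 by default, so the benign and extreme corners of the
input space map to risks near 0.1 and 0.9 and the all-midpoint record maps
near 0.5.

## Evaluation protocol

Three analyses quantify how trustworthy a batch of assessments is.

*Credibility.* A percentile bootstrap interval on the mean risk (resample
records with replacement, default $B = 2000$, take empirical quantiles) at
the 90 % and 95 % levels. The percentile method is the assumption-light
default; BCa (jackknife acceleration) is available behind `method = "bca"`.
Intervals are bit-reproducible under a seed, and both levels computed from
one seed share resamples, so the 95 % interval always contains the 90 %.

*Significance.* No distributional assumptions are warranted for FIS output,
so association between each indicator (IAQI, TCI, NPI) and the risk output
is tested by permutation: statistic $|r|$ (Pearson), add-one-smoothed
p-value $p = (1 + \#\{|r_{perm}| \ge |r_{obs}|\})/(n_{perm}+1)$ with
$n_{perm} \ge 999$, so $p$ is never exactly 0 and has resolution
$1/(n_{perm}+1)$. The three p-values are reported raw; Holm-adjusted values
are additionally emitted and labelled. The test's type-I error at
$\alpha = 0.05$ is verified by simulation (1,000 null datasets of $n = 50$)
to lie in $[0.03, 0.07]$, and its power at a planted $r = 0.6$, $n = 100$
exceeds 95 %.

*Applicability.* Against an explicit observed-risk reference:
$\mathrm{RMSE}$, $R^2 = 1 - SS_{res}/SS_{tot}$, and a scalar residual
magnitude read as the mean absolute residual (the mean signed residual is
also emitted). What "observed risk" is must be supplied by the user — the
package requires an explicit column and does not invent a reference. Note
that the metrics compare on the raw scale: the default tree is an index,
not a calibrated probability, so against a latent probability scale $R^2$
can be small or negative even when rank agreement is strong; the recovery
correlation is the scale-free companion diagnostic.

Correlation screening (Pearson default, Spearman via config) covers the ten
monitoring variables plus the three indicators, with pairwise-complete
missing handling and explicit flags for constant factors.

## The synthetic-city generator

Because no multi-city multi-media monitoring dataset with ground-truth risk
is publicly deposited, the package ships a generator whose archetypes act as
the package's study conditions. Three profiles are anchored to composite
air-quality indices of 3.92 ("B", heavy pollution), 3.04 ("W", moderate)
and 2.3 ("K", relatively clean): pollutant means allocate the target index
across PM2.5/PM10/NO2/O3 with fixed shares (0.32/0.28/0.22/0.18), so batch
means reproduce the anchor within a few percent at $n = 500$.

Marginals are Normal truncated at zero. A-priori spread choices: pollutant
CV 0.25 (month-scale urban variability), noise sd 5 dB, heavy-metal CV 0.3,
dissolved-oxygen CV 0.1, pH sd 0.3, soil CVs 0.15 — water and soil are
temporally stabler media than air. Variables are independent except a
planted PM2.5–PM10 correlation of 0.8 (co-emitted particulates). Noise
decomposes into traffic/construction/ambient sources with Dirichlet(4,2,2)
contribution rates and source levels Normal around the overall level with
fixed offsets (+2/+4/−5 dB).

The latent health risk is a logistic of a weighted sum of the standardized
PM2.5 and noise levels plus Normal noise,
$\mathrm{risk} = \mathrm{logistic}(w_{pm}\,z_{pm25} + w_{n}\,z_{noise} +
\varepsilon)$. The logistic link keeps the latent risk in $[0,1]$ and makes
monotone recovery provable. Per-city loadings are set to the qualitative
correlation structure the archetypes represent — B: 0.75/0.62 with PM2.5
dominant; W: 0.62/0.70 and K: 0.45/0.55 with noise dominant — and
$\sigma_\varepsilon$ completes the linear predictor to approximately unit
variance, so the planted factor–risk correlations land near the loadings.

What the generator does **not** emulate: spatiotemporal autocorrelation,
seasonality, site heterogeneity beyond labels, inter-media dependence
(beyond PM2.5–PM10), and any thermal-comfort contribution to the latent
risk. Consequently the permutation test on TCI is expectedly
non-significant on synthetic batches — the generator plants no
thermal–risk association — and passing tests on synthetic data demonstrate
engine and protocol correctness, not real-world validity of the default
rule base.

## Numerical choices and degenerate inputs

- Sigmoid memberships are clamped to the open interval
  $[10^{-300}, 1-10^{-15}]$ so saturation never yields exact 0/1 and
  product-AND strengths never underflow to all-zero.
- Breakpoint rows must be sorted and contiguous to $10^{-9}$; the top row's
  upper bound is an inclusive cap.
- The batch assessor and the scalar assessor are one engine (the scalar
  path is the one-row batch); their agreement to $10^{-12}$ and their
  agreement with an independently coded straight-line oracle to $10^{-9}$
  are both under test.
- Bootstrap and permutation draws run inside a seed scope that restores the
  caller's RNG state, so library calls never perturb user simulations.
- Zero-variance inputs are errors (`degenerate_input`), not NaNs: constant
  observed vectors for $R^2$, constant indices for the permutation test.
  Constant *risks* for the bootstrap are fine and give a zero-width
  interval.
- Validation problems are collected, not silently dropped: `read_records()`
  returns the valid rows plus a `validation` attribute naming row, column
  and reason for every rejected cell.

## Problem sizes used in validation

The shipped validation suite uses $n = 500$ records per archetype for
calibration and recovery checks, 1,000 null datasets ($n = 50$) for
type-I-error calibration, 200 datasets ($n = 100$) for power, 500
replications ($n = 200$, $B = 2000$) for bootstrap coverage, 1,000 random
inputs per formula-index oracle comparison and 100 random systems for the
engine-equivalence check. These sizes make the Monte-Carlo acceptance bands
(e.g. type-I error in $[0.03, 0.07]$) comfortably stable across seeds.

## Known limitations

- The default tree encodes generic monotone expert knowledge, not
  city-specific epidemiology; its absolute risk values are an index, not a
  calibrated probability (see the applicability note above).
- Individual-level variation (age, susceptibility, exposure duration) is
  out of scope; assessments are per site-time record.
- No spatial interpolation between sites and no temporal forecasting are
  attempted.
- The thermal comfort and air-quality sub-index formulas are used as given;
  no unit inference or conversion is performed beyond validation of the
  configured units.
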